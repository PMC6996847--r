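#' Minimum-cost explanation of a transmitted haplotype
#'
#' Explains a haplotype transmitted from a phased parent as the parent's own
#' haplotype (no event), a crossover mosaic of the two parental haplotypes,
#' a short internal gene-conversion tract copied from the homolog, a
#' repeat-unit insertion/deletion, or a bounded combination of these.
#'
#' The cost model is explicit: each crossover breakpoint costs 2, each point
#' event (conversion or indel) costs 1, and the search budget is at most 3
#' breakpoints plus at most 1 point event — anything needing more is
#' returned as `unexplained` rather than silently dropped. Conversion is
#' only available for tracts spanning at most 2 panel loci flanked on both
#' sides by same-haplotype context, so a single-locus switch at a terminal
#' panel locus is always called recombination (the conversion reading is
#' recorded as a tie). Indel offsets must be an exact multiple of the
#' locus `repeat_unit`, at most `max_indel_units` units. Breakpoints are
#' localized to the interval between the flanking informative loci
#' (uninformative loci — where the parental haplotypes agree — widen the
#' interval and never anchor a breakpoint).
#'
#' @param parent_haps Integer `L x 2` matrix, the parent's two haplotypes in
#'   panel map order (`NA` = unresolved locus).
#' @param transmitted Integer vector of length `L`, the transmitted
#'   haplotype (`NA` = unresolved).
#' @param panel The [mhc_panel()].
#' @param max_breakpoints Breakpoint budget (default 3).
#' @param max_indel_units Largest indel size in repeat units (default 3).
#' @return List of class `mhc_explanation`: `status` (`"none"`, `"event"`,
#'   `"unexplained"` or `"skipped"`), `events` (tibble `type`,
#'   `breakpoints`, `loci`, `m`, `tie`), `cost`, `n_breakpoints`,
#'   `n_known`, `n_informative`.
#' @export
explain_transmission <- function(parent_haps, transmitted, panel,
                                 max_breakpoints = 3L,
                                 max_indel_units = 3L) {
  L <- nrow(panel)
  h1 <- parent_haps[, 1]
  h2 <- parent_haps[, 2]
  t_hap <- transmitted
  known <- which(!is.na(t_hap) & !is.na(h1) & !is.na(h2))
  empty_events <- tibble::tibble(type = character(), breakpoints = character(),
                                 loci = character(), m = integer(),
                                 tie = character())
  out <- function(status, events = empty_events, cost = NA_real_,
                  n_bp = NA_integer_) {
    structure(list(status = status, events = events, cost = cost,
                   n_breakpoints = n_bp, n_known = length(known),
                   n_informative = sum(h1[known] != h2[known])),
              class = "mhc_explanation")
  }
  if (length(known) < 2) return(out("skipped"))
  m1 <- t_hap[known] == h1[known]
  m2 <- t_hap[known] == h2[known]
  informative <- h1[known] != h2[known]
  neither <- !m1 & !m2
  if (sum(neither) > 1) return(out("unexplained"))
  forced_pos <- known[informative & !neither]
  src <- ifelse(m1[informative & !neither], 1L, 2L)
  runs <- if (length(src)) {
    r <- rle(src)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    tibble::tibble(src = r$values,
                   first = forced_pos[starts], last = forced_pos[ends],
                   n_loci = r$lengths)
  } else {
    tibble::tibble(src = integer(), first = integer(), last = integer(),
                   n_loci = integer())
  }
  k0 <- max(0L, nrow(runs) - 1L)
  points <- 0L
  extra_bp <- 0L
  extra_bps <- character(0)
  events <- empty_events
  ties <- character(0)

  # -- indel at the (single) locus matching neither parental allele
  if (any(neither)) {
    ln <- known[neither]
    ru <- panel$repeat_unit[ln]
    lf <- forced_pos[forced_pos < ln]
    rf <- forced_pos[forced_pos > ln]
    run_at <- function(pos) {
      hit <- which(runs$first <= pos & runs$last >= pos)
      if (length(hit)) runs$src[hit[1]] else NA_integer_
    }
    ctx_src <- NA_integer_
    both_flanks <- length(lf) > 0 && length(rf) > 0
    if (both_flanks) {
      sl <- run_at(max(lf))
      sr <- run_at(min(rf))
      if (!is.na(sl) && !is.na(sr) && sl == sr) ctx_src <- sl
    } else if (length(lf) > 0) {
      ctx_src <- run_at(max(lf))
    } else if (length(rf) > 0) {
      ctx_src <- run_at(min(rf))
    }
    check_off <- function(base) {
      d <- t_hap[ln] - base
      if (!is.na(base) && d != 0 && d %% ru == 0 &&
          abs(d %/% ru) <= max_indel_units) d %/% ru else NA_integer_
    }
    uninf <- h1[ln] == h2[ln]
    if (uninf) {
      m_units <- check_off(h1[ln])
      if (is.na(m_units)) return(out("unexplained"))
    } else if (!is.na(ctx_src)) {
      base_ctx <- if (ctx_src == 1L) h1[ln] else h2[ln]
      base_oth <- if (ctx_src == 1L) h2[ln] else h1[ln]
      m_units <- check_off(base_ctx)
      if (is.na(m_units)) {
        m_units <- check_off(base_oth)
        if (is.na(m_units)) return(out("unexplained"))
        # source flip needed around the indel locus
        extra_bp <- if (both_flanks) 2L else 1L
        if (length(lf)) {
          extra_bps <- c(extra_bps, paste0(panel$locus[max(lf)], "|",
                                           panel$locus[ln]))
        }
        if (length(rf)) {
          extra_bps <- c(extra_bps, paste0(panel$locus[ln], "|",
                                           panel$locus[min(rf)]))
        }
        extra_bps <- extra_bps[seq_len(extra_bp)]
      }
    } else {
      # no context (or the locus sits inside a switch interval): either
      # source is reachable without extra switches
      mu1 <- check_off(h1[ln])
      mu2 <- check_off(h2[ln])
      if (is.na(mu1) && is.na(mu2)) return(out("unexplained"))
      m_units <- if (!is.na(mu1) && !is.na(mu2)) {
        if (abs(mu1) <= abs(mu2)) mu1 else mu2
      } else if (!is.na(mu1)) mu1 else mu2
    }
    points <- 1L
    events <- dplyr::bind_rows(events, tibble::tibble(
      type = if (m_units > 0) "insertion" else "deletion",
      breakpoints = NA_character_, loci = panel$locus[ln],
      m = as.integer(m_units), tie = NA_character_))
  }

  # -- conversion absorption: internal run spanning <= 2 panel loci
  absorbed <- integer(0)
  if (points == 0L && nrow(runs) >= 3) {
    span <- runs$last - runs$first + 1L
    eligible <- which(seq_len(nrow(runs)) > 1 &
                        seq_len(nrow(runs)) < nrow(runs) & span <= 2L)
    if (length(eligible)) {
      pick <- eligible[1]
      absorbed <- pick
      if (length(eligible) > 1) ties <- c(ties, "multiple_conversion_candidates")
      conv_loci <- panel$locus[forced_pos[forced_pos >= runs$first[pick] &
                                            forced_pos <= runs$last[pick]]]
      events <- dplyr::bind_rows(events, tibble::tibble(
        type = "conversion", breakpoints = NA_character_,
        loci = paste(conv_loci, collapse = ","), m = NA_integer_,
        tie = NA_character_))
      points <- 1L
    }
  }
  final_runs <- if (length(absorbed)) {
    kept <- runs[-absorbed, ]
    # neighbours of the absorbed island share a source: merge them
    merged <- kept[1, ]
    for (i in seq_len(nrow(kept))[-1]) {
      if (kept$src[i] == merged$src[nrow(merged)]) {
        merged$last[nrow(merged)] <- kept$last[i]
        merged$n_loci[nrow(merged)] <- merged$n_loci[nrow(merged)] +
          kept$n_loci[i]
      } else {
        merged <- dplyr::bind_rows(merged, kept[i, ])
      }
    }
    merged
  } else {
    runs
  }
  k_final <- max(0L, nrow(final_runs) - 1L) + extra_bp
  if (k_final > max_breakpoints) return(out("unexplained"))
  if (nrow(final_runs) >= 2 || length(extra_bps)) {
    if (nrow(final_runs) >= 2 &&
        (final_runs$n_loci[1] == 1L ||
         final_runs$n_loci[nrow(final_runs)] == 1L)) {
      ties <- c(ties, "terminal_single_locus_switch_vs_conversion")
    }
    bps <- if (nrow(final_runs) >= 2) {
      vapply(seq_len(nrow(final_runs) - 1L), function(i) {
        paste0(panel$locus[final_runs$last[i]], "|",
               panel$locus[final_runs$first[i + 1L]])
      }, character(1))
    } else character(0)
    bps <- c(bps, extra_bps)
    events <- dplyr::bind_rows(tibble::tibble(
      type = "recombination", breakpoints = paste(bps, collapse = ";"),
      loci = NA_character_, m = NA_integer_,
      tie = if (length(ties)) paste(ties, collapse = ";") else NA_character_),
      events)
  }
  cost <- 2 * k_final + points
  if (nrow(events) == 0) {
    return(out("none",
               tibble::tibble(type = "none", breakpoints = NA_character_,
                              loci = NA_character_, m = NA_integer_,
                              tie = NA_character_),
               cost = 0, n_bp = 0L))
  }
  out("event", events, cost = cost, n_bp = k_final)
}

#' Call meiotic events for every resolvable transmission
#'
#' Runs [explain_transmission()] for each parent-offspring transmission
#' (both sides of a full trio) where the parent's phase and the offspring's
#' transmitted haplotype are sufficiently resolved. Mendelian-conflict loci
#' with a unique best-effort orientation contribute their candidate allele
#' to the transmitted haplotype (that is how indels surface); duplication
#' patterns (offspring carrying both alleles of one parent at a locus,
#' neither matching the other parent) are emitted directly as conversion
#' events on the failing parent's transmission. Transmissions that cannot
#' be compared are reported as `skipped`, never silently dropped.
#'
#' @param data An `mhc_data` object with pedigree.
#' @param phase The matching `mhc_phase` from [phase_population()].
#' @return Tibble of class `mhc_events`, one row per event (plus `none`,
#'   `unexplained` and `skipped` rows), with columns `offspring`, `parent`,
#'   `parent_sex`, `population`, `type`, `breakpoints`, `loci`, `m`,
#'   `n_breakpoints`, `cost`, `tie`, `resulting_haplotype`,
#'   `is_new_haplotype`.
#' @export
call_events <- function(data, phase) {
  panel <- data$panel
  info <- phase$info
  parent_pool <- haplotype_inventory(phase, include = "parents")
  rows <- list()
  off <- info[info$is_offspring, ]
  origin_by_id <- split(phase$origin, phase$origin$id)
  gm <- genotype_matrices(data)
  # which of a parent's two haplotypes does a transmission trace? NA when
  # the votes are absent or mixed (candidate recombinant)
  source_side <- function(t_hap, pid) {
    pA <- phase$hap_a[, pid]
    pB <- phase$hap_b[, pid]
    sel <- !is.na(t_hap) & !is.na(pA) & !is.na(pB) & pA != pB
    vA <- sum(t_hap[sel] == pA[sel])
    vB <- sum(t_hap[sel] == pB[sel])
    if (vA > 0 && vB == 0) "A" else if (vB > 0 && vA == 0) "B" else
      NA_character_
  }
  for (i in seq_len(nrow(off))) {
    oid <- off$id[i]
    pop <- off$population[i]
    o_origin <- origin_by_id[[oid]]
    for (side in c("dam", "sire")) {
      pid <- off[[side]][i]
      if (is.na(pid)) next
      parent_haps <- cbind(phase$hap_a[, pid], phase$hap_b[, pid])
      t_hap <- if (side == "dam") phase$hap_a[, oid] else phase$hap_b[, oid]
      conv_dup <- character(0)
      if (!is.null(o_origin)) {
        confl <- o_origin$status == "conflict"
        cand <- if (side == "dam") o_origin$maternal else o_origin$paternal
        t_hap[confl & !is.na(cand)] <- cand[confl & !is.na(cand)]
        dup_here <- confl & !is.na(o_origin$dup_parent) &
          o_origin$dup_parent == side
        conv_dup <- o_origin$locus[dup_here]
        t_hap[confl & !is.na(o_origin$dup_parent)] <- NA_integer_
        # orient remaining conflict loci from the other parent's
        # established transmission: the allele matching the other parent's
        # transmitted haplotype belongs to the other side
        other <- if (side == "dam") "sire" else "dam"
        other_pid <- off[[other]][i]
        open <- which(confl & is.na(t_hap) & is.na(o_origin$dup_parent))
        if (length(open) && !is.na(other_pid)) {
          other_t <- if (other == "dam") phase$hap_a[, oid] else
            phase$hap_b[, oid]
          s <- source_side(other_t, other_pid)
          if (!is.na(s)) {
            other_hap <- if (s == "A") phase$hap_a[, other_pid] else
              phase$hap_b[, other_pid]
            og <- gm[[oid]]
            for (l in open) {
              if (is.na(other_hap[l])) next
              hit <- og[l, ] == other_hap[l]
              if (sum(hit) == 1) t_hap[l] <- og[l, !hit]
            }
          }
        }
      }
      expl <- explain_transmission(parent_haps, t_hap, panel)
      hs <- hap_string(t_hap)
      is_new <- if (is.na(hs)) NA else
        !hs %in% parent_pool$haplotype[parent_pool$population == pop]
      base <- tibble::tibble(
        offspring = oid, parent = pid, parent_sex = side, population = pop,
        n_breakpoints = expl$n_breakpoints, cost = expl$cost,
        resulting_haplotype = hs, is_new_haplotype = is_new
      )
      ev <- if (expl$status %in% c("skipped", "unexplained")) {
        tibble::tibble(type = expl$status, breakpoints = NA_character_,
                       loci = NA_character_, m = NA_integer_,
                       tie = NA_character_)
      } else {
        expl$events
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        base[rep(1, nrow(ev)), ], ev)
      for (lc in conv_dup) {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          base, tibble::tibble(type = "conversion", breakpoints = NA_character_,
                               loci = lc, m = NA_integer_,
                               tie = "duplication_pattern"))
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(offspring = character(), parent = character(),
                   parent_sex = character(), population = character(),
                   n_breakpoints = integer(), cost = numeric(),
                   resulting_haplotype = character(),
                   is_new_haplotype = logical(), type = character(),
                   breakpoints = character(), loci = character(),
                   m = integer(), tie = character())
  class(out) <- c("mhc_events", class(out))
  out
}

#' Count observable meioses per population
#'
#' One meiosis per parent-offspring pair: 2 per offspring with both parents
#' recorded, 1 per offspring with a single recorded parent.
#'
#' @param data An `mhc_data` object.
#' @return Tibble `population`, `n_offspring`, `n_meioses`.
#' @export
count_meioses <- function(data) {
  ind <- individuals(data)
  ind |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_offspring = sum(.data$is_offspring),
      n_meioses = sum((!is.na(.data$sire)) + (!is.na(.data$dam))),
      .groups = "drop"
    )
}

#' Per-population meiotic event frequencies and new-haplotype ratio
#'
#' Frequencies are percentages of meioses (parent-offspring pairs): a
#' transmission carrying at least one event of a type counts once for that
#' type. Offspring-level, transmission(haplotype)-level and
#' breakpoint-level recombination counts are all reported, since they
#' differ whenever one meiosis carries several breakpoints. The
#' new-haplotype ratio is the percentage of meioses whose transmitted
#' haplotype is a distinct, fully resolved haplotype absent from the
#' parental-generation pool.
#'
#' @param events An `mhc_events` tibble from [call_events()] (or any tibble
#'   with the same columns).
#' @param data The `mhc_data` the events were called on (for meiosis
#'   counts).
#' @return Tibble, one row per population: `n_offspring`, `n_meioses`,
#'   event counts (`n_recombinant_haplotypes`,
#'   `n_recombinant_offspring`, `n_breakpoints`, `n_conversion`,
#'   `n_insertion`, `n_deletion`, `n_none`, `n_unexplained`, `n_skipped`),
#'   `recombination_frequency`, `conversion_frequency`, `indel_frequency`,
#'   `n_new_haplotypes` and `new_haplotype_ratio` (percent).
#' @export
event_summary <- function(events, data) {
  mei <- count_meioses(data)
  pops <- mei$population
  rows <- lapply(pops, function(pop) {
    e <- events[events$population == pop, ]
    trans_key <- paste(e$offspring, e$parent)
    by_type <- function(tt) {
      length(unique(trans_key[e$type %in% tt]))
    }
    rec <- e[e$type == "recombination", ]
    n_bp <- sum(vapply(rec$breakpoints, function(b)
      if (is.na(b)) 0L else length(strsplit(b, ";")[[1]]), integer(1)))
    n_mei <- mei$n_meioses[mei$population == pop]
    pct <- function(n) if (n_mei > 0) 100 * n / n_mei else NA_real_
    new_haps <- unique(e$resulting_haplotype[!is.na(e$is_new_haplotype) &
                                               e$is_new_haplotype])
    tibble::tibble(
      population = pop,
      n_offspring = mei$n_offspring[mei$population == pop],
      n_meioses = n_mei,
      n_recombinant_haplotypes = by_type("recombination"),
      n_recombinant_offspring =
        length(unique(e$offspring[e$type == "recombination"])),
      n_breakpoints = n_bp,
      n_conversion = by_type("conversion"),
      n_insertion = by_type("insertion"),
      n_deletion = by_type("deletion"),
      n_none = by_type("none"),
      n_unexplained = by_type("unexplained"),
      n_skipped = by_type("skipped"),
      recombination_frequency = pct(by_type("recombination")),
      conversion_frequency = pct(by_type("conversion")),
      indel_frequency = pct(by_type(c("insertion", "deletion"))),
      n_new_haplotypes = length(new_haps),
      new_haplotype_ratio = pct(length(new_haps))
    )
  })
  dplyr::bind_rows(rows)
}

#' New-haplotype ratio from phased inventories
#'
#' Percentage of meioses whose offspring haplotype is a distinct fully
#' resolved haplotype absent from the parental-generation inventory of the
#' same population.
#'
#' @param phase An `mhc_phase`.
#' @param data The matching `mhc_data`.
#' @return Tibble `population`, `n_new_haplotypes`, `n_meioses`,
#'   `new_haplotype_ratio` (percent; `NA` where there are no meioses).
#' @export
new_haplotype_ratio <- function(phase, data) {
  mei <- count_meioses(data)
  parents <- haplotype_inventory(phase, include = "parents")
  kids <- haplotype_inventory(phase, include = "offspring")
  rows <- lapply(mei$population, function(pop) {
    ph <- parents$haplotype[parents$population == pop]
    kh <- unique(kids$haplotype[kids$population == pop])
    n_new <- sum(!kh %in% ph)
    n_mei <- mei$n_meioses[mei$population == pop]
    tibble::tibble(population = pop, n_new_haplotypes = n_new,
                   n_meioses = n_mei,
                   new_haplotype_ratio =
                     if (n_mei > 0) 100 * n_new / n_mei else NA_real_)
  })
  dplyr::bind_rows(rows)
}
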