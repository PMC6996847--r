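#' Per-locus parental-origin assignment for one offspring
#'
#' Labels the two offspring alleles maternal/paternal wherever Mendelian
#' logic forces it. At each locus both orientations are tested against the
#' typed parents: exactly one consistent orientation resolves the locus,
#' two leave it ambiguous, none is a conflict (a candidate meiotic event —
#' conflicts are reported, never dropped). For conflicts, a best-effort
#' orientation is recorded when exactly one side can still be attributed
#' (e.g. one allele is present in the sire but the other is absent from the
#' dam, pointing at a maternal-side mutation), and the duplication pattern —
#' both offspring alleles present in one parent, neither in the other — is
#' flagged as a candidate conversion on the failing parent's transmission.
#'
#' @param offspring,dam,sire Integer `L x 2` genotype matrices in panel map
#'   order (`NA` rows for missing loci); `dam`/`sire` may be `NULL` for an
#'   untyped parent.
#' @param panel The [mhc_panel()] giving locus names.
#' @return Tibble `locus`, `status`
#'   (`resolved`/`ambiguous`/`conflict`/`missing`), `maternal`, `paternal`
#'   (allele bp or `NA`), `dup_parent` (`NA`, `"dam"` or `"sire"`).
#' @export
assign_parental_origin <- function(offspring, dam, sire, panel) {
  L <- nrow(panel)
  status <- rep("missing", L)
  mat <- pat <- rep(NA_integer_, L)
  dup <- rep(NA_character_, L)
  for (l in seq_len(L)) {
    o <- offspring[l, ]
    if (anyNA(o)) next
    dg <- if (!is.null(dam)) dam[l, ] else c(NA_integer_, NA_integer_)
    sg <- if (!is.null(sire)) sire[l, ] else c(NA_integer_, NA_integer_)
    dam_typed <- !anyNA(dg)
    sire_typed <- !anyNA(sg)
    if (!dam_typed && !sire_typed) {
      status[l] <- "ambiguous"
      next
    }
    in_dam <- function(a) !dam_typed || a %in% dg
    in_sire <- function(a) !sire_typed || a %in% sg
    c1 <- in_dam(o[1]) && in_sire(o[2])  # maternal = o1
    c2 <- in_dam(o[2]) && in_sire(o[1])  # maternal = o2
    if (o[1] == o[2]) {
      if (c1) {
        status[l] <- "resolved"
        mat[l] <- o[1]
        pat[l] <- o[2]
      } else {
        status[l] <- "conflict"
      }
    } else if (c1 && !c2) {
      status[l] <- "resolved"
      mat[l] <- o[1]
      pat[l] <- o[2]
    } else if (c2 && !c1) {
      status[l] <- "resolved"
      mat[l] <- o[2]
      pat[l] <- o[1]
    } else if (c1 && c2) {
      status[l] <- "ambiguous"
    } else {
      status[l] <- "conflict"
      # best-effort orientation: one parent side still consistent
      d1 <- in_dam(o[1]); d2 <- in_dam(o[2])
      s1 <- in_sire(o[1]); s2 <- in_sire(o[2])
      if (dam_typed && sire_typed && d1 && d2 && !s1 && !s2) {
        dup[l] <- "sire"  # both alleles maternal in origin
      } else if (dam_typed && sire_typed && s1 && s2 && !d1 && !d2) {
        dup[l] <- "dam"
      } else {
        o1_ok <- d1 || s2   # orientation maternal=o1
        o2_ok <- d2 || s1   # orientation maternal=o2
        # prefer the orientation in which more parent checks pass
        sc1 <- d1 + s2
        sc2 <- d2 + s1
        if (sc1 > sc2) {
          mat[l] <- o[1]; pat[l] <- o[2]
        } else if (sc2 > sc1) {
          mat[l] <- o[2]; pat[l] <- o[1]
        }
      }
    }
  }
  tibble::tibble(locus = panel$locus, status = status,
                 maternal = mat, paternal = pat, dup_parent = dup)
}

#' Phase one family trio (or parent-offspring pair)
#'
#' Runs [assign_parental_origin()] and assembles the offspring's maternal
#' and paternal haplotypes from the resolved loci; ambiguous loci stay
#' unknown (no statistical imputation). For population-wide phasing with
#' parent back-inference and pool matching use [phase_population()].
#'
#' @inheritParams assign_parental_origin
#' @return List `origin` (the per-locus assignment tibble), `hap_maternal`,
#'   `hap_paternal` (integer vectors with `NA` at unresolved loci),
#'   `source` (`"trio"` or `"pair"`).
#' @export
phase_trio <- function(offspring, dam, sire, panel) {
  origin <- assign_parental_origin(offspring, dam, sire, panel)
  list(origin = origin,
       hap_maternal = origin$maternal,
       hap_paternal = origin$paternal,
       source = if (!is.null(dam) && !is.null(sire)) "trio" else "pair")
}

#' Phase a pedigreed population by constraint propagation
#'
#' Mirrors, as an algorithm, the manual trio-comparison procedure used to
#' determine multi-locus MHC haplotypes in horse families: only
#' Mendelian-forced assignments and matching against already established
#' parental haplotypes are used — unresolved loci stay unknown rather than
#' being imputed, so the result is fully reproducible and deterministic
#' (independent of input row order; individuals are processed in sorted id
#' order).
#'
#' The fixpoint iteration alternates three steps until nothing changes:
#' offspring are phased from their trios/pairs; each parent's two haplotypes
#' are accumulated from the haplotypes it transmitted (homozygous loci are
#' trivially phased; at heterozygous loci consistent transmissions are
#' merged greedily in sorted offspring order, and a transmission that
#' conflicts with the accumulated phase — a candidate recombinant — is set
#' aside for event calling rather than merged); remaining ambiguous
#' offspring loci are resolved when the transmitting parental haplotype is
#' established and matches exactly one orientation.
#'
#' @param data An `mhc_data` object with a pedigree attached.
#' @param max_iter Iteration cap for the fixpoint loop.
#' @return An object of class `mhc_phase`: list with matrices `hap_a`,
#'   `hap_b` (loci x individuals; for offspring, A = maternal and
#'   B = paternal), `status` (per-locus flags), tibbles `origin` (per
#'   offspring locus), `info` (per individual: `source`, population), and
#'   the `panel`. `tidy()` returns the haplotypes in long form.
#' @export
phase_population <- function(data, max_iter = 25L) {
  stopifnot(inherits(data, "mhc_data"))
  panel <- data$panel
  L <- nrow(panel)
  gm <- genotype_matrices(data)
  ind <- individuals(data)
  ind <- ind[order(ind$id), ]
  ids <- ind$id
  N <- length(ids)
  hap_a <- hap_b <- matrix(NA_integer_, L, N, dimnames = list(panel$locus, ids))
  status <- matrix("missing", L, N, dimnames = list(panel$locus, ids))
  offspring_ids <- ids[ind$is_offspring]
  # step 1: per-offspring Mendelian origin assignment (fixed)
  origin <- lapply(offspring_ids, function(oid) {
    i <- match(oid, ind$id)
    dam_id <- ind$dam[i]
    sire_id <- ind$sire[i]
    assign_parental_origin(
      gm[[oid]],
      if (!is.na(dam_id)) gm[[dam_id]] else NULL,
      if (!is.na(sire_id)) gm[[sire_id]] else NULL,
      panel
    )
  })
  names(origin) <- offspring_ids
  for (oid in offspring_ids) {
    o <- origin[[oid]]
    hap_a[, oid] <- o$maternal
    hap_b[, oid] <- o$paternal
    # conflict-orientation candidates are kept out of the phase itself
    hap_a[o$status == "conflict", oid] <- NA_integer_
    hap_b[o$status == "conflict", oid] <- NA_integer_
    status[, oid] <- o$status
  }
  # children of each parent, sorted (greedy merge order)
  kids_of <- function(pid, role) {
    sort(ind$id[!is.na(ind[[role]]) & ind[[role]] == pid])
  }
  parents <- sort(unique(stats::na.omit(c(ind$sire, ind$dam))))
  set_aside <- list()  # parent -> offspring ids whose transmission conflicted
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # step 2: accumulate parent phase from transmitted haplotypes
    for (pid in parents) {
      pg <- gm[[pid]]
      hom <- !is.na(pg[, 1]) & pg[, 1] == pg[, 2]
      het <- !is.na(pg[, 1]) & pg[, 1] != pg[, 2]
      A <- hap_a[, pid]
      B <- hap_b[, pid]
      newA <- ifelse(hom, pg[, 1], A)
      newB <- ifelse(hom, pg[, 1], B)
      trans <- list()
      for (kid in kids_of(pid, "dam")) trans[[kid]] <- hap_a[, kid]
      for (kid in kids_of(pid, "sire")) trans[[kid]] <- hap_b[, kid]
      aside <- character(0)
      kids <- sort(names(trans))
      # mutation candidates (allele not in the parent) are set aside first
      usable <- character(0)
      for (kid in kids) {
        t_hap <- trans[[kid]]
        sel <- het & !is.na(t_hap)
        if (!any(sel)) next
        if (all(t_hap[sel] == pg[sel, 1] | t_hap[sel] == pg[sel, 2])) {
          usable <- c(usable, kid)
        } else {
          aside <- c(aside, kid)
        }
      }
      # pairwise conflict graph: two transmissions conflict when, over the
      # parent-heterozygous loci both cover, they agree at some loci and
      # complement at others (one of them must be a recombinant mosaic);
      # iteratively drop the max-conflict transmissions (all of them on a
      # tie, no guessing) until the graph is conflict-free
      if (length(usable) > 1) {
        nk <- length(usable)
        conf <- matrix(FALSE, nk, nk)
        for (i in seq_len(nk - 1)) {
          for (j in (i + 1):nk) {
            ti <- trans[[usable[i]]]
            tj <- trans[[usable[j]]]
            sel <- het & !is.na(ti) & !is.na(tj)
            if (!any(sel)) next
            same <- sum(ti[sel] == tj[sel])
            diff <- sum(ti[sel] != tj[sel])
            conf[i, j] <- conf[j, i] <- same > 0 && diff > 0
          }
        }
        while (any(conf)) {
          deg <- rowSums(conf)
          drop <- which(deg == max(deg))
          aside <- c(aside, usable[drop])
          conf[drop, ] <- FALSE
          conf[, drop] <- FALSE
          usable <- replace(usable, drop, NA)
        }
        usable <- usable[!is.na(usable)]
      }
      # merge the surviving, mutually consistent transmissions; ones with
      # no overlap yet are deferred until the accumulated phase reaches them
      pending <- usable
      anchored <- any(het & !is.na(newA))
      repeat {
        progressed <- FALSE
        still <- character(0)
        for (kid in pending) {
          t_hap <- trans[[kid]]
          sel <- het & !is.na(t_hap)
          known <- !is.na(newA[sel])
          vA <- sum(known & t_hap[sel] == newA[sel])
          vB <- sum(known & t_hap[sel] != newA[sel])
          if (vA > 0 && vB > 0) {
            aside <- c(aside, kid)  # mosaic w.r.t. accumulated phase
            next
          }
          if (vA == 0 && vB == 0 && anchored) {
            still <- c(still, kid)
            next
          }
          if (vB > 0) {
            # transmission is the B side: complement into A
            fill <- sel & is.na(newA)
            newA[fill] <- ifelse(t_hap[fill] == pg[fill, 1],
                                 pg[fill, 2], pg[fill, 1])
          } else {
            fill <- sel & is.na(newA)
            newA[fill] <- t_hap[fill]
          }
          anchored <- TRUE
          progressed <- TRUE
        }
        pending <- still
        if (!progressed || !length(pending)) break
      }
      newB[het] <- ifelse(is.na(newA[het]), NA_integer_,
                          ifelse(newA[het] == pg[het, 1],
                                 pg[het, 2], pg[het, 1]))
      if (!identical(newA, A) || !identical(newB, B)) {
        hap_a[, pid] <- newA
        hap_b[, pid] <- newB
        st <- status[, pid]
        st[(hom | het) & !is.na(newA)] <- "resolved"
        st[(hom | het) & is.na(newA) & st != "conflict"] <- "ambiguous"
        status[, pid] <- st
        changed <- TRUE
      }
      set_aside[[pid]] <- aside
    }
    # step 3: resolve ambiguous offspring loci by matching the established
    # parental haplotype (pool matching); only uniquely forced resolutions
    for (oid in offspring_ids) {
      i <- match(oid, ind$id)
      o <- origin[[oid]]
      amb <- which(o$status == "ambiguous")
      if (!length(amb)) next
      og <- gm[[oid]]
      for (side in c("dam", "sire")) {
        pid <- ind[[side]][i]
        if (is.na(pid)) next
        t_hap <- if (side == "dam") hap_a[, oid] else hap_b[, oid]
        pA <- hap_a[, pid]
        pB <- hap_b[, pid]
        # which parental haplotype is being transmitted?
        sel <- !is.na(t_hap) & !is.na(pA) & !is.na(pB) & pA != pB
        vA <- sum(t_hap[sel] == pA[sel])
        vB <- sum(t_hap[sel] == pB[sel])
        if ((vA > 0) == (vB > 0)) next  # unknown or mosaic: no propagation
        src <- if (vA > 0) pA else pB
        for (l in amb) {
          if (o$status[l] != "ambiguous" || is.na(src[l])) next
          hit <- og[l, ] == src[l]
          if (sum(hit) == 1) {
            m_allele <- if (side == "dam") og[l, hit] else og[l, !hit]
            p_allele <- if (side == "dam") og[l, !hit] else og[l, hit]
            o$status[l] <- "resolved"
            o$maternal[l] <- m_allele
            o$paternal[l] <- p_allele
            hap_a[l, oid] <- m_allele
            hap_b[l, oid] <- p_allele
            status[l, oid] <- "resolved"
            changed <- TRUE
          } else if (sum(hit) == 2) {
            # offspring homozygous cannot be ambiguous; defensive no-op
          }
        }
      }
      origin[[oid]] <- o
    }
    if (!changed) break
  }
  source <- vapply(unname(ids), function(id) {
    i <- match(id, ind$id)
    if (ind$is_offspring[i]) {
      if (!is.na(ind$sire[i]) && !is.na(ind$dam[i])) "trio" else "pair"
    } else if (any(!is.na(hap_a[, id]))) "propagated" else "unphased"
  }, character(1), USE.NAMES = FALSE)
  origin_tbl <- dplyr::bind_rows(
    lapply(offspring_ids, function(oid) {
      o <- origin[[oid]]
      o$id <- oid
      o
    })
  )
  structure(
    list(hap_a = hap_a, hap_b = hap_b, status = status,
         origin = origin_tbl,
         info = tibble::tibble(id = ids, population = ind$population,
                               sire = ind$sire, dam = ind$dam,
                               is_offspring = ind$is_offspring,
                               source = source),
         set_aside = set_aside,
         panel = panel),
    class = "mhc_phase"
  )
}

#' @export
print.mhc_phase <- function(x, ...) {
  res <- mean(x$status == "resolved")
  cat("<mhc_phase> ", ncol(x$hap_a), " individuals, ",
      nrow(x$hap_a), " loci; ", round(100 * res, 1),
      "% of individual-loci resolved\n", sep = "")
  print(table(x$info$source))
  invisible(x)
}

#' @rdname phase_population
#' @param x An `mhc_phase` object.
#' @param ... Unused.
#' @export
tidy.mhc_phase <- function(x, ...) {
  ids <- colnames(x$hap_a)
  loci <- rownames(x$hap_a)
  is_off <- x$info$is_offspring[match(ids, x$info$id)]
  a <- tibble::tibble(id = rep(ids, each = length(loci)),
                      locus = rep(loci, length(ids)),
                      origin = ifelse(rep(is_off, each = length(loci)),
                                      "maternal", "hap1"),
                      allele = as.integer(x$hap_a),
                      status = as.character(x$status))
  b <- tibble::tibble(id = rep(ids, each = length(loci)),
                      locus = rep(loci, length(ids)),
                      origin = ifelse(rep(is_off, each = length(loci)),
                                      "paternal", "hap2"),
                      allele = as.integer(x$hap_b),
                      status = as.character(x$status))
  dplyr::bind_rows(a, b)
}

#' Collapse a haplotype vector to its dash-separated string form
#'
#' Returns `NA` when any locus is unresolved, so only complete haplotypes
#' ever enter an inventory.
#'
#' @param h Integer vector of allele sizes in panel map order.
#' @return A string like `"226-147-..."`, or `NA_character_`.
#' @export
hap_string <- function(h) {
  if (anyNA(h)) NA_character_ else paste(h, collapse = "-")
}

#' Population haplotype inventory
#'
#' Distinct fully resolved haplotypes per population with carrier counts.
#' A haplotype enters the inventory only when all panel loci are resolved —
#' partially known haplotypes are never counted as distinct (they are
#' tallied as unresolved instead).
#'
#' @param phase An `mhc_phase` from [phase_population()].
#' @param include Which individuals to count: `"all"` (default),
#'   `"parents"` (non-offspring only) or `"offspring"`.
#' @return An object of class `mhc_inventory`: tibble `population`,
#'   `haplotype` (dash-separated allele string in map order), `n_copies`
#'   (chromosome count), plus attributes `totals` (distinct haplotypes and
#'   unresolved chromosome tallies per population).
#' @export
haplotype_inventory <- function(phase, include = c("all", "parents",
                                                   "offspring")) {
  include <- match.arg(include)
  info <- phase$info
  keep <- switch(include,
                 all = info$id,
                 parents = info$id[!info$is_offspring],
                 offspring = info$id[info$is_offspring])
  rows <- list()
  unresolved <- stats::setNames(rep(0L, length(unique(info$population))),
                                sort(unique(info$population)))
  for (id in keep) {
    pop <- info$population[info$id == id]
    for (h in list(phase$hap_a[, id], phase$hap_b[, id])) {
      hs <- hap_string(h)
      if (is.na(hs)) {
        unresolved[pop] <- unresolved[pop] + 1L
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          population = pop, haplotype = hs)
      }
    }
  }
  tab <- if (length(rows)) {
    dplyr::count(dplyr::bind_rows(rows), .data$population, .data$haplotype,
                 name = "n_copies")
  } else {
    tibble::tibble(population = character(), haplotype = character(),
                   n_copies = integer())
  }
  totals <- tab |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n_distinct = dplyr::n(),
                     n_copies = sum(.data$n_copies), .groups = "drop")
  totals$n_unresolved <- as.integer(unresolved[match(totals$population,
                                                     names(unresolved))])
  structure(tab, totals = totals, class = c("mhc_inventory", class(tab)))
}

#' Haplotypes shared between two populations
#'
#' Exact intersection of the fully resolved haplotype sets.
#'
#' @param inventory An `mhc_inventory` from [haplotype_inventory()].
#' @param pop_a,pop_b Population labels.
#' @return Character vector of shared haplotype strings (possibly empty).
#' @export
shared_haplotypes <- function(inventory, pop_a, pop_b) {
  ha <- inventory$haplotype[inventory$population == pop_a]
  hb <- inventory$haplotype[inventory$population == pop_b]
  sort(intersect(ha, hb))
}
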