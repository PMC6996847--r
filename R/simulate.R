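#' Configuration for the forward pedigree simulator
#'
#' Defaults mirror the study design the package targets: three horse
#' populations with 49/16/19 founder dams, 8/4/4 founder sires and 43/12/15
#' offspring; per-locus founder allele counts equal to the allele numbers
#' observed in the combined study population (5 to 14 per locus); a small
#' founder-haplotype sharing fraction between the two related populations;
#' and per-meiosis event rates on the order of the study's observed
#' frequencies (crossover ~0.8% per map interval, conversion 1.5% per
#' meiosis, stepwise indel 1.75% per locus per meiosis). Events are planted
#' independently per meiosis (no interference model).
#'
#' @param panel An [mhc_panel()].
#' @param populations Tibble `name`, `n_dams`, `n_sires`, `n_offspring`.
#' @param allele_counts Named integer vector (per panel locus) of founder
#'   allele counts, each in `[2, pool size]`; default 5-14 per locus.
#' @param pool_size Named integer vector of founder haplotype pool sizes per
#'   population; default `2 * (n_dams + n_sires)`.
#' @param sharing Tibble `pop_a`, `pop_b`, `fraction`: fraction of the
#'   second population's founder pool copied from the first.
#' @param crossover_prob Per-interval crossover probability per meiosis
#'   (scalar or length `L - 1`).
#' @param conversion_prob Per-meiosis probability of one 1-2 locus internal
#'   conversion tract.
#' @param indel_prob Per-locus per-meiosis probability of a +/-1 repeat-unit
#'   shift.
#' @param seed Default base seed used by [simulate_mhc()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(panel = default_panel(),
                       populations = NULL,
                       allele_counts = NULL,
                       pool_size = NULL,
                       sharing = NULL,
                       crossover_prob = 0.008,
                       conversion_prob = 0.015,
                       indel_prob = 0.0175,
                       seed = 1L) {
  if (is.null(populations)) {
    populations <- tibble::tibble(
      name = c("Pop1", "Pop2", "Pop3"),
      n_dams = c(49L, 16L, 19L),
      n_sires = c(8L, 4L, 4L),
      n_offspring = c(43L, 12L, 15L)
    )
  }
  populations <- tibble::as_tibble(populations)
  if (is.null(allele_counts)) {
    allele_counts <- stats::setNames(
      c(12L, 5L, 10L, 13L, 10L, 7L, 11L, 10L, 14L, 14L, 8L)[
        seq_len(nrow(panel))],
      panel$locus)
  }
  if (length(allele_counts) == 1L && is.null(names(allele_counts))) {
    allele_counts <- stats::setNames(rep(as.integer(allele_counts),
                                         nrow(panel)), panel$locus)
  }
  if (is.null(pool_size)) {
    pool_size <- stats::setNames(
      2L * (populations$n_dams + populations$n_sires), populations$name)
  }
  if (is.null(sharing)) {
    sharing <- if (all(c("Pop2", "Pop3") %in% populations$name)) {
      tibble::tibble(pop_a = "Pop2", pop_b = "Pop3", fraction = 0.08)
    } else {
      tibble::tibble(pop_a = character(), pop_b = character(),
                     fraction = numeric())
    }
  }
  L <- nrow(panel)
  if (length(crossover_prob) == 1L) {
    crossover_prob <- rep(crossover_prob, L - 1L)
  }
  stopifnot(length(crossover_prob) == L - 1L,
            all(crossover_prob >= 0 & crossover_prob <= 1),
            conversion_prob >= 0, conversion_prob <= 1,
            indel_prob >= 0, indel_prob <= 1,
            all(allele_counts >= 2L),
            all(populations$n_dams + populations$n_sires >= 1L))
  if (any(pool_size[populations$name] < 2L)) {
    stop("founder haplotype pool must hold at least 2 haplotypes",
         call. = FALSE)
  }
  structure(
    list(panel = panel, populations = populations,
         allele_counts = allele_counts, pool_size = pool_size,
         sharing = sharing, crossover_prob = crossover_prob,
         conversion_prob = conversion_prob, indel_prob = indel_prob,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Sample founder haplotype pools and founder individuals
#'
#' Per locus, allele sizes are a contiguous block on the `repeat_unit`
#' lattice inside the locus size range (so a stepwise indel usually lands on
#' an existing allele, as in the study, where no indel produced a new
#' allele), with Dirichlet-distributed frequencies. Each population gets a
#' finite founder haplotype pool (every configured allele represented at
#' least once, the rest drawn from the allele frequencies), cross-population
#' sharing is applied, and every founder receives two pool haplotypes drawn
#' independently and uniformly — i.e. under Hardy-Weinberg equilibrium.
#' Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default from config).
#' @return List with `pools` (per population, an `L x pool_size` matrix),
#'   `founders` (tibble `id`, `population`, `role`), `founder_haps` (list of
#'   `L x 2` matrices keyed by founder id).
#' @export
sample_founders <- function(config, seed = config$seed) {
  panel <- config$panel
  L <- nrow(panel)
  with_local_seed(substream_seed(seed, 0L), {
    allele_sets <- lapply(seq_len(L), function(l) {
      k <- config$allele_counts[[panel$locus[l]]]
      ru <- panel$repeat_unit[l]
      lo <- panel$size_min[l]
      hi <- panel$size_max[l]
      if (is.na(lo)) lo <- 100L
      if (is.na(hi)) hi <- lo + ru * (k + 6L)
      n_slots <- (hi - lo) %/% ru + 1L
      if (n_slots < k + 2L) stop("size range too narrow at ", panel$locus[l])
      start <- sample.int(n_slots - k - 1L, 1L)  # keep 1-slot margins
      lo + ru * (start + 0:(k - 1L))
    })
    freqs <- lapply(allele_sets, function(a) {
      w <- stats::rgamma(length(a), 1)
      w / sum(w)
    })
    pools <- list()
    for (p in config$populations$name) {
      np <- config$pool_size[[p]]
      pool <- matrix(NA_integer_, L, np)
      for (l in seq_len(L)) {
        k <- length(allele_sets[[l]])
        first <- sample(allele_sets[[l]], min(k, np))
        rest <- if (np > k) {
          sample(allele_sets[[l]], np - k, replace = TRUE,
                 prob = freqs[[l]])
        } else integer(0)
        pool[l, ] <- sample(c(first, rest))  # shuffle column assignment
      }
      pools[[p]] <- pool
    }
    if (nrow(config$sharing)) {
      for (i in seq_len(nrow(config$sharing))) {
        a <- config$sharing$pop_a[i]
        b <- config$sharing$pop_b[i]
        frac <- config$sharing$fraction[i]
        n_share <- round(frac * min(ncol(pools[[a]]), ncol(pools[[b]])))
        if (n_share > 0) {
          src <- sample(ncol(pools[[a]]), n_share)
          dst <- ncol(pools[[b]]) - seq_len(n_share) + 1L
          pools[[b]][, dst] <- pools[[a]][, src]
        }
      }
    }
    founders <- list()
    founder_haps <- list()
    for (p in config$populations$name) {
      row <- config$populations[config$populations$name == p, ]
      ids <- c(sprintf("%s_D%02d", p, seq_len(row$n_dams)),
               sprintf("%s_S%02d", p, seq_len(row$n_sires)))
      roles <- c(rep("dam", row$n_dams), rep("sire", row$n_sires))
      founders[[p]] <- tibble::tibble(id = ids, population = p, role = roles)
      for (id in ids) {
        picks <- sample(ncol(pools[[p]]), 2L, replace = TRUE)
        founder_haps[[id]] <- pools[[p]][, picks, drop = FALSE]
      }
    }
    list(pools = pools, founders = dplyr::bind_rows(founders),
         founder_haps = founder_haps)
  })
}

#' Simulate one meiosis from a phased parent
#'
#' Picks a start haplotype by fair coin, switches between the homologs at
#' each map interval with the configured crossover probability, then with
#' `conversion_prob` copies a 1-2 locus internal tract from the homolog and
#' with `indel_prob` per locus shifts the transmitted allele by one
#' `repeat_unit` (direction random, reflected at the locus size range).
#' Uses the current RNG state; [simulate_mhc()] wraps it in per-meiosis
#' substreams.
#'
#' @param haps `L x 2` integer matrix, the parent's two haplotypes.
#' @param config A [sim_config()].
#' @return List `hap` (transmitted integer vector), `events` (tibble `type`,
#'   `interval_left`, `interval_right`, `loci`, `m`), `start_hap`.
#' @export
simulate_meiosis <- function(haps, config) {
  panel <- config$panel
  L <- nrow(panel)
  start <- sample(2L, 1L)
  switches <- stats::runif(L - 1L) < config$crossover_prob
  src <- (cumsum(c(start - 1L, switches)) %% 2L) + 1L
  hap <- haps[cbind(seq_len(L), src)]
  events <- list()
  for (i in which(switches)) {
    events[[length(events) + 1L]] <- tibble::tibble(
      type = "crossover", interval_left = panel$locus[i],
      interval_right = panel$locus[i + 1L], loci = NA_character_,
      m = NA_integer_)
  }
  if (stats::runif(1) < config$conversion_prob && L >= 4L) {
    len <- sample(2L, 1L)
    start_pos <- sample(seq(2L, L - len), 1L)
    tract <- start_pos:(start_pos + len - 1L)
    hap[tract] <- haps[cbind(tract, 3L - src[tract])]
    events[[length(events) + 1L]] <- tibble::tibble(
      type = "conversion", interval_left = NA_character_,
      interval_right = NA_character_,
      loci = paste(panel$locus[tract], collapse = ","), m = NA_integer_)
  }
  indels <- which(stats::runif(L) < config$indel_prob)
  for (l in indels) {
    ru <- panel$repeat_unit[l]
    m <- sample(c(-1L, 1L), 1L)
    newa <- hap[l] + m * ru
    if (!is.na(panel$size_min[l]) && newa < panel$size_min[l]) {
      m <- 1L
      newa <- hap[l] + ru
    }
    if (!is.na(panel$size_max[l]) && newa > panel$size_max[l]) {
      m <- -1L
      newa <- hap[l] - ru
    }
    hap[l] <- newa
    events[[length(events) + 1L]] <- tibble::tibble(
      type = if (m > 0) "insertion" else "deletion",
      interval_left = NA_character_, interval_right = NA_character_,
      loci = panel$locus[l], m = m)
  }
  list(hap = hap,
       events = if (length(events)) dplyr::bind_rows(events) else
         tibble::tibble(type = character(), interval_left = character(),
                        interval_right = character(), loci = character(),
                        m = integer()),
       start_hap = start)
}

#' Simulate a pedigreed multi-population dataset with a truth log
#'
#' Builds founder pools and founders via [sample_founders()], then creates
#' each offspring from one dam meiosis and one sire meiosis
#' ([simulate_meiosis()]). Dams are assigned without replacement where
#' possible (at most one offspring per dam, as in a single breeding
#' season), sires with replacement. Every meiosis runs in its own
#' counter-based RNG substream, so adding offspring does not perturb
#' earlier draws, and the whole dataset is reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer base seed (default from config).
#' @return Object of class `mhc_sim`: list with `data` (an [mhc_data()]
#'   with pedigree), `truth` (tibble, one row per meiosis: `offspring`,
#'   `parent`, `parent_sex`, `population`, `start_hap`, list-columns
#'   `events` and `transmitted`), `founder_haps`, `pools`, `config`,
#'   `seed`.
#' @export
simulate_mhc <- function(config = sim_config(), seed = config$seed) {
  fd <- sample_founders(config, seed)
  panel <- config$panel
  truth <- list()
  geno_rows <- list()
  ped_rows <- list()
  counter <- 0L
  for (id in fd$founders$id) {
    h <- fd$founder_haps[[id]]
    geno_rows[[id]] <- tibble::tibble(
      id = id, population = fd$founders$population[fd$founders$id == id],
      locus = panel$locus, a1 = h[, 1], a2 = h[, 2])
  }
  for (p in config$populations$name) {
    row <- config$populations[config$populations$name == p, ]
    if (row$n_offspring == 0L) next
    dams <- fd$founders$id[fd$founders$population == p &
                             fd$founders$role == "dam"]
    sires <- fd$founders$id[fd$founders$population == p &
                              fd$founders$role == "sire"]
    # prefix-stable assignment: a full dam permutation (cycled when there
    # are more offspring than dams) and sequential sire draws, so adding
    # offspring never changes who the earlier offspring descend from
    assign <- with_local_seed(
      substream_seed(seed, 1000000L + match(p, config$populations$name)), {
        dam_perm <- sample(dams)
        list(
          dams = dam_perm[((seq_len(row$n_offspring) - 1L) %%
                             length(dams)) + 1L],
          sires = sires[sample.int(length(sires), row$n_offspring,
                                   replace = TRUE)]
        )
      })
    for (j in seq_len(row$n_offspring)) {
      oid <- sprintf("%s_F%03d", p, j)
      dam <- assign$dams[j]
      sire <- assign$sires[j]
      mm <- with_local_seed(substream_seed(seed, counter <- counter + 1L),
                            simulate_meiosis(fd$founder_haps[[dam]], config))
      pm <- with_local_seed(substream_seed(seed, counter <- counter + 1L),
                            simulate_meiosis(fd$founder_haps[[sire]], config))
      geno_rows[[oid]] <- tibble::tibble(
        id = oid, population = p, locus = panel$locus,
        a1 = mm$hap, a2 = pm$hap)
      ped_rows[[oid]] <- tibble::tibble(id = oid, sire = sire, dam = dam)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        offspring = oid, parent = dam, parent_sex = "dam", population = p,
        start_hap = mm$start_hap, events = list(mm$events),
        transmitted = list(mm$hap))
      truth[[length(truth) + 1L]] <- tibble::tibble(
        offspring = oid, parent = sire, parent_sex = "sire", population = p,
        start_hap = pm$start_hap, events = list(pm$events),
        transmitted = list(pm$hap))
    }
  }
  data <- mhc_data(dplyr::bind_rows(geno_rows), panel = panel)
  if (length(ped_rows)) {
    data <- attach_pedigree(data, dplyr::bind_rows(ped_rows))
  }
  structure(
    list(data = data,
         truth = dplyr::bind_rows(truth),
         founder_haps = fd$founder_haps, pools = fd$pools,
         config = config, seed = as.integer(seed)),
    class = "mhc_sim"
  )
}

#' @export
print.mhc_sim <- function(x, ...) {
  cat("<mhc_sim> seed", x$seed, "\n")
  print(x$data)
  n_ev <- sum(vapply(x$truth$events, nrow, integer(1)))
  cat("  meioses:", nrow(x$truth), " planted events:", n_ev, "\n")
  invisible(x)
}

#' Replay the truth log
#'
#' Reconstructs every offspring genotype from the logged founder
#' haplotypes, start haplotypes and planted events, and compares with the
#' simulated genotypes. Used to prove the truth log is exhaustive and
#' exact.
#'
#' @param sim An `mhc_sim`.
#' @return `TRUE` if every offspring genotype is reproduced exactly,
#'   otherwise an error describing the first discrepancy.
#' @export
replay_truth <- function(sim) {
  panel <- sim$config$panel
  L <- nrow(panel)
  gm <- genotype_matrices(sim$data)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    haps <- sim$founder_haps[[tr$parent]]
    src <- rep(tr$start_hap, L)
    ev <- tr$events[[1]]
    for (j in seq_len(nrow(ev))) {
      if (ev$type[j] == "crossover") {
        pos <- match(ev$interval_right[j], panel$locus)
        src[pos:L] <- 3L - src[pos:L]
      }
    }
    hap <- haps[cbind(seq_len(L), src)]
    for (j in seq_len(nrow(ev))) {
      if (ev$type[j] == "conversion") {
        tract <- match(strsplit(ev$loci[j], ",")[[1]], panel$locus)
        hap[tract] <- haps[cbind(tract, 3L - src[tract])]
      } else if (ev$type[j] %in% c("insertion", "deletion")) {
        l <- match(ev$loci[j], panel$locus)
        hap[l] <- hap[l] + ev$m[j] * panel$repeat_unit[l]
      }
    }
    if (!identical(as.integer(hap), as.integer(tr$transmitted[[1]]))) {
      stop("replay mismatch for ", tr$offspring, "/", tr$parent_sex)
    }
  }
  # genotypes are stored with canonicalized (sorted) pairs: compare as sets
  for (oid in unique(sim$truth$offspring)) {
    tr <- sim$truth[sim$truth$offspring == oid, ]
    hm <- tr$transmitted[[which(tr$parent_sex == "dam")]]
    hp <- tr$transmitted[[which(tr$parent_sex == "sire")]]
    og <- gm[[oid]]
    want <- cbind(pmin(hm, hp), pmax(hm, hp))
    if (!identical(as.integer(og), as.integer(want))) {
      stop("genotype mismatch for offspring ", oid)
    }
  }
  TRUE
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genotypes.csv` (wide), `pedigree.csv`, `panel.json` and
#' `truth.json` under `dir`.
#'
#' @param sim An `mhc_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim$config$panel
  g <- sim$data$genotypes
  wide <- tidyr::pivot_wider(
    g, id_cols = c("id", "population"), names_from = "locus",
    values_from = c("a1", "a2"), names_glue = "{locus}.{ifelse(.value=='a1',1,2)}")
  ord <- c("id", "population",
           as.vector(rbind(paste0(panel$locus, ".1"),
                           paste0(panel$locus, ".2"))))
  readr::write_csv(wide[, ord], file.path(dir, "genotypes.csv"))
  readr::write_csv(sim$data$pedigree, file.path(dir, "pedigree.csv"))
  write_panel(panel, file.path(dir, "panel.json"))
  truth <- sim$truth
  truth$transmitted <- lapply(truth$transmitted, as.integer)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       na = "null")
  invisible(dir)
}
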