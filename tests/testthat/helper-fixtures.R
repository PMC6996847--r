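# small panels and datasets built in code ------------------------------------

tiny_panel <- function(n = 2, ru = 2L) {
  mhc_panel(tibble::tibble(
    locus = paste0("L", seq_len(n)), mhc_class = "II",
    map_index = seq_len(n), repeat_unit = ru,
    size_min = 100L, size_max = 200L
  ))
}

# wide genotype tibble -> mhc_data over tiny panel
tiny_data <- function(wide, panel = NULL) {
  if (is.null(panel)) {
    loci <- unique(sub("\\.[12]$", "",
                       setdiff(names(wide), c("id", "population"))))
    panel <- mhc_panel(tibble::tibble(locus = loci, mhc_class = "II",
                                      map_index = seq_along(loci),
                                      size_min = 50L, size_max = 400L))
  }
  mhc_data(wide, panel = panel)
}

# wide-range panel + high-diversity single population, used where event
# detectability must be near-complete (many offspring per parent)
informative_config <- function(n_offspring, n_dams = 100L, n_sires = 20L,
                               crossover_prob = 0, conversion_prob = 0,
                               indel_prob = 0, seed = 1L) {
  pan <- default_panel()
  pan$size_min <- 100L
  pan$size_max <- 180L
  sim_config(
    panel = pan,
    populations = tibble::tibble(name = "SimPop", n_dams = n_dams,
                                 n_sires = n_sires,
                                 n_offspring = as.integer(n_offspring)),
    allele_counts = 14L,
    pool_size = c(SimPop = 240L),
    sharing = tibble::tibble(pop_a = character(), pop_b = character(),
                             fraction = numeric()),
    crossover_prob = crossover_prob, conversion_prob = conversion_prob,
    indel_prob = indel_prob, seed = seed
  )
}

# independent oracle: exact HWE probability test for 2 alleles ---------------
# enumerates heterozygote counts directly from the closed-form conditional
# probability, independently of the package's general table recursion
oracle_hwe_2allele <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  m1 <- 2 * n11 + n12
  m2 <- 2 * n22 + n12
  hs <- seq(m1 %% 2, min(m1, m2), by = 2)
  logp <- vapply(hs, function(h) {
    x11 <- (m1 - h) / 2
    x22 <- (m2 - h) / 2
    lfactorial(n) + h * log(2) + lfactorial(m1) + lfactorial(m2) -
      lfactorial(x11) - lfactorial(h) - lfactorial(x22) -
      lfactorial(2 * n)
  }, numeric(1))
  obs <- logp[hs == n12]
  min(1, sum(exp(logp)[logp <= obs + 1e-9]))
}

# independent oracle: exhaustive minimum-cost transmission explanation ------
# enumerates every (start haplotype, breakpoint set of <= 3, optional single
# conversion tract or indel) explanation and returns the minimal cost
# (2 per breakpoint + 1 per point event); Inf if nothing is valid
oracle_min_cost <- function(h1, h2, t_hap, panel, max_bp = 3L,
                            max_units = 3L) {
  L <- length(t_hap)
  known <- which(!is.na(t_hap) & !is.na(h1) & !is.na(h2))
  if (length(known) < 2) return(NA_real_)  # skipped
  gaps <- seq_len(L - 1)
  bp_sets <- list(integer(0))
  for (k in seq_len(min(max_bp, length(gaps)))) {
    bp_sets <- c(bp_sets, utils::combn(gaps, k, simplify = FALSE))
  }
  informative <- h1 != h2
  best <- Inf
  for (start in 1:2) {
    for (B in bp_sets) {
      src <- (cumsum(c(start - 1L, as.integer(gaps %in% B))) %% 2L) + 1L
      base_cost <- 2 * length(B)
      if (base_cost >= best) next
      hs <- ifelse(src == 1L, h1, h2)
      mism <- known[t_hap[known] != hs[known]]
      if (length(mism) == 0) {
        best <- min(best, base_cost)
        next
      }
      # one point event allowed
      if (base_cost + 1 >= best) next
      # indel at the single mismatching known locus; an indel must match
      # NEITHER parental allele and sit a repeat-unit multiple away from
      # the mosaic-source allele
      if (length(mism) == 1) {
        l <- mism
        d <- t_hap[l] - hs[l]
        ru <- panel$repeat_unit[l]
        if (t_hap[l] != h1[l] && t_hap[l] != h2[l] &&
            d %% ru == 0 && d != 0 && abs(d %/% ru) <= max_units) {
          best <- min(best, base_cost + 1)
        }
      }
      # conversion tract of 1-2 panel loci, flanked by informative known
      # context both sides, no breakpoint touching the tract
      for (i in 2:(L - 1)) {
        for (len in 1:2) {
          j <- i + len - 1L
          if (j > L - 1L) next
          if (any(B %in% (i - 1L):j)) next
          left_known <- known[known < i]
          right_known <- known[known > j]
          if (!any(informative[left_known]) ||
              !any(informative[right_known])) next
          s2 <- src
          s2[i:j] <- 3L - s2[i:j]
          hs2 <- ifelse(s2 == 1L, h1, h2)
          if (all(t_hap[known] == hs2[known])) best <- min(best, base_cost + 1)
        }
      }
    }
  }
  best
}

# cost reported by the package for comparison with the oracle
pkg_cost <- function(expl) {
  switch(expl$status,
         none = 0,
         event = expl$cost,
         unexplained = Inf,
         skipped = NA_real_)
}
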