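#' Per-locus allele frequencies
#'
#' Counts both alleles of every typed individual; frequencies are counts over
#' `n_genes` = 2 x typed individuals. Individuals missing a locus are
#' excluded from that locus only (pairwise deletion).
#'
#' @param data An `mhc_data` object.
#' @param by_population Count within each population separately (`TRUE`) or
#'   pooled over the whole dataset (`FALSE`, population `"all"`).
#' @param loci Optional character vector restricting the loci.
#' @return Tibble `population`, `locus`, `allele`, `count`, `freq`,
#'   `n_genes`.
#' @export
allele_freqs <- function(data, by_population = FALSE, loci = NULL) {
  g <- data$genotypes
  if (!is.null(loci)) g <- g[g$locus %in% loci, ]
  if (!by_population) g$population <- "all"
  g <- g[!is.na(g$a1), ]
  long <- tibble::tibble(
    population = rep(g$population, 2L),
    locus = rep(g$locus, 2L),
    allele = c(g$a1, g$a2)
  )
  out <- long |>
    dplyr::count(.data$population, .data$locus, .data$allele,
                 name = "count") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(n_genes = sum(.data$count),
                  freq = .data$count / .data$n_genes) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$population,
                   match(.data$locus, data$panel$locus), .data$allele)
  out[, c("population", "locus", "allele", "count", "freq", "n_genes")]
}

#' Unbiased expected heterozygosity (gene diversity)
#'
#' Nei's small-sample corrected estimator
#' `He = n_genes/(n_genes - 1) * (1 - sum(p^2))`.
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @param n_genes Number of sampled gene copies (2 x typed individuals).
#' @return He in `[0, 1]`; `NA` with a warning when `n_genes < 2`.
#' @export
expected_het <- function(p, n_genes) {
  if (n_genes < 2) {
    warning("expected heterozygosity undefined for fewer than 2 genes")
    return(NA_real_)
  }
  n_genes / (n_genes - 1) * (1 - sum(p^2))
}

#' Polymorphism information content
#'
#' Botstein's marker informativeness index
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, always `<= He`.
#'
#' @param p Numeric vector of allele frequencies.
#' @return PIC in `[0, 1]`.
#' @export
pic_index <- function(p) {
  pic_botstein(p)
}

pic_botstein <- function(p) {
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Within-population inbreeding coefficient from Ho and He
#'
#' Heterozygote deficit relative to Hardy-Weinberg expectation, in the simple
#' ratio form `Fis = 1 - Ho/He`. This is the form the package reports by
#' default; a small-sample corrected alternative is available from
#' [locus_stats()].
#'
#' @param ho Observed heterozygosity.
#' @param he Expected heterozygosity; must be `> 0`.
#' @return Fis in `[-1, 1]`; `NA` with a warning when `he = 0`.
#' @export
fis <- function(ho, he) {
  out <- 1 - ho / he
  if (any(he == 0, na.rm = TRUE)) {
    warning("Fis undefined where He = 0")
    out[he == 0] <- NA_real_
  }
  out
}

#' Chakraborty null-allele frequency estimate
#'
#' `r = (He - Ho)/(He + Ho)`; negative values indicate heterozygote excess.
#'
#' @param ho Observed heterozygosity.
#' @param he Expected heterozygosity.
#' @return Estimated null-allele frequency; `NA` with a warning when
#'   `Ho + He = 0`.
#' @export
null_allele_freq <- function(ho, he) {
  out <- (he - ho) / (he + ho)
  if (any(ho + he == 0, na.rm = TRUE)) {
    warning("null-allele frequency undefined where Ho + He = 0")
    out[ho + he == 0] <- NA_real_
  }
  out
}

#' Rarefacted allelic richness
#'
#' Expected number of distinct alleles in a hypergeometric subsample of `g`
#' gene copies: `AR = sum_a (1 - choose(N - N_a, g)/choose(N, g))` with `N`
#' sampled genes and `N_a` the count of allele `a`. At `g = N` this is the
#' raw allele count.
#'
#' @param counts Integer vector of allele counts at the locus.
#' @param g Rarefaction size in gene copies, `1 <= g <= sum(counts)`.
#' @return Expected allele count, a real `>= 1`.
#' @export
allelic_richness <- function(counts, g) {
  n <- sum(counts)
  if (g > n || g < 1) {
    stop("rarefaction size g must be in [1, total gene count]",
         call. = FALSE)
  }
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

# Nei & Chesser (1983) small-sample Fis: 1 - Ho/Hs with
# Hs = n/(n-1) * (1 - sum p^2 - Ho/(2n)), n individuals.
fis_corrected <- function(ho, p, n_ind) {
  if (n_ind < 2) return(NA_real_)
  hs <- n_ind / (n_ind - 1) * (1 - sum(p^2) - ho / (2 * n_ind))
  if (hs <= 0) return(NA_real_)
  1 - ho / hs
}

#' Per-locus diversity statistics table
#'
#' The standard microsatellite characterization panel, per locus and
#' (optionally) per population: typed individuals, allele count, observed and
#' unbiased expected heterozygosity, PIC, Fis (ratio form `1 - Ho/He` and the
#' Nei-Chesser small-sample corrected form), rarefacted allelic richness,
#' effective allele number, Chakraborty null-allele frequency and the exact
#' Hardy-Weinberg test p-value.
#'
#' @param data An `mhc_data` object.
#' @param by_population Compute within populations (`TRUE`) or pooled
#'   (`FALSE`).
#' @param g Rarefaction size in gene copies for allelic richness. Default:
#'   per locus, the minimum gene count across the populations being compared
#'   (so the smallest population's AR is its raw allele count); when pooled,
#'   the locus's own gene count (no rarefaction).
#' @param hwe Run the Hardy-Weinberg exact test per locus (see
#'   [hwe_exact_test()]).
#' @param n_mc Monte-Carlo shuffles for the HWE test when full enumeration is
#'   infeasible.
#' @param seed Seed for the HWE Monte-Carlo test.
#' @return Tibble with one row per population x locus.
#' @export
locus_stats <- function(data, by_population = FALSE, g = NULL,
                        hwe = TRUE, n_mc = 1e4, seed = 1L) {
  freqs <- allele_freqs(data, by_population = by_population)
  geno <- data$genotypes
  if (!by_population) geno$population <- "all"
  g_default <- freqs |>
    dplyr::distinct(.data$population, .data$locus, .data$n_genes) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(g_min = min(.data$n_genes), .groups = "drop")
  combos <- unique(freqs[, c("population", "locus")])
  rows <- purrr::pmap(combos, function(population, locus) {
    f <- freqs[freqs$population == population & freqs$locus == locus, ]
    gg <- geno[geno$population == population & geno$locus == locus &
                 !is.na(geno$a1), ]
    n_typed <- nrow(gg)
    n_genes <- f$n_genes[1]
    p <- f$freq
    ho <- mean(gg$a1 != gg$a2)
    he <- expected_het(p, n_genes)
    g_use <- if (is.null(g)) g_default$g_min[g_default$locus == locus] else g
    g_use <- min(g_use, n_genes)
    hw <- if (hwe) {
      hwe_exact_test(gg$a1, gg$a2, n_mc = n_mc,
                     seed = seed + match(locus, data$panel$locus))
    } else {
      list(p = NA_real_, testable = NA, method = NA_character_)
    }
    tibble::tibble(
      population = population, locus = locus,
      n_typed = n_typed, n_alleles = nrow(f),
      ho = ho, he = he,
      pic = pic_botstein(p),
      fis = if (!is.na(he) && he > 0) 1 - ho / he else NA_real_,
      fis_corrected = fis_corrected(ho, p, n_typed),
      ar = allelic_richness(f$count, g_use), ar_g = g_use,
      ne = 1 / sum(p^2),
      null_freq = if (ho + he > 0) (he - ho) / (he + ho) else NA_real_,
      hwe_p = hw$p, hwe_testable = hw$testable, hwe_method = hw$method
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$population, match(out$locus, data$panel$locus)), ]
}

#' Per-population allelic pattern summary
#'
#' Mean over loci of the allele count (Na), effective allele number
#' (Ne = 1/sum(p^2)), private allele count (Np: alleles observed in exactly
#' one population) and observed/unbiased expected heterozygosity.
#'
#' @param data An `mhc_data` object with at least one typed locus.
#' @return Tibble `population`, `na`, `ne`, `np`, `ho`, `he` (means over
#'   loci). `np` is `NA` with a warning when the dataset holds a single
#'   population.
#' @export
population_summary <- function(data) {
  freqs <- allele_freqs(data, by_population = TRUE)
  pops <- unique(freqs$population)
  # private alleles: seen in exactly one population (per locus)
  priv <- freqs |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::mutate(n_pops_with = dplyr::n()) |>
    dplyr::ungroup()
  single_pop <- length(pops) < 2
  if (single_pop) warning("private alleles undefined for a single population")
  st <- locus_stats(data, by_population = TRUE, hwe = FALSE)
  per_pop <- st |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(na = mean(.data$n_alleles), ne = mean(.data$ne),
                     ho = mean(.data$ho), he = mean(.data$he),
                     .groups = "drop")
  np <- priv |>
    dplyr::filter(.data$n_pops_with == 1L) |>
    dplyr::count(.data$population, .data$locus) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(np_total = sum(.data$n), .groups = "drop")
  n_loci <- nrow(data$panel)
  per_pop$np <- if (single_pop) NA_real_ else {
    v <- np$np_total[match(per_pop$population, np$population)]
    v[is.na(v)] <- 0
    v / n_loci
  }
  per_pop[, c("population", "na", "ne", "np", "ho", "he")]
}

#' Chi-square test of allele-frequency homogeneity across populations
#'
#' Pearson chi-square on the populations x alleles gene-count table at each
#' locus, with a Bonferroni correction over the number of loci tested
#' (`p_bonferroni = min(1, p * m)`).
#'
#' @param data An `mhc_data` object with `>= 2` populations.
#' @param loci Loci to test (default: the whole panel).
#' @param m Bonferroni family size; defaults to the number of loci tested.
#' @return Tibble `locus`, `chi2`, `df`, `p`, `p_bonferroni`.
#' @export
allele_homogeneity_test <- function(data, loci = NULL, m = NULL) {
  if (is.null(loci)) loci <- data$panel$locus
  if (is.null(m)) m <- length(loci)
  freqs <- allele_freqs(data, by_population = TRUE, loci = loci)
  rows <- lapply(loci, function(lc) {
    f <- freqs[freqs$locus == lc, ]
    pops <- unique(f$population)
    typed <- f |>
      dplyr::distinct(.data$population, .data$n_genes)
    drop <- typed$population[typed$n_genes == 0]
    if (length(drop)) {
      warning("population(s) with no typed genes at ", lc, " excluded: ",
              paste(drop, collapse = ", "))
      f <- f[!f$population %in% drop, ]
      pops <- setdiff(pops, drop)
    }
    if (length(pops) < 2) {
      stop("allele homogeneity test needs >= 2 typed populations at ", lc,
           call. = FALSE)
    }
    tab <- tidyr::pivot_wider(f[, c("population", "allele", "count")],
                              names_from = "allele", values_from = "count",
                              values_fill = 0L)
    mat <- as.matrix(tab[, -1])
    e <- outer(rowSums(mat), colSums(mat)) / sum(mat)
    chi2 <- sum((mat - e)^2 / e)
    df <- (nrow(mat) - 1L) * (ncol(mat) - 1L)
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    tibble::tibble(locus = lc, chi2 = chi2, df = df, p = p,
                   p_bonferroni = min(1, p * m))
  })
  dplyr::bind_rows(rows)
}
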