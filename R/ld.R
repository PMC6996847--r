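#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Log-likelihood-ratio (G) statistic on the genotype x genotype contingency
#' table of two loci over individuals typed at both, with the null
#' distribution obtained by permuting one locus's genotypes across
#' individuals. The p-value uses the add-one correction
#' `(hits + 1)/(n_perm + 1)`.
#'
#' @param gA,gB Character or integer vectors of genotype labels (one entry
#'   per individual; `NA` for untyped). Use [ld_test()] for a whole dataset.
#' @param n_perm Number of permutations.
#' @param seed Seed (local to this call).
#' @return List `p`, `g_stat`, `testable` (`FALSE`, with `p = 1`, when
#'   either locus is monomorphic in the tested pool).
#' @export
ld_pair_test <- function(gA, gB, n_perm = 999, seed = 1L) {
  keep <- !is.na(gA) & !is.na(gB)
  gA <- gA[keep]
  gB <- gB[keep]
  if (length(unique(gA)) < 2 || length(unique(gB)) < 2) {
    return(list(p = 1, g_stat = NA_real_, testable = FALSE))
  }
  g_obs <- g_statistic(gA, gB)
  hits <- with_local_seed(seed, {
    h <- 0L
    for (i in seq_len(n_perm)) {
      if (g_statistic(gA, sample(gB)) >= g_obs - 1e-12) h <- h + 1L
    }
    h
  })
  list(p = (hits + 1) / (n_perm + 1), g_stat = g_obs, testable = TRUE)
}

g_statistic <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab)
  e <- as.numeric(e)
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

#' Linkage-disequilibrium tests for all locus pairs
#'
#' @param data An `mhc_data` object.
#' @param population Optional population label restricting the pool
#'   (default: all individuals).
#' @param n_perm Permutations per pair.
#' @param seed Base seed; each pair gets a deterministic substream.
#' @return Tibble `locus_a`, `locus_b`, `g_stat`, `p`, `testable`.
#' @export
ld_test <- function(data, population = NULL, n_perm = 999, seed = 1L) {
  g <- data$genotypes
  if (!is.null(population)) g <- g[g$population %in% population, ]
  ids <- unique(g$id)
  loci <- data$panel$locus
  lab <- function(lc) {
    gi <- g[g$locus == lc, ]
    gi <- gi[match(ids, gi$id), ]
    ifelse(is.na(gi$a1), NA, paste(gi$a1, gi$a2, sep = "/"))
  }
  labs <- lapply(loci, lab)
  names(labs) <- loci
  pairs <- utils::combn(loci, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    res <- ld_pair_test(labs[[a]], labs[[b]], n_perm = n_perm,
                        seed = substream_seed(seed, j))
    tibble::tibble(locus_a = a, locus_b = b, g_stat = res$g_stat,
                   p = res$p, testable = res$testable)
  })
  dplyr::bind_rows(rows)
}
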