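#' Exact test of Hardy-Weinberg equilibrium
#'
#' Guo & Thompson probability test conditional on allele counts: each
#' genotype-count table with the observed allele margins has conditional
#' probability
#' `P = n! * 2^h * prod(m_a!) / (prod(n_gg!) * (2n)!)`
#' (`n` individuals, `h` heterozygotes, `m_a` allele counts, `n_gg` genotype
#' counts), and the p-value is the total probability of tables no more
#' probable than the observed one. Tables are fully enumerated when the
#' table space has at most `max_tables` members; otherwise the distribution
#' is sampled by `n_mc` random shuffles of the gene vector.
#'
#' @param a1,a2 Integer vectors, the two alleles of each typed individual.
#' @param n_mc Number of Monte-Carlo shuffles for large table spaces.
#' @param max_tables Enumeration cap; above it Monte-Carlo is used.
#' @param seed Seed for the Monte-Carlo path (local to this call).
#' @return List with `p`, `testable` (`FALSE` for monomorphic loci, which
#'   return `p = 1` rather than `NA` so tabulations keep the row), `method`
#'   (`"enumeration"` or `"mc"`) and `p_obs` (probability of the observed
#'   table).
#' @export
#' @examples
#' # two individuals AA and BB: only tables are h = 0 (prob 1/3) and
#' # h = 2 (prob 2/3), so the probability test gives p = 1/3
#' hwe_exact_test(c(1L, 2L), c(1L, 2L))$p
hwe_exact_test <- function(a1, a2, n_mc = 1e4, max_tables = 1e5,
                           seed = NULL) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]
  a2 <- a2[keep]
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2 || n < 2) {
    return(list(p = 1, testable = FALSE, method = "none", p_obs = 1))
  }
  i1 <- match(a1, alleles)
  i2 <- match(a2, alleles)
  m <- tabulate(c(i1, i2), nbins = k)  # allele counts
  obs <- genotype_count_matrix(i1, i2, k)
  logp_obs <- hwe_log_prob(obs, m, n)
  tol <- 1e-9
  # enumeration is attempted only when the table space is plausibly small;
  # the recursion still aborts at max_tables and falls back to Monte-Carlo
  try_enum <- max_tables > 1 &&
    (k == 2 || (k <= 4 && n <= 60) || (k <= 6 && n <= 20))
  enum <- if (try_enum) enumerate_hwe_tables(m, max_tables) else NULL
  if (!is.null(enum)) {
    logps <- vapply(enum, function(tab) hwe_log_prob(tab, m, n), numeric(1))
    p <- sum(exp(logps)[logps <= logp_obs + tol])
    return(list(p = min(1, p), testable = TRUE, method = "enumeration",
                p_obs = exp(logp_obs)))
  }
  # Monte-Carlo: shuffle the gene vector, pair consecutive copies
  genes <- c(i1, i2)
  run_mc <- function() {
    hits <- 0L
    for (it in seq_len(n_mc)) {
      g <- sample(genes)
      tab <- genotype_count_matrix(g[seq_len(n)], g[n + seq_len(n)], k)
      if (hwe_log_prob(tab, m, n) <= logp_obs + tol) hits <- hits + 1L
    }
    (hits + 1) / (n_mc + 1)
  }
  p <- if (is.null(seed)) run_mc() else with_local_seed(seed, run_mc())
  list(p = p, testable = TRUE, method = "mc", p_obs = exp(logp_obs))
}

# upper-triangular genotype counts as a k x k matrix (lower kept zero)
genotype_count_matrix <- function(i1, i2, k) {
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  matrix(tabulate((hi - 1L) * k + lo, nbins = k * k), k, k)
}

hwe_log_prob <- function(tab, m, n) {
  h <- sum(tab) - sum(diag(tab))
  lfactorial(n) + h * log(2) + sum(lfactorial(m)) -
    sum(lfactorial(tab[upper.tri(tab, diag = TRUE)])) - lfactorial(2 * n)
}

# Enumerate all genotype-count tables with allele margins m; NULL if more
# than max_tables tables exist.
enumerate_hwe_tables <- function(m, max_tables) {
  k <- length(m)
  out <- vector("list", 0L)
  count <- 0L
  overflow <- FALSE
  tab <- matrix(0L, k, k)
  # remaining margin per allele as we fill cells (a,b), a <= b, row-major
  rec <- function(a, b, rem) {
    if (overflow) return(invisible())
    if (a > k) {
      count <<- count + 1L
      if (count > max_tables) {
        overflow <<- TRUE
        return(invisible())
      }
      out[[count]] <<- tab
      return(invisible())
    }
    if (b > k) {
      if (rem[a] != 0L) return(invisible())
      rec(a + 1L, a + 1L, rem)
      return(invisible())
    }
    if (a == b) {
      top <- rem[a] %/% 2L
      for (x in 0:top) {
        tab[a, b] <<- x
        r <- rem
        r[a] <- r[a] - 2L * x
        # feasibility: remaining of allele a must fit in cells (a, b>k?) to come
        rec(a, b + 1L, r)
        if (overflow) break
      }
      tab[a, b] <<- 0L
    } else {
      top <- min(rem[a], rem[b])
      for (x in 0:top) {
        tab[a, b] <<- x
        r <- rem
        r[a] <- r[a] - x
        r[b] <- r[b] - x
        rec(a, b + 1L, r)
        if (overflow) break
      }
      tab[a, b] <<- 0L
    }
  }
  rec(1L, 1L, m)
  if (overflow) NULL else out
}

#' Hardy-Weinberg exact tests over a dataset
#'
#' Runs [hwe_exact_test()] per locus, pooled or per population.
#'
#' @inheritParams locus_stats
#' @return Tibble `population`, `locus`, `p`, `testable`, `method`.
#' @export
hwe_test <- function(data, by_population = FALSE, n_mc = 1e4, seed = 1L) {
  geno <- data$genotypes
  if (!by_population) geno$population <- "all"
  combos <- unique(geno[, c("population", "locus")])
  rows <- purrr::pmap(combos, function(population, locus) {
    gg <- geno[geno$population == population & geno$locus == locus &
                 !is.na(geno$a1), ]
    res <- hwe_exact_test(gg$a1, gg$a2, n_mc = n_mc,
                          seed = seed + match(locus, data$panel$locus))
    tibble::tibble(population = population, locus = locus, p = res$p,
                   testable = res$testable, method = res$method)
  })
  dplyr::bind_rows(rows)
}
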