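make_geno <- function(pairs, locus = "L1") {
  # pairs: list of c(a1, a2)
  wide <- tibble::tibble(
    id = sprintf("i%03d", seq_along(pairs)), population = "P",
    a = vapply(pairs, `[`, integer(1), 1),
    b = vapply(pairs, `[`, integer(1), 2)
  )
  names(wide)[3:4] <- paste0(locus, c(".1", ".2"))
  tiny_data(wide)
}

test_that("allele frequencies count both gene copies per typed individual", {
  d <- make_geno(rep(list(c(226L, 230L)), 10))
  f <- allele_freqs(d)
  expect_equal(f$freq, c(0.5, 0.5))
  expect_equal(unique(f$n_genes), 20L)
  d2 <- make_geno(list(c(226L, 226L), c(226L, 230L)))
  f2 <- allele_freqs(d2)
  expect_equal(f2$freq[f2$allele == 226], 0.75)
  expect_equal(f2$freq[f2$allele == 230], 0.25)
})

test_that("simulated founder allele frequencies match the pool's sampling
          distribution", {
  cfg <- informative_config(0, n_dams = 500L, n_sires = 0L, seed = 9)
  sim <- simulate_mhc(cfg)
  f <- allele_freqs(sim$data, loci = "COR110")
  pool <- sim$pools$SimPop
  pool_counts <- table(pool[1, ])
  pool_p <- as.numeric(pool_counts) / sum(pool_counts)
  obs <- f$count[match(as.integer(names(pool_counts)), f$allele)]
  obs[is.na(obs)] <- 0
  gof <- suppressWarnings(stats::chisq.test(obs, p = pool_p))
  expect_gt(gof$p.value, 0.001)
})

test_that("heterozygosity, PIC, Fis, null-allele and Ne kernels match hand
          arithmetic", {
  expect_equal(expected_het(c(0.5, 0.5), 20), 20 / 19 * 0.5)
  expect_equal(expected_het(1, 10), 0)           # monomorphic
  expect_equal(pic_index(1), 0)
  expect_equal(pic_index(c(0.5, 0.5)), 0.375)
  expect_equal(fis(0.5, 0.5), 0)
  expect_equal(null_allele_freq(0.5, 0.5), 0)
  expect_equal(null_allele_freq(0.4, 0.8), 1 / 3)
  d <- make_geno(rep(list(c(100L, 100L)), 5))        # all homozygous
  st <- locus_stats(d, hwe = FALSE)
  expect_equal(st$ho, 0)
  d2 <- make_geno(rep(list(c(100L, 102L)), 5))       # all heterozygous
  expect_equal(locus_stats(d2, hwe = FALSE)$ho, 1)
})

test_that("PIC never exceeds He and both stay in [0, 1]", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    p <- as.numeric(stats::rgamma(k, 1))
    p <- p / sum(p)
    n_genes <- 2 * sample(5:100, 1)
    he <- expected_het(p, n_genes)
    pic <- pic_index(p)
    expect_lte(pic, he + 1e-12)
    expect_gte(pic, 0)
    expect_lte(he, 1)
  }
})

test_that("allelic richness matches the hypergeometric enumeration", {
  # counts {A:3, B:1}, g = 2: all C(4,2)=6 subsamples contain A; B appears
  # in 3 of 6, so AR = 1 + 0.5
  expect_equal(allelic_richness(c(3, 1), 2), 1.5)
  # g = N returns the raw allele count for any configuration
  set.seed(7)
  for (i in 1:20) {
    counts <- sample(1:6, sample(2:5, 1), replace = TRUE)
    expect_equal(allelic_richness(counts, sum(counts)), length(counts))
  }
  expect_error(allelic_richness(c(3, 1), 5), "rarefaction")
})

test_that("rarefaction defaults make the smallest population's AR integer", {
  wide <- tibble::tibble(
    id = sprintf("i%02d", 1:12),
    population = rep(c("A", "B"), c(8, 4)),
    L1.1 = c(100L, 102L, 104L, 106L, 100L, 102L, 104L, 106L,
             100L, 102L, 104L, 106L),
    L1.2 = c(102L, 104L, 106L, 108L, 102L, 104L, 106L, 108L,
             102L, 104L, 106L, 100L)
  )
  d <- tiny_data(wide)
  st <- locus_stats(d, by_population = TRUE, hwe = FALSE)
  b <- st[st$population == "B", ]
  expect_equal(b$ar_g, 8L)                       # min gene count = pop B
  expect_equal(b$ar, b$n_alleles)                # its own raw allele count
  expect_equal(b$ar %% 1, 0)
})

test_that("effective and private alleles follow their definitions", {
  wide <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"), population = c("A", "A", "B", "B"),
    L1.1 = c(100L, 100L, 120L, 120L), L1.2 = c(102L, 102L, 120L, 120L)
  )
  d <- tiny_data(wide)
  ps <- population_summary(d)
  # pop A: p = (0.5, 0.5) -> Ne = 2; pop B fixed -> Ne = 1
  expect_equal(ps$ne[ps$population == "A"], 2)
  expect_equal(ps$ne[ps$population == "B"], 1)
  # disjoint allele sets: every allele private
  expect_equal(ps$np[ps$population == "A"], 2)
  expect_equal(ps$np[ps$population == "B"], 1)
  one <- tiny_data(wide[1:2, ])
  expect_warning(population_summary(one), "single population")
})

test_that("chi-square homogeneity test matches hand computation", {
  wide <- tibble::tibble(
    id = sprintf("i%02d", 1:20), population = rep(c("A", "B"), each = 10),
    L1.1 = rep(c(100L, 120L), each = 10), L1.2 = rep(c(100L, 120L), each = 10)
  )
  d <- tiny_data(wide)
  res <- allele_homogeneity_test(d, m = 1)
  # gene-count table [[20,0],[0,20]]: chi2 = 40, df = 1
  expect_equal(res$chi2, 40)
  expect_equal(res$df, 1L)
  expect_equal(res$p, stats::pchisq(40, 1, lower.tail = FALSE))
  # identical tables: chi2 = 0, p = 1
  wide2 <- wide
  wide2$L1.1 <- rep(c(100L, 120L), 10)
  wide2$L1.2 <- rep(c(100L, 120L), 10)
  res2 <- allele_homogeneity_test(tiny_data(wide2), m = 11)
  expect_equal(res2$chi2, 0)
  expect_equal(res2$p_bonferroni, 1)
})

test_that("Evanno delta-K reproduces the hand-computed example and flags", {
  # replicate sets whose means are -100, -80, -79.5, -79 with sd(K3) = 2
  # and sd(K4) = 0.5: deltaK(3) = 19.5/2, deltaK(4) = 0
  # two replicates at mean +/- x have sd = x * sqrt(2)
  x3 <- 2 / sqrt(2)
  x4 <- 0.5 / sqrt(2)
  lnp <- tibble::tibble(
    K = rep(2:5, each = 2), replicate = rep(1:2, 4),
    lnP = c(-101, -99, -80 - x3, -80 + x3, -79.5 - x4, -79.5 + x4,
            -79.5, -78.5)
  )
  res <- evanno_delta_k(lnp)
  tab <- res$table
  expect_equal(tab$delta_k[tab$K == 3], 19.5 / 2)
  expect_equal(tab$delta_k[tab$K == 4], 0)
  expect_equal(res$best_k, 3L)
  # linear lnP: all interior deltaK are 0
  lin <- tibble::tibble(K = rep(2:5, each = 2), replicate = rep(1:2, 4),
                        lnP = rep(c(-100, -90, -80, -70), each = 2) +
                          rep(c(-0.5, 0.5), 4))
  expect_true(all(evanno_delta_k(lin)$table$delta_k[2:3] == 0))
  # zero replicate spread: infinite deltaK, flagged
  flat <- tibble::tibble(K = rep(2:4, each = 2), replicate = rep(1:2, 3),
                         lnP = rep(c(-100, -80, -79), each = 2))
  res2 <- evanno_delta_k(flat)
  expect_true(is.infinite(res2$table$delta_k[2]))
  expect_true(res2$table$sd_zero[2])
  expect_error(evanno_delta_k(lnp[lnp$K < 4, ]), "consecutive")
})

test_that("tidy and glance methods expose the delta-K table", {
  lnp <- tibble::tibble(K = rep(2:4, each = 3), replicate = rep(1:3, 3),
                        lnP = c(-101, -100, -99, -81, -80, -79,
                                -80.5, -79.5, -78.5))
  res <- evanno_delta_k(lnp)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$best_k, res$best_k)
  expect_s3_class(autoplot(res), "ggplot")
})
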