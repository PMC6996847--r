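gmat <- function(...) {
  # builds an L x 2 genotype matrix from c(a, b) rows
  do.call(rbind, list(...))
}

test_that("parental-origin assignment follows Mendelian forcing", {
  panel <- tiny_panel(1)
  # forced: 226 can only be maternal, 230 only paternal
  o <- assign_parental_origin(gmat(c(226L, 230L)), gmat(c(226L, 226L)),
                              gmat(c(230L, 232L)), panel)
  expect_equal(o$status, "resolved")
  expect_equal(o$maternal, 226L)
  expect_equal(o$paternal, 230L)
  # all three identical heterozygotes: both orientations fit
  o2 <- assign_parental_origin(gmat(c(226L, 230L)), gmat(c(226L, 230L)),
                               gmat(c(226L, 230L)), panel)
  expect_equal(o2$status, "ambiguous")
  # offspring shares no allele with either parent
  o3 <- assign_parental_origin(gmat(c(228L, 228L)), gmat(c(226L, 226L)),
                               gmat(c(230L, 230L)), panel)
  expect_equal(o3$status, "conflict")
  # duplication pattern: both offspring alleles from the dam
  o4 <- assign_parental_origin(gmat(c(226L, 230L)), gmat(c(226L, 230L)),
                               gmat(c(240L, 242L)), panel)
  expect_equal(o4$status, "conflict")
  expect_equal(o4$dup_parent, "sire")
})

test_that("trio phasing resolves fully informative trios completely", {
  panel <- tiny_panel(3)
  off <- gmat(c(100L, 110L), c(102L, 112L), c(104L, 114L))
  dam <- gmat(c(100L, 100L), c(102L, 102L), c(104L, 104L))
  sire <- gmat(c(110L, 110L), c(112L, 112L), c(114L, 114L))
  ph <- phase_trio(off, dam, sire, panel)
  expect_equal(ph$hap_maternal, c(100L, 102L, 104L))
  expect_equal(ph$hap_paternal, c(110L, 112L, 114L))
  expect_equal(ph$source, "trio")
  # all-ambiguous trio: everything stays unknown
  het <- gmat(c(100L, 110L), c(102L, 112L), c(104L, 114L))
  ph2 <- phase_trio(het, het, het, panel)
  expect_true(all(is.na(ph2$hap_maternal)))
  expect_true(all(ph2$origin$status == "ambiguous"))
})

test_that("a multi-offspring parent is phased from its transmissions", {
  # stallion het everywhere; two offspring receive its two different
  # haplotypes, each trio forcing the transmitted haplotype
  wide <- tibble::tibble(
    id = c("sire", "dam1", "dam2", "f1", "f2"),
    population = "P",
    L1.1 = c(100L, 108L, 108L, 100L, 102L),
    L1.2 = c(102L, 108L, 108L, 108L, 108L),
    L2.1 = c(120L, 128L, 128L, 120L, 122L),
    L2.2 = c(122L, 128L, 128L, 128L, 128L)
  )
  d <- tiny_data(wide)
  d <- attach_pedigree(d, tibble::tibble(id = c("f1", "f2"),
                                         sire = "sire",
                                         dam = c("dam1", "dam2")))
  ph <- phase_population(d)
  expect_setequal(c(hap_string(ph$hap_a[, "sire"]),
                    hap_string(ph$hap_b[, "sire"])),
                  c("100-120", "102-122"))
  expect_equal(ph$info$source[ph$info$id == "sire"], "propagated")
})

test_that("no pedigree means every individual stays unphased", {
  wide <- tibble::tibble(id = c("a", "b"), population = "P",
                         L1.1 = c(100L, 102L), L1.2 = c(104L, 106L))
  ph <- phase_population(tiny_data(wide))
  expect_true(all(ph$info$source == "unphased"))
})

test_that("phasing recovers planted haplotypes exactly when rates are 0", {
  cfg <- informative_config(500, n_dams = 250L, n_sires = 25L, seed = 31)
  sim <- simulate_mhc(cfg)
  ph <- phase_population(sim$data)
  # offspring: maternal/paternal haplotypes at resolved loci must equal the
  # planted transmissions at 100% of resolved loci
  mism <- 0L
  res_frac <- numeric(0)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    got <- if (tr$parent_sex == "dam") ph$hap_a[, tr$offspring] else
      ph$hap_b[, tr$offspring]
    want <- tr$transmitted[[1]]
    sel <- !is.na(got)
    mism <- mism + sum(got[sel] != want[sel])
    res_frac <- c(res_frac, mean(sel))
  }
  expect_equal(mism, 0L)
  # >= 95% of offspring loci resolved with informative founders
  expect_gte(mean(res_frac), 0.95)
  # parents recovered where phased
  for (pid in unique(sim$data$pedigree$sire)) {
    if (is.na(pid)) next
    got <- c(hap_string(ph$hap_a[, pid]), hap_string(ph$hap_b[, pid]))
    truehap <- apply(sim$founder_haps[[pid]], 2, paste, collapse = "-")
    got <- got[!is.na(got)]
    expect_true(all(got %in% truehap))
  }
})

test_that("phase_population is deterministic and row-order independent", {
  sim <- simulate_mhc(sim_config(seed = 17))
  d <- sim$data
  ph1 <- phase_population(d)
  # shuffle genotype rows and pedigree rows
  set.seed(1)
  d2 <- d
  d2$genotypes <- d2$genotypes[sample(nrow(d2$genotypes)), ]
  d2$genotypes <- d2$genotypes[order(match(d2$genotypes$id,
                                           unique(d2$genotypes$id))), ]
  perm <- sample(nrow(d2$pedigree))
  d2$pedigree <- d2$pedigree[perm, ]
  ph2 <- phase_population(d2)
  expect_identical(ph1$hap_a, ph2$hap_a)
  expect_identical(ph1$hap_b, ph2$hap_b)
  expect_identical(phase_population(d)$hap_a, ph1$hap_a)
})

test_that("phase consistency: resolved loci are a permutation of the
          genotype", {
  sim <- simulate_mhc(sim_config(seed = 19))
  ph <- phase_population(sim$data)
  gm <- equimhc:::genotype_matrices(sim$data)
  for (id in colnames(ph$hap_a)) {
    sel <- !is.na(ph$hap_a[, id]) & !is.na(ph$hap_b[, id])
    got <- unname(cbind(pmin(ph$hap_a[sel, id], ph$hap_b[sel, id]),
                        pmax(ph$hap_a[sel, id], ph$hap_b[sel, id])))
    expect_identical(got, unname(gm[[id]][sel, , drop = FALSE]))
  }
})

test_that("adding an offspring never reduces a parent's resolved loci", {
  cfg <- informative_config(40, n_dams = 10L, n_sires = 4L, seed = 23)
  sim <- simulate_mhc(cfg)
  d_full <- sim$data
  ped <- d_full$pedigree
  kids <- ped$id[!is.na(ped$sire)]
  drop_kid <- sort(kids)[length(kids)]   # remove the last-sorted offspring
  d_less <- equimhc:::subset_individuals(d_full, setdiff(ped$id, drop_kid))
  ph_full <- phase_population(d_full)
  ph_less <- phase_population(d_less)
  for (pid in unique(stats::na.omit(c(ped$sire, ped$dam)))) {
    expect_gte(sum(!is.na(ph_full$hap_a[, pid])),
               sum(!is.na(ph_less$hap_a[, pid])))
  }
})

test_that("haplotype inventory counts distinct complete haplotypes only", {
  wide <- tibble::tibble(
    id = c("p1", "p2"), population = "P",
    L1.1 = c(100L, 100L), L1.2 = c(102L, 104L),
    L2.1 = c(120L, 120L), L2.2 = c(122L, 124L)
  )
  d <- tiny_data(wide)
  ph <- phase_population(d)
  # nothing phased -> empty inventory, all chromosomes unresolved
  inv <- haplotype_inventory(ph)
  expect_equal(nrow(inv), 0L)
  # hand-build a phase: two individuals share one haplotype
  ph$hap_a[, "p1"] <- c(100L, 120L)
  ph$hap_b[, "p1"] <- c(102L, 122L)
  ph$hap_a[, "p2"] <- c(100L, 120L)
  ph$hap_b[, "p2"] <- c(104L, 124L)
  inv2 <- haplotype_inventory(ph)
  expect_equal(nrow(inv2), 3L)
  expect_equal(inv2$n_copies[inv2$haplotype == "100-120"], 2L)
  # haplotype with an unknown locus is excluded but tallied
  ph$hap_b[1, "p2"] <- NA_integer_
  inv3 <- haplotype_inventory(ph)
  expect_equal(nrow(inv3), 2L)
  expect_equal(attr(inv3, "totals")$n_unresolved, 1L)
})

test_that("shared haplotypes are the exact intersection", {
  inv <- tibble::tibble(
    population = c("A", "A", "B", "B"),
    haplotype = c("1-2", "3-4", "3-4", "5-6"),
    n_copies = 1L
  )
  expect_equal(shared_haplotypes(inv, "A", "B"), "3-4")
  expect_equal(shared_haplotypes(inv[1:2, ], "A", "B"), character(0))
  expect_equal(shared_haplotypes(inv[c(1, 2, 1, 2), ] |>
                                   dplyr::mutate(population =
                                                   rep(c("A", "B"), each = 2)),
                                 "A", "B"),
               c("1-2", "3-4"))
})
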