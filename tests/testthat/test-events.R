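panel11 <- default_panel()

# two everywhere-informative parental haplotypes over the default panel
h1 <- seq(100L, by = 10L, length.out = 11)
h2 <- h1 + 2L

test_that("exact parental copies are explained as no event", {
  for (hap in list(h1, h2)) {
    ex <- explain_transmission(cbind(h1, h2), hap, panel11)
    expect_equal(ex$status, "none")
    expect_equal(ex$cost, 0)
  }
})

test_that("a single switch localizes to the flanking informative loci", {
  # hap1 up to UM011 (position 10), hap2 from COR114 (position 11) on
  t_hap <- c(h1[1:10], h2[11])
  ex <- explain_transmission(cbind(h1, h2), t_hap, panel11)
  rec <- ex$events[ex$events$type == "recombination", ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$breakpoints, "UM011|COR114")
  # terminal single-locus switch is recombination, tie recorded
  expect_match(rec$tie, "terminal_single_locus_switch")
  # uninformative loci widen the interval
  h2b <- h2
  h2b[10] <- h1[10]                     # UM011 uninformative
  t2 <- c(h1[1:9], h1[10], h2b[11])
  ex2 <- explain_transmission(cbind(h1, h2b), t2, panel11)
  expect_equal(ex2$events$breakpoints[1], "COR113|COR114")
})

test_that("internal mismatch islands are conversions, not double
          crossovers", {
  t_hap <- h1
  t_hap[5] <- h2[5]
  ex <- explain_transmission(cbind(h1, h2), t_hap, panel11)
  expect_equal(ex$events$type, "conversion")
  expect_equal(ex$events$loci, "UMNe65")
  expect_equal(ex$cost, 1)
  # two-locus tract
  t2 <- h1
  t2[5:6] <- h2[5:6]
  ex2 <- explain_transmission(cbind(h1, h2), t2, panel11)
  expect_equal(ex2$events$type, "conversion")
  expect_equal(ex2$events$loci, "UMNe65,ABGe9030")
  # three-locus island must be recombination (2 breakpoints)
  t3 <- h1
  t3[5:7] <- h2[5:7]
  ex3 <- explain_transmission(cbind(h1, h2), t3, panel11)
  expect_equal(ex3$events$type, "recombination")
  expect_equal(ex3$n_breakpoints, 2L)
})

test_that("repeat-unit offsets are indels and larger offsets unexplained", {
  t_hap <- h1
  t_hap[4] <- h1[4] + 2L               # +1 unit, but equals h2's allele:
  ex <- explain_transmission(cbind(h1, h2), t_hap, panel11)
  expect_equal(ex$events$type, "conversion")   # cheaper reading wins
  # an offset that matches neither haplotype is forced to be an indel
  t_hap[4] <- h1[4] - 2L
  ex <- explain_transmission(cbind(h1, h2), t_hap, panel11)
  expect_equal(ex$events$type, "deletion")
  expect_equal(ex$events$m, -1L)
  t2 <- h1
  t2[4] <- h1[4] + 4L                  # +2 units, still within budget
  ex2 <- explain_transmission(cbind(h1, h2), t2, panel11)
  expect_equal(ex2$events$type, "insertion")
  expect_equal(ex2$events$m, 2L)
  t3 <- h1
  t3[4] <- h1[4] + 8L   # 4 units from the context haplotype: only readable
  ex3 <- explain_transmission(cbind(h1, h2), t3, panel11)
  # as a +3-unit shift off the homolog, which needs a 2-breakpoint island
  expect_equal(ex3$events$type[which(ex3$events$m == 3L)], "insertion")
  expect_equal(ex3$n_breakpoints, 2L)
  expect_equal(ex3$cost, 5)
  t4 <- h1
  t4[4] <- h1[4] + 1L                  # not a repeat-unit multiple
  ex4 <- explain_transmission(cbind(h1, h2), t4, panel11)
  expect_equal(ex4$status, "unexplained")
})

test_that("breakpoint count equals true switch count for all mosaics", {
  # enumerate all 2^11 mosaics of two everywhere-informative haplotypes;
  # every explained mosaic must account for the exact switch count
  # (a conversion stands for two switches), and mosaics within the
  # breakpoint budget are always explained
  for (mask in 0:(2^11 - 1)) {
    src <- as.integer(intToBits(mask))[1:11] + 1L
    t_hap <- ifelse(src == 1L, h1, h2)
    s <- sum(diff(src) != 0)
    ex <- explain_transmission(cbind(h1, h2), t_hap, panel11)
    if (ex$status == "unexplained") {
      expect_gt(s, 3)
    } else {
      n_conv <- sum(ex$events$type == "conversion")
      expect_equal(ex$n_breakpoints + 2L * n_conv, s)
    }
    if (s <= 3) expect_true(ex$status %in% c("none", "event"))
  }
})

test_that("minimal cost equals exhaustive search on random 6-locus cases", {
  panel6 <- tiny_panel(6)
  set.seed(77)
  n_checked <- 0
  for (case in 1:1000) {
    p1 <- sample(seq(100L, 116L, by = 2L), 6, replace = TRUE)
    p2 <- sample(seq(100L, 116L, by = 2L), 6, replace = TRUE)
    kind <- sample(3, 1)
    t_hap <- if (kind == 1) {
      # mosaic with optional point change
      src <- cumsum(c(sample(2, 1) - 1, stats::runif(5) < 0.3)) %% 2 + 1
      tt <- ifelse(src == 1, p1, p2)
      if (stats::runif(1) < 0.4) {
        l <- sample(6, 1)
        tt[l] <- tt[l] + sample(c(-6L, -4L, -2L, 2L, 4L, 6L, 8L), 1)
      }
      tt
    } else if (kind == 2) {
      sample(seq(98L, 118L, by = 2L), 6, replace = TRUE)  # arbitrary
    } else {
      tt <- ifelse(stats::runif(6) < 0.5, p1, p2)
      tt[sample(6, 1)] <- NA_integer_                      # partial
      tt
    }
    got <- pkg_cost(explain_transmission(cbind(p1, p2), t_hap, panel6))
    want <- oracle_min_cost(p1, p2, t_hap, panel6)
    expect_equal(got, want,
                 info = paste("case", case, ":",
                              paste(p1, collapse = ","), "/",
                              paste(p2, collapse = ","), "->",
                              paste(t_hap, collapse = ",")))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("event conservation: every transmission is accounted for once", {
  sim <- simulate_mhc(sim_config(seed = 7))
  ph <- phase_population(sim$data)
  ev <- call_events(sim$data, ph)
  per_trans <- dplyr::distinct(ev, offspring, parent_sex)
  expect_equal(nrow(per_trans), nrow(sim$truth))
  expect_true(all(ev$type %in% c("none", "recombination", "conversion",
                                 "insertion", "deletion", "unexplained",
                                 "skipped")))
})

test_that("a planted crossover is recovered with the breakpoint inside the
          reported interval", {
  cfg <- informative_config(10, n_dams = 5L, n_sires = 2L, seed = 41)
  sim <- simulate_mhc(cfg)
  # plant one crossover by hand in one offspring's paternal transmission
  panel <- cfg$panel
  sire <- sim$data$pedigree$sire[!is.na(sim$data$pedigree$sire)][1]
  oid <- sim$data$pedigree$id[which(sim$data$pedigree$sire == sire)[1]]
  haps <- sim$founder_haps[[sire]]
  recomb <- c(haps[1:6, 1], haps[7:11, 2])
  g <- sim$data$genotypes
  dam <- sim$data$pedigree$dam[sim$data$pedigree$id == oid]
  dam_tr <- sim$truth$transmitted[[
    which(sim$truth$offspring == oid & sim$truth$parent_sex == "dam")]]
  for (l in seq_len(11)) {
    sel <- g$id == oid & g$locus == panel$locus[l]
    g$a1[sel] <- min(dam_tr[l], recomb[l])
    g$a2[sel] <- max(dam_tr[l], recomb[l])
  }
  sim$data$genotypes <- g
  ph <- phase_population(sim$data)
  ev <- call_events(sim$data, ph)
  rec <- ev[ev$type == "recombination", ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$offspring, oid)
  expect_equal(rec$parent_sex, "sire")
  # the reported interval must contain the planted breakpoint (positions
  # 6|7); an uninformative flank legitimately widens it
  bp <- strsplit(rec$breakpoints, "\\|")[[1]]
  expect_lte(match(bp[1], panel$locus), 6L)
  expect_gte(match(bp[2], panel$locus), 7L)
})

test_that("event frequencies use meioses as the denominator", {
  # pedigree shaped like a 12-trio population: 24 meioses
  wide <- tibble::tibble(
    id = c(sprintf("f%02d", 1:12), sprintf("d%02d", 1:12), "s1"),
    population = "Pop2", L1.1 = 100L, L1.2 = 102L)
  d <- tiny_data(wide)
  d <- attach_pedigree(d, tibble::tibble(id = sprintf("f%02d", 1:12),
                                         sire = "s1",
                                         dam = sprintf("d%02d", 1:12)))
  expect_equal(count_meioses(d)$n_meioses, 24L)
  ev <- tibble::tibble(
    offspring = c("f01", "f02", "f03"), parent = "s1",
    parent_sex = "sire", population = "Pop2",
    n_breakpoints = 1L, cost = 2, resulting_haplotype = c("a", "b", "c"),
    is_new_haplotype = TRUE, type = "recombination",
    breakpoints = "L1|L1", loci = NA_character_, m = NA_integer_,
    tie = NA_character_)
  es <- event_summary(ev, d)
  expect_equal(es$recombination_frequency, 100 * 3 / 24)
  # zero events
  es0 <- event_summary(ev[0, ], d)
  expect_equal(es0$recombination_frequency, 0)
  expect_equal(es0$new_haplotype_ratio, 0)
})

test_that("zero-rate simulation yields zero events and zero new
          haplotypes", {
  sim <- simulate_mhc(sim_config(crossover_prob = 0, conversion_prob = 0,
                                 indel_prob = 0, seed = 3))
  ph <- phase_population(sim$data)
  ev <- call_events(sim$data, ph)
  expect_equal(sum(ev$type %in% c("recombination", "conversion",
                                  "insertion", "deletion")), 0L)
  nh <- new_haplotype_ratio(ph, sim$data)
  expect_true(all(nh$n_new_haplotypes == 0))
})

test_that("recombination frequency is recovered across a range of rates", {
  for (r in c(0.02, 0.125)) {
    cfg <- informative_config(1000, crossover_prob = 1 - (1 - r)^(1 / 10),
                              seed = round(1000 * r))
    sim <- simulate_mhc(cfg)
    ph <- phase_population(sim$data)
    ev <- call_events(sim$data, ph)
    es <- event_summary(ev, sim$data)
    est <- es$recombination_frequency / 100
    n <- es$n_meioses
    half <- 1.96 * sqrt(est * (1 - est) / n)
    expect_lt(abs(est - r), half)
  }
})
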