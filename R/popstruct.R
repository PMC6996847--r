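#' Nei genetic identity and distance between two populations
#'
#' `I = Jxy / sqrt(Jx * Jy)` with `Jxy = sum(x_a * y_a)`, `Jx = sum(x_a^2)`,
#' `Jy = sum(y_a^2)` averaged over loci, and `D = -ln(I)`. With
#' `unbiased = TRUE` (default) the within-population J terms use Nei's
#' sample-size correction `(2n * J - 1)/(2n - 1)`; the unbiased identity can
#' slightly exceed 1 for very similar samples, in which case `D` is negative
#' (reported as-is). `I = 0` yields `D = Inf` with a flag.
#'
#' @param freqs_a,freqs_b Allele-frequency tables for the two populations as
#'   returned by [allele_freqs()] (columns `locus`, `allele`, `freq`,
#'   `n_genes`), over a shared panel.
#' @param unbiased Apply the sample-size correction to Jx and Jy.
#' @return List `identity`, `distance`, `infinite` (flag), `n_loci`.
#' @export
nei_identity_distance <- function(freqs_a, freqs_b, unbiased = TRUE) {
  loci <- intersect(unique(freqs_a$locus), unique(freqs_b$locus))
  if (!length(loci)) stop("no shared locus with frequencies", call. = FALSE)
  jxy <- jx <- jy <- numeric(length(loci))
  for (i in seq_along(loci)) {
    fa <- freqs_a[freqs_a$locus == loci[i], ]
    fb <- freqs_b[freqs_b$locus == loci[i], ]
    alleles <- union(fa$allele, fb$allele)
    x <- fa$freq[match(alleles, fa$allele)]
    y <- fb$freq[match(alleles, fb$allele)]
    x[is.na(x)] <- 0
    y[is.na(y)] <- 0
    jxy[i] <- sum(x * y)
    jx_raw <- sum(x^2)
    jy_raw <- sum(y^2)
    if (unbiased) {
      na <- fa$n_genes[1]
      nb <- fb$n_genes[1]
      jx[i] <- (na * jx_raw - 1) / (na - 1)
      jy[i] <- (nb * jy_raw - 1) / (nb - 1)
    } else {
      jx[i] <- jx_raw
      jy[i] <- jy_raw
    }
  }
  id <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  inf <- id <= 0
  list(identity = id,
       distance = if (inf) Inf else -log(id),
       infinite = inf, n_loci = length(loci))
}

#' Pairwise Nei identity/distance for all population pairs
#'
#' @param data An `mhc_data` object.
#' @param unbiased See [nei_identity_distance()].
#' @return Tibble `pop_a`, `pop_b`, `nei_i`, `nei_d`, `infinite`.
#' @export
nei_distance <- function(data, unbiased = TRUE) {
  freqs <- allele_freqs(data, by_population = TRUE)
  pops <- sort(unique(freqs$population))
  pairs <- utils::combn(pops, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    res <- nei_identity_distance(freqs[freqs$population == a, ],
                                 freqs[freqs$population == b, ],
                                 unbiased = unbiased)
    tibble::tibble(pop_a = a, pop_b = b, nei_i = res$identity,
                   nei_d = res$distance, infinite = res$infinite)
  })
  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# AMOVA: three-level hierarchical partition (among groups / among individuals
# within groups / within individuals) for codominant multilocus genotypes.
# Squared distance between two gene copies at a locus is the allele mismatch
# indicator (0/1), summed over loci; this is equivalent to a nested ANOVA on
# per-allele indicator variables with SS scaled by 1/2.

# per-locus sufficient statistics for fast (re)computation under permutation
amova_prepare <- function(data, groups) {
  g <- data$genotypes
  ids <- unique(g$id)
  grp <- groups[match(ids, names(groups))]
  per_locus <- lapply(data$panel$locus, function(lc) {
    gi <- g[g$locus == lc, ]
    gi <- gi[match(ids, gi$id), ]
    typed <- !is.na(gi$a1)
    alleles <- sort(unique(c(gi$a1[typed], gi$a2[typed])))
    # individual x allele count matrix (0/1/2)
    y <- matrix(0L, nrow = length(ids), ncol = length(alleles))
    y[cbind(seq_along(ids), match(gi$a1, alleles))[typed, , drop = FALSE]] <-
      y[cbind(seq_along(ids), match(gi$a1, alleles))[typed, , drop = FALSE]] + 1L
    y[cbind(seq_along(ids), match(gi$a2, alleles))[typed, , drop = FALSE]] <-
      y[cbind(seq_along(ids), match(gi$a2, alleles))[typed, , drop = FALSE]] + 1L
    list(y = y, typed = typed)
  })
  list(ids = ids, grp = grp, per_locus = per_locus)
}

# sums of squares at the three levels for a given group labelling
amova_ss <- function(prep, grp) {
  ss_ap <- ss_ai <- ss_wi <- 0
  sum_ni <- sum_ni2 <- 0
  n_tot <- 0
  n_groups <- length(unique(grp))
  for (pl in prep$per_locus) {
    y <- pl$y[pl$typed, , drop = FALSE]
    gl <- grp[pl$typed]
    n <- nrow(y)
    if (n < 2) next
    ga <- colSums(y)                       # total allele counts
    gia <- rowsum(y, gl)                   # group x allele counts
    ni <- as.integer(table(gl)[rownames(gia)])
    ss_tot_a <- ga - ga^2 / (2 * n)
    ss_wi_a <- 0.5 * colSums(y == 1L)      # het individuals contribute 1/2
    ss_ap_a <- colSums(gia^2 / (2 * ni)) - ga^2 / (2 * n)
    ss_ai_a <- ss_tot_a - ss_ap_a - ss_wi_a
    ss_ap <- ss_ap + 0.5 * sum(ss_ap_a)
    ss_ai <- ss_ai + 0.5 * sum(ss_ai_a)
    ss_wi <- ss_wi + 0.5 * sum(ss_wi_a)
  }
  list(ss_ap = ss_ap, ss_ai = ss_ai, ss_wi = ss_wi)
}

amova_components <- function(prep, grp) {
  ss <- amova_ss(prep, grp)
  n <- length(prep$ids)
  groups <- table(grp)
  r <- length(groups)
  df_ap <- r - 1L
  df_ai <- n - r
  df_wi <- n
  ms_ap <- ss$ss_ap / df_ap
  ms_ai <- ss$ss_ai / df_ai
  ms_wi <- ss$ss_wi / df_wi
  copies <- 2 * as.numeric(groups)
  n0 <- (sum(copies) - sum(copies^2) / sum(copies)) / df_ap
  v_wi <- ms_wi
  v_ai <- (ms_ai - ms_wi) / 2
  v_ap <- (ms_ap - ms_ai) / n0
  list(df = c(df_ap, df_ai, df_wi), ss = c(ss$ss_ap, ss$ss_ai, ss$ss_wi),
       ms = c(ms_ap, ms_ai, ms_wi), v = c(v_ap, v_ai, v_wi))
}

phi_pt <- function(v) {
  vt <- pmax(v, 0)
  tot <- sum(vt)
  if (tot <= 0) NA_real_ else vt[1] / tot
}

#' Hierarchical AMOVA for codominant multilocus genotypes
#'
#' Partitions genetic variance among groups, among individuals within groups
#' and within individuals, in the Excoffier framework: the squared distance
#' between two gene copies at a locus is the allele-mismatch indicator,
#' summed over loci (no repeat-size weighting). Individuals missing a locus
#' are skipped at that locus. Variance components are obtained by equating
#' mean squares; negative components are reported raw and truncated to zero
#' for the percent-of-total calculation (flagged). The Phi-PT p-value comes
#' from permuting individuals among groups with the add-one correction.
#'
#' @param data An `mhc_data` object with `>= 2` groups of `>= 2` individuals.
#' @param grouping Optional grouping: a data frame `id`, `group`, or a named
#'   character vector (names = individual ids). Default: population labels.
#'   Groups of size 1 are excluded with a warning.
#' @param n_perm Permutations for the Phi-PT test (0 to skip).
#' @param seed Seed for the permutations.
#' @return An object of class `mhc_amova` with `levels` (df, SS, MS, raw and
#'   truncated variance components, percent of total), `phi` (Phi-PT,
#'   Phi-IS, Phi-IT and the permutation p for Phi-PT) and bookkeeping
#'   fields. `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
amova <- function(data, grouping = NULL, n_perm = 999, seed = 1L) {
  ind <- individuals(data)
  groups <- if (is.null(grouping)) {
    stats::setNames(ind$population, ind$id)
  } else if (is.data.frame(grouping)) {
    stopifnot(all(c("id", "group") %in% names(grouping)))
    stats::setNames(as.character(grouping$group), as.character(grouping$id))
  } else {
    stats::setNames(as.character(grouping), names(grouping))
  }
  unassigned <- setdiff(ind$id, names(groups))
  if (length(unassigned)) {
    stop("individual(s) without group assignment: ",
         paste(utils::head(unassigned, 5), collapse = ", "), call. = FALSE)
  }
  groups <- groups[ind$id]
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning("group(s) of size 1 excluded from AMOVA: ",
            paste(singletons, collapse = ", "))
    keep <- !groups %in% singletons
    data <- subset_individuals(data, ind$id[keep])
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) {
    stop("AMOVA needs >= 2 groups of >= 2 individuals", call. = FALSE)
  }
  prep <- amova_prepare(data, groups)
  comp <- amova_components(prep, prep$grp)
  v <- comp$v
  vt <- pmax(v, 0)
  tot <- sum(vt)
  degenerate <- tot <= 0
  pct <- if (degenerate) rep(NA_real_, 3) else 100 * vt / tot
  phi_pt_obs <- phi_pt(v)
  phi_is <- if ((vt[2] + vt[3]) > 0) vt[2] / (vt[2] + vt[3]) else NA_real_
  phi_it <- if (!degenerate) (vt[1] + vt[2]) / tot else NA_real_
  p_ap <- NA_real_
  if (n_perm > 0 && !is.na(phi_pt_obs)) {
    hits <- with_local_seed(seed, {
      h <- 0L
      for (i in seq_len(n_perm)) {
        phi_perm <- phi_pt(amova_components(prep, sample(prep$grp))$v)
        if (!is.na(phi_perm) && phi_perm >= phi_pt_obs - 1e-12) h <- h + 1L
      }
      h
    })
    p_ap <- (hits + 1) / (n_perm + 1)
  }
  levels <- tibble::tibble(
    level = c("among_groups", "among_individuals", "within_individuals"),
    df = comp$df, ss = comp$ss, ms = comp$ms,
    variance_raw = v, variance = vt,
    percent = pct
  )
  phi <- tibble::tibble(
    statistic = c("phi_pt", "phi_is", "phi_it"),
    value = c(phi_pt_obs, phi_is, phi_it),
    p = c(p_ap, NA_real_, NA_real_)
  )
  structure(
    list(levels = levels, phi = phi, n_perm = n_perm,
         degenerate = degenerate,
         truncated = any(v < 0),
         excluded_groups = singletons),
    class = "mhc_amova"
  )
}

subset_individuals <- function(data, ids) {
  data$genotypes <- data$genotypes[data$genotypes$id %in% ids, ]
  data$pedigree <- data$pedigree[data$pedigree$id %in% ids, ]
  data$pedigree$sire[!data$pedigree$sire %in% ids] <- NA_character_
  data$pedigree$dam[!data$pedigree$dam %in% ids] <- NA_character_
  data
}

#' AMOVA across externally inferred clusters
#'
#' Same computation as [amova()] with cluster assignments (e.g. from a
#' Bayesian admixture run) as the grouping level.
#'
#' @param data An `mhc_data` object.
#' @param assignments Data frame `id`, `cluster` covering every individual.
#' @inheritParams amova
#' @return An `mhc_amova` object.
#' @export
cluster_amova <- function(data, assignments, n_perm = 999, seed = 1L) {
  stopifnot(all(c("id", "cluster") %in% names(assignments)))
  amova(data,
        grouping = data.frame(id = assignments$id,
                              group = assignments$cluster),
        n_perm = n_perm, seed = seed)
}

#' @export
print.mhc_amova <- function(x, ...) {
  cat("<mhc_amova>\n")
  print(x$levels)
  print(x$phi)
  if (x$truncated) cat("  note: negative variance component truncated to 0\n")
  if (x$degenerate) cat("  note: total variance 0; percents undefined\n")
  invisible(x)
}

#' @rdname amova
#' @param x,object An `mhc_amova` object.
#' @param ... Unused.
#' @export
tidy.mhc_amova <- function(x, ...) x$levels

#' @rdname amova
#' @export
glance.mhc_amova <- function(x, ...) {
  tibble::tibble(
    phi_pt = x$phi$value[1], phi_is = x$phi$value[2],
    phi_it = x$phi$value[3], p_phi_pt = x$phi$p[1],
    n_perm = x$n_perm, degenerate = x$degenerate
  )
}

#' @rdname amova
#' @export
autoplot.mhc_amova <- function(object, ...) {
  lv <- object$levels
  lv$level <- factor(lv$level, levels = rev(lv$level))
  ggplot2::ggplot(lv, ggplot2::aes(x = "", y = .data$percent,
                                   fill = .data$level)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of molecular variance",
                  fill = "level") +
    ggplot2::theme_minimal()
}

#' Pairwise population differentiation (Phi-PT / Fst)
#'
#' Default estimator is Phi-PT from a two-level [amova()] on each population
#' pair (identical to `amova()` restricted to the pair), with a permutation
#' p-value; the Weir-Cockerham theta estimator is available via `method`.
#' Raw (possibly negative) values are kept alongside values clamped to 0.
#'
#' @param data An `mhc_data` object.
#' @param method `"phipt"` (default) or `"wc"` (Weir-Cockerham theta).
#' @param n_perm Permutations of individuals between the two populations.
#' @param seed Base seed.
#' @return Tibble `pop_a`, `pop_b`, `fst` (clamped), `fst_raw`, `p`,
#'   `method`.
#' @export
pairwise_fst <- function(data, method = c("phipt", "wc"), n_perm = 999,
                         seed = 1L) {
  method <- match.arg(method)
  ind <- individuals(data)
  pops <- sort(unique(ind$population))
  pairs <- utils::combn(pops, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    sub <- subset_individuals(data, ind$id[ind$population %in% c(a, b)])
    if (method == "phipt") {
      res <- amova(sub, n_perm = n_perm, seed = substream_seed(seed, j))
      raw <- res$phi$value[1]
      p <- res$phi$p[1]
    } else {
      raw <- wc_theta(sub)
      p <- wc_theta_perm_p(sub, raw, n_perm, substream_seed(seed, j))
    }
    tibble::tibble(pop_a = a, pop_b = b, fst = max(0, raw), fst_raw = raw,
                   p = p, method = method)
  })
  dplyr::bind_rows(rows)
}

# Weir & Cockerham (1984) theta over loci and alleles
wc_theta <- function(data) {
  comps <- wc_components(data)
  sum(comps$a) / sum(comps$a + comps$b + comps$c)
}

wc_components <- function(data) {
  g <- data$genotypes
  a_sum <- b_sum <- c_sum <- numeric(0)
  for (lc in unique(g$locus)) {
    gi <- g[g$locus == lc & !is.na(g$a1), ]
    if (!nrow(gi)) next
    pops <- unique(gi$population)
    r <- length(pops)
    if (r < 2) next
    ni <- vapply(pops, function(p) sum(gi$population == p), numeric(1))
    if (any(ni < 1)) next
    alleles <- sort(unique(c(gi$a1, gi$a2)))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in alleles) {
      pi <- vapply(pops, function(p) {
        gp <- gi[gi$population == p, ]
        (sum(gp$a1 == al) + sum(gp$a2 == al)) / (2 * nrow(gp))
      }, numeric(1))
      hi <- vapply(pops, function(p) {
        gp <- gi[gi$population == p, ]
        mean(xor(gp$a1 == al, gp$a2 == al))
      }, numeric(1))
      pbar <- sum(ni * pi) / sum(ni)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / sum(ni)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      a_sum <- c(a_sum, a)
      b_sum <- c(b_sum, b)
      c_sum <- c(c_sum, cc)
    }
  }
  list(a = a_sum, b = b_sum, c = c_sum)
}

wc_theta_perm_p <- function(data, obs, n_perm, seed) {
  if (n_perm < 1 || is.na(obs)) return(NA_real_)
  ind <- individuals(data)
  with_local_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      perm <- data
      shuffled <- sample(ind$population)
      perm$genotypes$population <-
        shuffled[match(perm$genotypes$id, ind$id)]
      if (wc_theta(perm) >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}
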