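#' Evanno delta-K from clustering log-likelihoods
#'
#' Post-processes replicate log-probabilities of the data, `lnP(K)`, from an
#' external Bayesian clustering run (e.g. Structure or ADMIXTURE replicates)
#' to select the number of clusters: for each interior K,
#' `deltaK = |mean lnP(K+1) - 2 mean lnP(K) + mean lnP(K-1)| / sd(lnP(K))`,
#' and `best_k` is the K maximising deltaK. The clustering itself is out of
#' scope here; only its likelihood output is consumed.
#'
#' @param lnp Data frame with columns `K` (integer), `replicate` and `lnP`.
#'   At least 3 consecutive K values with `>= 2` replicates each.
#' @return An object of class `mhc_deltak`: list with `table` (tibble `K`,
#'   `n_rep`, `mean_lnp`, `sd_lnp`, `abs_l2`, `delta_k`, `sd_zero` flag) and
#'   `best_k`. `delta_k` is `Inf` (flagged) where `sd = 0`.
#' @export
#' @examples
#' lnp <- expand.grid(K = 2:5, replicate = 1:3)
#' lnp$lnP <- c(-100, -80, -79.5, -79)[lnp$K - 1] + rnorm(nrow(lnp), 0, 1)
#' evanno_delta_k(lnp)
evanno_delta_k <- function(lnp) {
  lnp <- tibble::as_tibble(lnp)
  stopifnot(all(c("K", "lnP") %in% names(lnp)))
  tab <- lnp |>
    dplyr::group_by(K = as.integer(.data$K)) |>
    dplyr::summarise(n_rep = dplyr::n(), mean_lnp = mean(.data$lnP),
                     sd_lnp = stats::sd(.data$lnP), .groups = "drop") |>
    dplyr::arrange(.data$K)
  if (nrow(tab) < 3 || any(diff(tab$K) != 1L)) {
    stop("need >= 3 consecutive K values", call. = FALSE)
  }
  if (any(tab$n_rep < 2)) {
    stop("need >= 2 replicates per K", call. = FALSE)
  }
  n <- nrow(tab)
  abs_l2 <- rep(NA_real_, n)
  inner <- 2:(n - 1)
  abs_l2[inner] <- abs(tab$mean_lnp[inner + 1] - 2 * tab$mean_lnp[inner] +
                         tab$mean_lnp[inner - 1])
  delta_k <- abs_l2 / tab$sd_lnp
  sd_zero <- tab$sd_lnp == 0 & !is.na(abs_l2)
  delta_k[sd_zero & abs_l2 > 0] <- Inf
  delta_k[sd_zero & abs_l2 == 0] <- NaN
  tab$abs_l2 <- abs_l2
  tab$delta_k <- delta_k
  tab$sd_zero <- tab$sd_lnp == 0
  best <- tab$K[which.max(replace(delta_k, is.na(delta_k), -Inf))]
  structure(list(table = tab, best_k = best), class = "mhc_deltak")
}

#' @export
print.mhc_deltak <- function(x, ...) {
  cat("<mhc_deltak> best K =", x$best_k, "\n")
  print(x$table)
  invisible(x)
}

#' @rdname evanno_delta_k
#' @param x An `mhc_deltak` object.
#' @param ... Unused.
#' @export
tidy.mhc_deltak <- function(x, ...) x$table

#' @rdname evanno_delta_k
#' @export
glance.mhc_deltak <- function(x, ...) {
  tibble::tibble(best_k = x$best_k,
                 max_delta_k = max(x$table$delta_k, na.rm = TRUE),
                 k_min = min(x$table$K), k_max = max(x$table$K))
}

#' @rdname evanno_delta_k
#' @param object An `mhc_deltak` object.
#' @export
autoplot.mhc_deltak <- function(object, ...) {
  tab <- object$table[!is.na(object$table$delta_k), ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K),
                  title = paste0("Evanno ΔK (best K = ",
                                 object$best_k, ")")) +
    ggplot2::theme_minimal()
}
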