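#' Validate a dataset: missingness, duplicates and Mendelian checks
#'
#' Report-only quality control. Mendelian incompatibilities — an offspring
#' that shares no allele with a recorded parent at a typed locus — are
#' reported but never removed: in this design they are candidate meiotic
#' events (repeat-unit insertions/deletions or conversions), not necessarily
#' typing errors, and are handed downstream to event classification.
#'
#' @param data An `mhc_data` object.
#' @return A list of class `mhc_validation`:
#'   \describe{
#'     \item{missingness}{tibble `locus`, `n_typed`, `n_missing`,
#'       `prop_missing`.}
#'     \item{mendelian}{tibble `offspring`, `parent`, `parent_role`, `locus`,
#'       offspring and parent allele pairs, one row per incompatible
#'       offspring/parent/locus combination.}
#'     \item{n_individuals, n_offspring}{counts.}
#'   }
#' @export
validate_mhc <- function(data) {
  stopifnot(inherits(data, "mhc_data"))
  g <- data$genotypes
  missingness <- g |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_typed = sum(!is.na(.data$a1)),
      n_missing = sum(is.na(.data$a1)),
      prop_missing = .data$n_missing / dplyr::n(),
      .groups = "drop"
    )
  missingness <- missingness[match(data$panel$locus, missingness$locus), ]
  gm <- genotype_matrices(data)
  ped <- data$pedigree
  rows <- list()
  for (i in which(!is.na(ped$sire) | !is.na(ped$dam))) {
    off <- ped$id[i]
    for (role in c("sire", "dam")) {
      par <- ped[[role]][i]
      if (is.na(par)) next
      og <- gm[[off]]
      pg <- gm[[par]]
      for (l in seq_len(nrow(data$panel))) {
        if (anyNA(og[l, ]) || anyNA(pg[l, ])) next
        if (!any(og[l, ] %in% pg[l, ])) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            offspring = off, parent = par, parent_role = role,
            locus = data$panel$locus[l],
            offspring_a1 = og[l, 1], offspring_a2 = og[l, 2],
            parent_a1 = pg[l, 1], parent_a2 = pg[l, 2]
          )
        }
      }
    }
  }
  mendelian <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(offspring = character(), parent = character(),
                   parent_role = character(), locus = character(),
                   offspring_a1 = integer(), offspring_a2 = integer(),
                   parent_a1 = integer(), parent_a2 = integer())
  structure(
    list(missingness = missingness, mendelian = mendelian,
         n_individuals = nrow(ped),
         n_offspring = sum(!is.na(ped$sire) | !is.na(ped$dam))),
    class = "mhc_validation"
  )
}

#' @export
print.mhc_validation <- function(x, ...) {
  cat("<mhc_validation> ", x$n_individuals, " individuals (",
      x$n_offspring, " offspring)\n", sep = "")
  cat("  Mendelian incompatibilities (candidate events):",
      nrow(x$mendelian), "\n")
  cat("  loci with missing genotypes:",
      sum(x$missingness$n_missing > 0), "\n")
  invisible(x)
}

#' @rdname validate_mhc
#' @param x An `mhc_validation` report.
#' @param ... Unused.
#' @export
tidy.mhc_validation <- function(x, ...) x$mendelian

#' Write a validation report as TSV (tables) and JSON (summary)
#'
#' @param report An `mhc_validation` report.
#' @param prefix Output path prefix; writes `<prefix>_missingness.tsv`,
#'   `<prefix>_mendelian.tsv`, `<prefix>.json`.
#' @return The JSON path, invisibly.
#' @export
write_validation <- function(report, prefix) {
  readr::write_tsv(report$missingness, paste0(prefix, "_missingness.tsv"))
  readr::write_tsv(report$mendelian, paste0(prefix, "_mendelian.tsv"))
  jsonlite::write_json(
    list(n_individuals = report$n_individuals,
         n_offspring = report$n_offspring,
         n_mendelian_incompatibilities = nrow(report$mendelian)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(prefix, ".json"))
}
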