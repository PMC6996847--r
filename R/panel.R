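#' Define a microsatellite locus panel
#'
#' A panel is the ordered set of microsatellite loci along the chromosome map.
#' It is the coordinate system for the whole package: genotypes carry one
#' allele pair per panel locus, haplotypes are ordered by `map_index`, and
#' recombination breakpoints are named by the flanking locus pair (the map
#' gives no base-pair positions).
#'
#' @param loci A data frame with columns `locus` (character, unique),
#'   `mhc_class` (one of `"I"`, `"II"`, `"III"`), `map_index` (strictly
#'   increasing integers), and optionally `repeat_unit` (positive integer,
#'   default 2), `size_min`, `size_max` (inclusive allele size range in bp).
#'   `NULL` returns the default panel, see [default_panel()].
#'
#' @return A tibble with class `mhc_panel`, one row per locus in map order.
#' @export
#' @examples
#' mhc_panel()
mhc_panel <- function(loci = NULL) {
  if (is.null(loci)) {
    return(default_panel())
  }
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("locus", "mhc_class", "map_index") %in% names(loci)))
  if (!"repeat_unit" %in% names(loci)) loci$repeat_unit <- 2L
  if (!"size_min" %in% names(loci)) loci$size_min <- NA_integer_
  if (!"size_max" %in% names(loci)) loci$size_max <- NA_integer_
  loci$locus <- as.character(loci$locus)
  loci$map_index <- as.integer(loci$map_index)
  loci$repeat_unit <- as.integer(loci$repeat_unit)
  if (anyDuplicated(loci$locus)) {
    stop("panel locus names must be unique", call. = FALSE)
  }
  if (any(!nzchar(loci$locus))) {
    stop("panel locus names must be non-empty", call. = FALSE)
  }
  if (any(loci$repeat_unit < 1L)) {
    stop("repeat_unit must be >= 1", call. = FALSE)
  }
  if (!all(loci$mhc_class %in% c("I", "II", "III"))) {
    stop("mhc_class must be one of I, II, III", call. = FALSE)
  }
  loci <- loci[order(loci$map_index), , drop = FALSE]
  if (any(diff(loci$map_index) <= 0L)) {
    stop("map_index must be strictly increasing", call. = FALSE)
  }
  structure(
    loci[, c("locus", "mhc_class", "map_index", "repeat_unit",
             "size_min", "size_max")],
    class = c("mhc_panel", class(tibble::tibble()))
  )
}

#' Default 11-locus equine MHC microsatellite panel
#'
#' Eleven intra-MHC microsatellites on horse chromosome 20, ordered along the
#' chromosome map: three MHC class I loci (COR110, UMN-JH38, TAMU30593), two
#' class III loci (ABGe9019, UMNe65) and six class II loci (ABGe9030,
#' TKY3324, COR112, COR113, UM011, COR114). The within-class order of the
#' three class I loci is not constrained by any observable crossover, so it
#' is configurable through [mhc_panel()]; the default places UMN-JH38 between
#' COR110 and TAMU30593. All loci are dinucleotide repeats (`repeat_unit` 2).
#'
#' @return An `mhc_panel` tibble with 11 rows.
#' @export
default_panel <- function() {
  mhc_panel(tibble::tibble(
    locus = c("COR110", "UMN-JH38", "TAMU30593", "ABGe9019", "UMNe65",
              "ABGe9030", "TKY3324", "COR112", "COR113", "UM011", "COR114"),
    mhc_class = c("I", "I", "I", "III", "III",
                  "II", "II", "II", "II", "II", "II"),
    map_index = 1:11,
    repeat_unit = 2L,
    size_min = c(216L, 145L, 140L, 120L, 130L, 90L, 150L, 220L, 260L, 170L, 240L),
    size_max = c(260L, 165L, 180L, 170L, 170L, 130L, 200L, 260L, 300L, 220L, 280L)
  ))
}

#' Read a locus panel from a JSON file
#'
#' The JSON file holds an array of objects with fields `locus`, `mhc_class`,
#' `map_index` and optionally `repeat_unit`, `size_min`, `size_max`.
#'
#' @param path Path to a panel JSON file.
#' @return An `mhc_panel` tibble.
#' @export
read_panel <- function(path) {
  mhc_panel(jsonlite::fromJSON(path))
}

#' Write a locus panel to JSON
#'
#' @param panel An `mhc_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(as.data.frame(panel), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}
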