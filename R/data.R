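#' Assemble an MHC microsatellite dataset
#'
#' Bundles diploid genotypes, an optional pedigree and a locus panel into the
#' container used by every analysis function. Genotypes are stored in long
#' (tidy) form, one row per individual per locus, with the allele pair
#' canonicalized so that `a1 <= a2` (pair order carries no meaning) and a
#' locus with either allele missing treated as wholly missing.
#'
#' @param genotypes A data frame in either wide form (`id`, `population`,
#'   then two columns `<locus>.1`, `<locus>.2` per panel locus) or long form
#'   (`id`, `population`, `locus`, `a1`, `a2`).
#' @param pedigree Optional data frame with columns `id`, `sire`, `dam`
#'   (`NA` or `""` for unknown parents). See [attach_pedigree()].
#' @param panel An [mhc_panel()]; defaults to [default_panel()].
#'
#' @return An object of class `mhc_data`: a list with tibbles `genotypes`
#'   (long), `pedigree` (one row per individual) and the `panel`.
#' @export
#' @examples
#' geno <- tibble::tibble(
#'   id = c("f1", "d1", "s1"), population = "PopA",
#'   COR110.1 = c(226L, 226L, 230L), COR110.2 = c(230L, 226L, 232L)
#' )
#' panel <- mhc_panel(tibble::tibble(locus = "COR110", mhc_class = "I",
#'                                   map_index = 1L))
#' dat <- mhc_data(geno, panel = panel)
#' dat$genotypes
mhc_data <- function(genotypes, pedigree = NULL, panel = default_panel()) {
  stopifnot(inherits(panel, "mhc_panel"))
  genotypes <- tibble::as_tibble(genotypes)
  long <- if (all(c("locus", "a1", "a2") %in% names(genotypes))) {
    genotypes[, c("id", "population", "locus", "a1", "a2")]
  } else {
    wide_to_long(genotypes, panel)
  }
  long$id <- as.character(long$id)
  long$population <- as.character(long$population)
  long$locus <- as.character(long$locus)
  bad <- setdiff(unique(long$locus), panel$locus)
  if (length(bad)) {
    stop("genotype loci not in panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(long$id)
  # complete: one row per individual per panel locus, map order
  long <- tidyr::complete(
    long,
    tidyr::nesting(!!rlang::sym("id"), !!rlang::sym("population")),
    locus = panel$locus
  )
  long <- long[order(match(long$id, ids), match(long$locus, panel$locus)), ]
  long[c("a1", "a2")] <- canonicalize_pairs(long$a1, long$a2)
  if (any(long$a1 <= 0, na.rm = TRUE)) {
    stop("allele sizes must be positive", call. = FALSE)
  }
  per_ind <- unique(long[, c("id", "population")])
  if (anyDuplicated(per_ind$id)) {
    stop("duplicate individual id: ",
         paste(unique(per_ind$id[duplicated(per_ind$id)]), collapse = ", "),
         call. = FALSE)
  }
  ped <- tibble::tibble(id = per_ind$id,
                        sire = NA_character_, dam = NA_character_)
  out <- structure(
    list(genotypes = tibble::as_tibble(long),
         pedigree = ped, panel = panel),
    class = "mhc_data"
  )
  if (!is.null(pedigree)) out <- attach_pedigree(out, pedigree)
  out
}

wide_to_long <- function(wide, panel) {
  if (!all(c("id", "population") %in% names(wide))) {
    stop("genotype table must have columns 'id' and 'population'",
         call. = FALSE)
  }
  if (anyDuplicated(wide$id)) {
    stop("duplicate individual id: ",
         paste(unique(wide$id[duplicated(wide$id)]), collapse = ", "),
         call. = FALSE)
  }
  allele_cols <- setdiff(names(wide), c("id", "population"))
  locus_of <- sub("\\.[12]$", "", allele_cols)
  unknown <- setdiff(unique(locus_of), panel$locus)
  if (length(unknown)) {
    stop("unknown locus column(s): ",
         paste(allele_cols[locus_of %in% unknown], collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(paste0(rep(panel$locus, each = 2), c(".1", ".2")),
                  allele_cols)
  if (length(miss)) {
    stop("missing allele column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parse_allele <- function(col, colname) {
    x <- wide[[col]]
    if (is.numeric(x)) {
      if (any(!is.na(x) & x != floor(x))) {
        row <- which(!is.na(x) & x != floor(x))[1]
        stop("non-integer allele in column ", colname, ", row ", row,
             call. = FALSE)
      }
      x <- as.integer(x)
    } else {
      x <- trimws(as.character(x))
      x[x == ""] <- NA
      ok <- is.na(x) | grepl("^[0-9]+$", x)
      if (!all(ok)) {
        stop("non-integer allele in column ", colname, ", row ",
             which(!ok)[1], call. = FALSE)
      }
      x <- as.integer(x)
    }
    x[!is.na(x) & x == 0L] <- NA_integer_  # 0 codes missing
    x
  }
  rows <- lapply(panel$locus, function(lc) {
    tibble::tibble(
      id = as.character(wide$id),
      population = as.character(wide$population),
      locus = lc,
      a1 = parse_allele(paste0(lc, ".1"), paste0(lc, ".1")),
      a2 = parse_allele(paste0(lc, ".2"), paste0(lc, ".2"))
    )
  })
  dplyr::bind_rows(rows)
}

canonicalize_pairs <- function(a1, a2) {
  miss <- is.na(a1) | is.na(a2)
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  lo[miss] <- NA_integer_
  hi[miss] <- NA_integer_
  list(a1 = lo, a2 = hi)
}

#' Read a wide-format genotype CSV
#'
#' Expects a header `id`, `population`, then two columns per panel locus
#' named `<locus>.1` and `<locus>.2`. Missing alleles may be coded as an
#' empty cell or `0`; a locus with either allele missing is treated as
#' wholly missing.
#'
#' @param path Path to the CSV file.
#' @param panel An [mhc_panel()].
#' @return An `mhc_data` object (no pedigree attached).
#' @export
read_genotypes <- function(path, panel = default_panel()) {
  wide <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  names(wide) <- trimws(names(wide))
  mhc_data(wide, panel = panel)
}

#' Attach a pedigree to a dataset
#'
#' @param data An `mhc_data` object.
#' @param pedigree Data frame with columns `id`, `sire`, `dam`; blank or `NA`
#'   means unknown. Every non-blank id must exist in the dataset; pedigree
#'   cycles (including self-parents) are rejected. An individual is an
#'   offspring iff at least one parent is recorded.
#' @return `data` with the pedigree attached.
#' @export
attach_pedigree <- function(data, pedigree) {
  stopifnot(inherits(data, "mhc_data"))
  ped <- tibble::as_tibble(pedigree)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  clean <- function(x) {
    x <- trimws(as.character(x))
    x[!nzchar(x) | is.na(x)] <- NA_character_
    x
  }
  ped$id <- clean(ped$id)
  ped$sire <- clean(ped$sire)
  ped$dam <- clean(ped$dam)
  known <- data$pedigree$id
  refs <- unique(stats::na.omit(c(ped$id, ped$sire, ped$dam)))
  missing <- setdiff(refs, known)
  if (length(missing)) {
    stop("pedigree references unknown individual(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data$pedigree
  m <- match(ped$id, out$id)
  out$sire[m] <- ped$sire
  out$dam[m] <- ped$dam
  check_pedigree_acyclic(out)
  data$pedigree <- out
  data
}

check_pedigree_acyclic <- function(ped) {
  parent_of <- function(id) {
    i <- match(id, ped$id)
    stats::na.omit(c(ped$sire[i], ped$dam[i]))
  }
  state <- stats::setNames(integer(nrow(ped)), ped$id)  # 0 new 1 open 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) {
      stop("pedigree cycle involving individual ", id, call. = FALSE)
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (p in parent_of(id)) visit(p)
    state[[id]] <<- 2L
  }
  for (id in ped$id) visit(id)
  invisible()
}

#' Read a pedigree CSV and attach it
#'
#' @param path CSV with columns `id`, `sire`, `dam` (blank = unknown).
#' @param data An `mhc_data` object.
#' @return `data` with parent links attached.
#' @export
read_pedigree <- function(path, data) {
  ped <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  attach_pedigree(data, ped)
}

#' @export
print.mhc_data <- function(x, ...) {
  n_ind <- nrow(x$pedigree)
  pops <- table(unique(x$genotypes[, c("id", "population")])$population)
  n_off <- sum(!is.na(x$pedigree$sire) | !is.na(x$pedigree$dam))
  cat("<mhc_data> ", n_ind, " individuals, ", nrow(x$panel), " loci, ",
      length(pops), " population(s)\n", sep = "")
  cat("  populations:",
      paste(names(pops), "(", as.integer(pops), ")", collapse = ", "), "\n")
  cat("  offspring with recorded parents:", n_off, "\n")
  invisible(x)
}

#' Individuals and their population labels
#'
#' @param data An `mhc_data` object.
#' @return Tibble `id`, `population`, `sire`, `dam`, `is_offspring`.
#' @export
individuals <- function(data) {
  ind <- unique(data$genotypes[, c("id", "population")])
  out <- dplyr::left_join(ind, data$pedigree, by = "id")
  out$is_offspring <- !is.na(out$sire) | !is.na(out$dam)
  tibble::as_tibble(out)
}

# genotype matrix helpers used by phasing/event code -------------------------

# returns list of L x 2 integer matrices keyed by individual id (map order)
genotype_matrices <- function(data) {
  g <- data$genotypes
  ids <- unique(g$id)
  L <- nrow(data$panel)
  g <- g[order(match(g$id, ids), match(g$locus, data$panel$locus)), ]
  a1 <- matrix(g$a1, nrow = L)
  a2 <- matrix(g$a2, nrow = L)
  out <- lapply(seq_along(ids), function(i) cbind(a1[, i], a2[, i]))
  names(out) <- ids
  out
}
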