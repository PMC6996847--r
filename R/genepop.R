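#' Export a dataset as a Genepop 4.x text file
#'
#' Writes the classic Genepop layout: a title line, one locus name per line,
#' then one `Pop` block per population with individuals as
#' `id ,  001002 010010 ...` using 3-digit allele codes and `000000` for a
#' missing locus. Allele sizes in bp can exceed 999, so each observed size is
#' mapped to a rank-based code per locus (sorted ascending, starting at 001)
#' and the code-to-bp map is written to a sidecar JSON file
#' `<path>.codes.json` together with the population labels, which the
#' companion reader [read_genepop()] uses to round-trip the dataset exactly.
#'
#' @param data An `mhc_data` object.
#' @param path Output path (conventionally `.gen`).
#' @param title Title line; defaults to a short description.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(data, path,
                          title = "equimhc export: MHC microsatellite genotypes") {
  g <- data$genotypes
  panel <- data$panel
  codes <- lapply(panel$locus, function(lc) {
    sizes <- sort(unique(stats::na.omit(c(g$a1[g$locus == lc],
                                          g$a2[g$locus == lc]))))
    if (length(sizes) > 999L) {
      stop("locus ", lc, " has more than 999 distinct alleles; ",
           "cannot encode for Genepop", call. = FALSE)
    }
    sizes
  })
  names(codes) <- panel$locus
  encode <- function(lc, a) {
    vapply(seq_along(a), function(j) {
      r <- match(a[j], codes[[lc[j]]])
      if (is.na(r)) "000" else sprintf("%03d", r)
    }, character(1))
  }
  ind <- unique(g[, c("id", "population")])
  pops <- unique(ind$population)
  lines <- c(title, panel$locus)
  for (p in pops) {
    lines <- c(lines, "Pop")
    for (i in ind$id[ind$population == p]) {
      gi <- g[g$id == i, ]
      gi <- gi[match(panel$locus, gi$locus), ]
      geno <- paste0(encode(gi$locus, gi$a1), encode(gi$locus, gi$a2))
      geno[is.na(gi$a1)] <- "000000"
      lines <- c(lines, paste0(i, " ,  ", paste(geno, collapse = " ")))
    }
  }
  writeLines(lines, path)
  jsonlite::write_json(
    list(populations = pops,
         codes = lapply(codes, function(s) as.integer(s))),
    paste0(path, ".codes.json"), auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read a Genepop text file written by [write_genepop()]
#'
#' Parses the title line, the locus list and the `Pop` blocks. When the
#' sidecar `<path>.codes.json` is present, allele codes are decoded back to
#' bp sizes and population labels restored; otherwise the 3-digit codes are
#' kept as allele values and populations are labelled `Pop1`, `Pop2`, ...
#'
#' @param path Path to a `.gen` file.
#' @param panel Optional [mhc_panel()] whose locus names must match the file;
#'   by default a panel is synthesized from the file's locus list.
#' @return An `mhc_data` object.
#' @export
read_genepop <- function(path, panel = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("not a Genepop file: no Pop line after a locus list", call. = FALSE)
  }
  loci <- trimws(lines[2:(first_pop - 1L)])
  # support the one-line comma-separated locus variant
  if (length(loci) == 1L && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  sidecar <- paste0(path, ".codes.json")
  codes <- NULL
  pop_names <- NULL
  if (file.exists(sidecar)) {
    side <- jsonlite::fromJSON(sidecar)
    codes <- side$codes
    pop_names <- side$populations
  }
  if (is.null(panel)) {
    panel <- mhc_panel(tibble::tibble(
      locus = loci, mhc_class = "II", map_index = seq_along(loci)
    ))
  } else if (!identical(panel$locus, loci)) {
    stop("panel loci do not match Genepop locus list", call. = FALSE)
  }
  pop_idx <- cumsum(is_pop)
  rows <- list()
  for (k in which(pop_idx > 0 & !is_pop)) {
    ln <- lines[k]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) {
      stop("malformed Genepop individual line: ", ln, call. = FALSE)
    }
    id <- trimws(parts[1])
    gcodes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(gcodes) != length(loci)) {
      stop("individual ", id, " has ", length(gcodes),
           " genotypes for ", length(loci), " loci", call. = FALSE)
    }
    a1 <- as.integer(substr(gcodes, 1, 3))
    a2 <- as.integer(substr(gcodes, 4, 6))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    if (!is.null(codes)) {
      a1 <- vapply(seq_along(loci), function(j)
        if (is.na(a1[j])) NA_integer_ else as.integer(codes[[loci[j]]][a1[j]]),
        integer(1))
      a2 <- vapply(seq_along(loci), function(j)
        if (is.na(a2[j])) NA_integer_ else as.integer(codes[[loci[j]]][a2[j]]),
        integer(1))
    }
    pop_lab <- if (!is.null(pop_names)) pop_names[pop_idx[k]] else
      paste0("Pop", pop_idx[k])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = id, population = pop_lab, locus = loci, a1 = a1, a2 = a2
    )
  }
  mhc_data(dplyr::bind_rows(rows), panel = panel)
}
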