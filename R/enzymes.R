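#' Load a restriction-enzyme table
#'
#' Parses a tab-delimited enzyme table with columns
#' `name`, `recognition`, `cut_top`, `cut_bottom` (a header line is optional
#' and detected automatically). Cut offsets are inter-residue positions
#' measured from the 5' end of the recognition motif on its own strand
#' (`cut_top`) and on the opposite strand in the same coordinates
#' (`cut_bottom`); offsets may exceed the motif length for offset
#' (type IIS-like) cutters. A blunt cutter has `cut_top == cut_bottom`.
#' For REBASE-style `site(N/M)` notation, add the motif length to N and M.
#'
#' @param path Path to a tab-delimited enzyme table.
#' @return A tibble with columns `enzyme`, `recognition`, `cut_top`,
#'   `cut_bottom`, `blunt`, `palindromic`.
#' @export
load_enzyme_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "" & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop(sprintf("%s: empty enzyme table", path), call. = FALSE)
  first <- strsplit(lines[keep[1]], "\t")[[1]]
  if (identical(tolower(trimws(first[1])), "name")) keep <- keep[-1]
  rows <- lapply(keep, function(i) {
    f <- trimws(strsplit(lines[i], "\t")[[1]])
    if (length(f) < 4) {
      stop(sprintf("%s: expected 4 tab-delimited fields at line %d", path, i),
           call. = FALSE)
    }
    ct <- suppressWarnings(as.integer(f[3]))
    cb <- suppressWarnings(as.integer(f[4]))
    if (is.na(ct) || is.na(cb) || ct < 0 || cb < 0) {
      stop(sprintf("%s: invalid (negative or non-integer) cut offset at line %d",
                   path, i), call. = FALSE)
    }
    motif <- toupper(f[2])
    if (nchar(motif) < 4 || grepl("[^ACGTRYSWKMBDHVN]", motif)) {
      stop(sprintf("%s: invalid recognition motif '%s' at line %d (IUPAC, length >= 4)",
                   path, f[2], i), call. = FALSE)
    }
    tibble(enzyme = f[1], recognition = motif, cut_top = ct, cut_bottom = cb)
  })
  out <- dplyr::bind_rows(rows)
  dup <- out$enzyme[duplicated(out$enzyme)]
  if (length(dup)) {
    stop(sprintf("%s: duplicate enzyme name(s): %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  out$blunt <- out$cut_top == out$cut_bottom
  out$palindromic <- vapply(out$recognition, is_palindromic, logical(1),
                            USE.NAMES = FALSE)
  out
}

#' Bundled default enzyme table
#'
#' Roughly two dozen common 4-6 bp cutters plus the two assay enzymes:
#' NaeI (GCC^GGC, blunt, offsets 3/3) and SfaNI (GCATC with scission 5 nt past
#' the motif on the top strand and 9 nt on the bottom, stored as offsets
#' 10/14 from the motif 5' end).
#'
#' @param names Optional character vector restricting (and ordering) the
#'   returned enzymes; unknown names are an error.
#' @return A tibble as from [load_enzyme_table()].
#' @export
default_enzymes <- function(names = NULL) {
  tab <- load_enzyme_table(system.file("extdata", "enzymes.tsv",
                                       package = "rflpkit", mustWork = TRUE))
  if (is.null(names)) return(tab)
  missing <- setdiff(names, tab$enzyme)
  if (length(missing)) {
    stop(sprintf("unknown enzyme(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tab[match(names, tab$enzyme), ]
}

# normalize an enzyme argument: a tibble row set, or character names resolved
# against the bundled table
as_enzyme_table <- function(enzymes) {
  if (is.character(enzymes)) return(default_enzymes(enzymes))
  stopifnot(is.data.frame(enzymes),
            all(c("enzyme", "recognition", "cut_top", "cut_bottom") %in% names(enzymes)))
  if (!"palindromic" %in% names(enzymes)) {
    enzymes$palindromic <- vapply(enzymes$recognition, is_palindromic,
                                  logical(1), USE.NAMES = FALSE)
  }
  if (!"blunt" %in% names(enzymes)) {
    enzymes$blunt <- enzymes$cut_top == enzymes$cut_bottom
  }
  enzymes
}
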