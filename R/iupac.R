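#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom ggplot2 autoplot
NULL

# IUPAC nucleotide codes as bitmasks over the concrete bases A=1, C=2, G=4, T=8.
# Two codes are compatible iff their base sets intersect, i.e. bitwAnd() != 0.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

IUPAC_LETTERS <- names(IUPAC_BITS)

# complement swaps A<->T and C<->G within each base set
IUPAC_COMP_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_COMP_TO   <- "TGCAYRSWMKVHDBN"

# fast ASCII -> bitmask lookup (0 marks a non-IUPAC character)
.iupac_tab <- local({
  tab <- integer(128)
  tab[utf8ToInt(paste(IUPAC_LETTERS, collapse = ""))] <- unname(IUPAC_BITS)
  tab
})

# integer bitmask vector for one residue string; non-IUPAC characters -> error
seq_bits <- function(residues, what = "sequence") {
  ints <- utf8ToInt(residues)
  if (any(ints > 127L) || any(.iupac_tab[ints] == 0L)) {
    bad <- strsplit(residues, "")[[1]]
    bad <- unique(bad[!bad %in% IUPAC_LETTERS])
    stop(sprintf("non-IUPAC character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  .iupac_tab[ints]
}

#' Canonicalize a nucleotide sequence
#'
#' Uppercases, strips whitespace and digits, maps U to T (with a warning) and
#' verifies that every remaining character is a 15-letter IUPAC nucleotide code
#' (optionally allowing `-` gaps).
#'
#' @param x Character vector of sequences.
#' @param allow_gap Permit `-` gap characters (for alignment rows).
#' @return Canonicalized character vector.
#' @export
canonicalize_seq <- function(x, allow_gap = FALSE) {
  x <- toupper(gsub("[[:space:][:digit:]]", "", x))
  if (any(grepl("U", x, fixed = TRUE))) {
    warning("'U' residues mapped to 'T'", call. = FALSE)
    x <- gsub("U", "T", x, fixed = TRUE)
  }
  pat <- if (allow_gap) "[^ACGTRYSWKMBDHVN-]" else "[^ACGTRYSWKMBDHVN]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    offending <- setdiff(unique(unlist(strsplit(x[bad], ""))),
                         c(IUPAC_LETTERS, if (allow_gap) "-"))
    stop(sprintf("non-IUPAC character(s) in sequence: %s",
                 paste(offending, collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(x))) stop("empty sequence", call. = FALSE)
  x
}

#' Do two IUPAC codes match?
#'
#' Two codes match iff their concrete-base sets intersect, so a concrete base
#' matches any degenerate code containing it, and two degenerate codes match
#' when they share at least one base. Symmetric by construction. Vectorized
#' with the usual recycling.
#'
#' @param base,pattern Single characters (or equal-length character vectors)
#'   from the IUPAC alphabet.
#' @return Logical vector.
#' @examples
#' iupac_match("A", "N")
#' iupac_match(c("G", "C"), "R")
#' @export
iupac_match <- function(base, pattern) {
  b <- .iupac_tab[utf8ToInt(paste(toupper(base), collapse = ""))]
  p <- .iupac_tab[utf8ToInt(paste(toupper(pattern), collapse = ""))]
  if (any(b == 0L)) stop("non-IUPAC character in `base`", call. = FALSE)
  if (any(p == 0L)) stop("non-IUPAC character in `pattern`", call. = FALSE)
  bitwAnd(b, p) > 0L
}

#' Reverse complement
#'
#' IUPAC-correct reverse complementation (R<->Y, S<->S, W<->W, K<->M, B<->V,
#' D<->H, N<->N). An involution: `revcomp(revcomp(x))` equals `x`.
#'
#' @param x Character vector of IUPAC nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' revcomp("GCATC")
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  ok <- !grepl("[^ACGTRYSWKMBDHVN]", x)
  if (!all(ok)) stop("non-IUPAC character in sequence", call. = FALSE)
  comp <- chartr(IUPAC_COMP_FROM, IUPAC_COMP_TO, x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# All 0-based start positions where `pattern` IUPAC-matches a window of
# `subject`. Both are plain residue strings; returns integer(0) when the
# pattern is longer than the subject.
scan_iupac <- function(subject, pattern) {
  sb <- seq_bits(subject, "subject")
  pb <- seq_bits(pattern, "pattern")
  np <- length(pb)
  n <- length(sb) - np + 1L
  if (n < 1L) return(integer(0))
  ok <- rep(TRUE, n)
  for (j in seq_len(np)) {
    ok <- ok & bitwAnd(sb[j:(j + n - 1L)], pb[j]) > 0L
  }
  which(ok) - 1L
}

# Per-window IUPAC mismatch counts of `pattern` against `subject`
# (0-based window starts); used by primer-site search.
scan_mismatches <- function(subject, pattern) {
  sb <- seq_bits(subject, "subject")
  pb <- seq_bits(pattern, "pattern")
  np <- length(pb)
  n <- length(sb) - np + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (j in seq_len(np)) {
    mm <- mm + as.integer(bitwAnd(sb[j:(j + n - 1L)], pb[j]) == 0L)
  }
  mm
}

# is the motif its own reverse complement, set-wise?
is_palindromic <- function(motif) identical(toupper(motif), revcomp(motif))

ungap <- function(x) gsub("-", "", x, fixed = TRUE)
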