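# Independent oracles used across the suite. These deliberately avoid the
# package's bitmask scanning path: IUPAC codes are explicit base sets and
# scans are naive per-offset loops.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

set_match <- function(a, b) {
  length(intersect(iupac_sets[[a]], iupac_sets[[b]])) > 0
}

# every 0-based offset (plus strand) where the motif set-matches the sequence
naive_plus_matches <- function(seq, motif) {
  sc <- strsplit(seq, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  n <- length(sc) - length(mc) + 1
  if (n < 1) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in seq_along(mc)) {
      if (!set_match(sc[i + j - 1], mc[j])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# both-strand recognition matches as tibble(start(1-based), strand),
# palindromes reported once (plus)
naive_both_strand <- function(seq, motif) {
  plus <- naive_plus_matches(seq, motif)
  rc <- revcomp(motif)
  minus <- if (identical(rc, toupper(motif))) integer(0) else
    naive_plus_matches(seq, rc)
  tibble::tibble(
    start = c(plus, minus) + 1L,
    strand = rep(c("+", "-"), c(length(plus), length(minus)))
  )
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

ref_haps <- function(...) its_reference_haplotypes(...)

# a constructed observed lane from sizes (+ intensities)
lane_of <- function(sizes, intensities = rep(1, length(sizes)),
                    weak = NULL) {
  if (is.null(weak)) {
    weak <- if (length(intensities)) {
      intensities < 0.05 * max(intensities)
    } else logical(0)
  }
  tibble::tibble(size = sizes, intensity = intensities, weak = weak)
}
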