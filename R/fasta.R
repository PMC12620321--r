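#' Read sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a tibble.
#' Residues are canonicalized: uppercased, whitespace and digits stripped,
#' `U` mapped to `T` with a warning, and validated against the 15-letter IUPAC
#' alphabet. Gaps (`-`) are rejected unless `gapped = TRUE` (alignment input).
#'
#' @param path Path to a FASTA file.
#' @param gapped Allow `-` gap characters (gapped FASTA alignments).
#' @return A tibble with columns `id`, `description` and `seq`, one row per
#'   record.
#' @export
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  nonblank <- which(trimws(lines) != "")
  if (length(hdr) == 0) {
    stop(sprintf("%s: no FASTA header found (line 1)", path), call. = FALSE)
  }
  if (length(nonblank) && nonblank[1] < hdr[1]) {
    stop(sprintf("%s: sequence data before first header (line %d)",
                 path, nonblank[1]), call. = FALSE)
  }
  bad_hdr <- hdr[trimws(substring(lines[hdr], 2)) == ""]
  if (length(bad_hdr)) {
    stop(sprintf("%s: malformed (empty) FASTA header at line %d",
                 path, bad_hdr[1]), call. = FALSE)
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  recs <- lapply(seq_along(hdr), function(i) {
    body <- lines[setdiff(seq(hdr[i], ends[i]), hdr[i])]
    paste(body, collapse = "")
  })
  empty <- which(!nzchar(gsub("[[:space:]]", "", unlist(recs))))
  if (length(empty)) {
    stop(sprintf("%s: empty FASTA record at line %d", path, hdr[empty[1]]),
         call. = FALSE)
  }
  header <- trimws(substring(lines[hdr], 2))
  id <- sub("[[:space:]].*$", "", header)
  description <- ifelse(grepl("[[:space:]]", header),
                        sub("^[^[:space:]]+[[:space:]]+", "", header), "")
  tibble(
    id = id,
    description = description,
    seq = canonicalize_seq(unlist(recs), allow_gap = gapped)
  )
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq` (and optionally
#'   `description`), as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a haplotype alignment from gapped FASTA
#'
#' An alignment must have at least two rows of equal (gapped) length, and
#' ungapping any row must yield a valid IUPAC sequence. Alignment columns are
#' numbered 1-based in all reports.
#'
#' @param path Path to a gapped FASTA file.
#' @return A tibble with columns `label` and `seq` (gapped rows).
#' @export
read_alignment <- function(path) {
  x <- read_fasta(path, gapped = TRUE)
  aln <- tibble(label = x$id, seq = x$seq)
  validate_alignment(aln)
  aln
}

validate_alignment <- function(aln) {
  if (!all(c("label", "seq") %in% names(aln))) {
    stop("alignment needs columns `label` and `seq`", call. = FALSE)
  }
  if (nrow(aln) < 2) stop("alignment needs at least 2 rows", call. = FALSE)
  if (length(unique(nchar(aln$seq))) != 1) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  invisible(canonicalize_seq(ungap(aln$seq)))
}

#' Bundled synthetic ITS haplotype reference
#'
#' Returns the packaged synthetic 729-bp ITS1-5.8S-ITS2 amplicon haplotypes
#' used throughout the examples and tests. The two sequences differ at
#' position 241 (HapA `C`, HapB `T`; the HapA state completes a NaeI site) and
#' at positions 465-467 (HapA `TGC`, HapB `CAA`; the HapA state completes an
#' SfaNI site on the antisense strand). The sequences are a constructed
#' stand-in for a published licorice ITS alignment that is only available as a
#' figure: amplicon length, primer ends, variable-site positions, restriction
#' site counts and the NaeI fragment sizes (242 + 487 bp) all match the
#' published assay.
#'
#' @param include_c Also derive Haplotype C, the (T, TGC) combination: HapA
#'   with the HapB state at position 241 (NaeI site absent, SfaNI sites as in
#'   HapA).
#' @return A tibble with columns `label` and `seq` (ungapped; the sequences
#'   are equal length, so the tibble is also a valid alignment).
#' @export
its_reference_haplotypes <- function(include_c = FALSE) {
  path <- system.file("extdata", "its_haplotypes_synthetic.fasta",
                      package = "rflpkit", mustWork = TRUE)
  x <- read_fasta(path)
  aln <- tibble(label = x$id, seq = x$seq)
  if (include_c) {
    a <- aln$seq[aln$label == "HapA"]
    b <- aln$seq[aln$label == "HapB"]
    hapc <- paste0(substr(a, 1, 240), substr(b, 241, 241),
                   substr(a, 242, nchar(a)))
    aln <- dplyr::bind_rows(aln, tibble(label = "HapC", seq = hapc))
  }
  aln
}

#' Universal ITS primer pair
#'
#' The ITS5 / ITS4 universal primers used to amplify the ITS1-5.8S-ITS2
#' region, written 5' to 3'.
#'
#' @return A tibble with columns `name` and `seq`.
#' @export
its_primers <- function() {
  tibble(
    name = c("ITS5", "ITS4"),
    seq = c("GGAAGTAAAAGTCGTAACAAGG", "TCCTCCGCTTATTGATATGC")
  )
}
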