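# coerce sequences argument to tibble(id, seq); accepts a (named) character
# vector or any data frame with id/seq (or label/seq) columns
as_seq_table <- function(seqs) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    return(tibble(id = ids, seq = canonicalize_seq(unname(seqs))))
  }
  stopifnot(is.data.frame(seqs))
  nm <- names(seqs)
  idcol <- intersect(c("id", "label", "template_id"), nm)[1]
  if (is.na(idcol) || !"seq" %in% nm) {
    stop("sequences must be a character vector or a data frame with id/label and seq columns",
         call. = FALSE)
  }
  tibble(id = as.character(seqs[[idcol]]), seq = canonicalize_seq(seqs$seq))
}

#' Find restriction recognition sites
#'
#' Scans both strands for IUPAC-matching occurrences of each enzyme's
#' recognition motif. Minus-strand occurrences are located as matches of the
#' reverse-complemented motif on the plus strand; palindromic motifs are
#' reported once per position (plus strand).
#'
#' @param seqs Sequences: a (named) character vector or a data frame with
#'   `id`/`label` and `seq` columns.
#' @param enzymes Enzymes: a tibble as from [default_enzymes()] /
#'   [load_enzyme_table()], or a character vector of names resolved against
#'   the bundled table.
#' @return A tibble with columns `id`, `enzyme`, `start` (1-based position of
#'   the motif's leftmost base on the plus strand) and `strand` (`+`/`-`).
#' @export
find_recognition_sites <- function(seqs, enzymes) {
  seqs <- as_seq_table(seqs)
  enzymes <- as_enzyme_table(enzymes)
  out <- purrr::pmap(
    list(rep(seqs$id, each = nrow(enzymes)),
         rep(seqs$seq, each = nrow(enzymes)),
         rep(seq_len(nrow(enzymes)), nrow(seqs))),
    function(id, s, k) {
      e <- enzymes[k, ]
      plus <- scan_iupac(s, e$recognition)
      minus <- if (e$palindromic) integer(0) else scan_iupac(s, revcomp(e$recognition))
      tibble(
        id = id, enzyme = e$enzyme,
        start = c(plus, minus) + 1L,
        strand = rep(c("+", "-"), c(length(plus), length(minus)))
      )
    })
  dplyr::arrange(dplyr::bind_rows(out), .data$id, .data$enzyme, .data$start)
}

#' Compute scission coordinates
#'
#' Maps recognition-site matches to top-strand scission coordinates. For a
#' plus-strand match starting at 0-based position `m`, the top strand is cut
#' at inter-residue coordinate `m + cut_top`; for a minus-strand match (motif
#' length `L`) at `m + L - cut_bottom`. Scissions falling at or beyond either
#' sequence end are discarded (they produce no fragment), and duplicate
#' coordinates are collapsed.
#'
#' @inheritParams find_recognition_sites
#' @param enzyme A single enzyme (one-row tibble or name).
#' @return A tibble with columns `id`, `enzyme`, `cut_after` (number of bases
#'   5' of the scission; an inter-residue coordinate in 1..len-1), plus
#'   `motif_start` (1-based) and `strand` of the occurrence responsible (the
#'   first, when several coincide).
#' @export
cut_positions <- function(seqs, enzyme) {
  seqs <- as_seq_table(seqs)
  enzyme <- as_enzyme_table(enzyme)
  stopifnot(nrow(enzyme) == 1)
  sites <- find_recognition_sites(seqs, enzyme)
  len <- stats::setNames(nchar(seqs$seq), seqs$id)
  L <- nchar(enzyme$recognition)
  sites$cut_after <- ifelse(sites$strand == "+",
                            sites$start - 1L + enzyme$cut_top,
                            sites$start - 1L + L - enzyme$cut_bottom)
  sites <- sites[sites$cut_after > 0 & sites$cut_after < len[sites$id], ]
  sites <- dplyr::arrange(sites, .data$id, .data$cut_after)
  dplyr::distinct(sites, .data$id, .data$cut_after, .keep_all = TRUE)[
    , c("id", "enzyme", "cut_after", "start", "strand")] |>
    dplyr::rename(motif_start = "start")
}

#' Complete restriction digestion
#'
#' Digests each sequence with one or more enzymes (complete digestion):
#' scission coordinates from all enzymes are pooled and fragments are the
#' intervals between consecutive coordinates. Fragment lengths follow the
#' top-strand scission convention, so they tile the sequence exactly. A
#' sequence with no sites yields a single full-length fragment.
#'
#' @inheritParams find_recognition_sites
#' @return A tibble with columns `id`, `start`, `end` (1-based inclusive),
#'   `length` and `molarity` (1 per template copy), sorted by `start`.
#' @examples
#' digest(c(x = "AAGCCGGCTT"), "NaeI")
#' @export
digest <- function(seqs, enzymes) {
  seqs <- as_seq_table(seqs)
  enzymes <- as_enzyme_table(enzymes)
  if (nrow(enzymes) < 1) stop("need at least one enzyme", call. = FALSE)
  cuts <- dplyr::bind_rows(lapply(seq_len(nrow(enzymes)), function(k) {
    cut_positions(seqs, enzymes[k, ])
  }))
  purrr::map2(seqs$id, nchar(seqs$seq), function(id, len) {
    cc <- sort(unique(cuts$cut_after[cuts$id == id]))
    bounds <- c(0L, cc, len)
    tibble(
      id = id,
      start = bounds[-length(bounds)] + 1L,
      end = bounds[-1],
      length = diff(bounds),
      molarity = 1
    )
  }) |> dplyr::bind_rows()
}

#' Digest a (possibly heterozygous) genotype
#'
#' Digests each allele completely, scaling fragment molarity by
#' `dosage * (1 - uncut_fraction)`, and adds a full-length undigested species
#' at `dosage * uncut_fraction` per allele to model incomplete digestion.
#' A heterozygote's observable band pattern is the union of its alleles'
#' patterns; combine by length with [band_multiset()] or resolve on a gel
#' with [resolve_bands()].
#'
#' @param alleles A data frame with columns `id`/`label`, `seq` and optionally
#'   `dosage` (default 1 per allele), or a (named) character vector.
#' @inheritParams find_recognition_sites
#' @param uncut_fraction Fraction of template copies left undigested, in
#'   `[0, 1)`.
#' @return A tibble with columns `allele`, `start`, `end`, `length`,
#'   `molarity`.
#' @export
digest_genotype <- function(alleles, enzymes, uncut_fraction = 0) {
  if (is.data.frame(alleles) && nrow(alleles) == 0) {
    stop("empty allele list", call. = FALSE)
  }
  if (is.character(alleles) && length(alleles) == 0) {
    stop("empty allele list", call. = FALSE)
  }
  dosage <- if (is.data.frame(alleles) && "dosage" %in% names(alleles)) {
    alleles$dosage
  } else NULL
  seqs <- as_seq_table(alleles)
  if (is.null(dosage)) dosage <- rep(1, nrow(seqs))
  if (any(dosage <= 0)) stop("dosages must be > 0", call. = FALSE)
  if (uncut_fraction < 0 || uncut_fraction >= 1) {
    stop("uncut_fraction must be in [0, 1)", call. = FALSE)
  }
  # alleles may share an id (e.g. a homozygote given twice); digest per row
  frags <- lapply(seq_len(nrow(seqs)), function(i) {
    f <- digest(seqs[i, ], enzymes)
    f$molarity <- dosage[i] * (1 - uncut_fraction)
    if (uncut_fraction > 0) {
      f <- dplyr::bind_rows(f, tibble(
        id = seqs$id[i], start = 1L, end = nchar(seqs$seq[i]),
        length = nchar(seqs$seq[i]), molarity = dosage[i] * uncut_fraction
      ))
    }
    f
  })
  out <- dplyr::bind_rows(frags)
  # merge coincident species (an uncut allele plus its uncut_fraction copy)
  out <- dplyr::summarise(
    dplyr::group_by(out, allele = .data$id, .data$start, .data$end, .data$length),
    molarity = sum(.data$molarity), .groups = "drop"
  )
  dplyr::arrange(out, .data$allele, .data$start)
}

#' Combine fragments into a band multiset
#'
#' Sums molarity over identical fragment lengths (no gel resolution applied;
#' see [resolve_bands()] for co-migration).
#'
#' @param fragments A fragment tibble from [digest()] or [digest_genotype()].
#' @return A tibble with columns `length` and `molarity`, sorted by
#'   decreasing length.
#' @export
band_multiset <- function(fragments) {
  dplyr::summarise(dplyr::group_by(fragments, .data$length),
                   molarity = sum(.data$molarity), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$length))
}
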