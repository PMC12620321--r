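# map 1-based ungapped positions to 1-based alignment columns for one gapped row
aln_col_of_ungapped <- function(gapped_row) {
  chars <- strsplit(gapped_row, "")[[1]]
  which(chars != "-")
}

#' Find variable sites in a haplotype alignment
#'
#' Reports maximal runs of adjacent alignment columns at which the rows are
#' not all identical; a run of consecutive variable columns is one site.
#' Sites involving gap characters are flagged as indels. Columns are 1-based.
#'
#' @param aln An alignment tibble with columns `label` and `seq` (gapped rows
#'   of equal length), e.g. from [read_alignment()].
#' @return A tibble with columns `site` (name, e.g. `"site241"` or
#'   `"site465_467"`), `start_col`, `end_col`, `is_indel` and `residues`
#'   (list-column of named per-haplotype residue strings).
#' @export
find_variable_sites <- function(aln) {
  validate_alignment(aln)
  mat <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  differs <- apply(mat, 2, function(col) length(unique(col)) > 1)
  if (!any(differs)) {
    return(tibble(site = character(), start_col = integer(),
                  end_col = integer(), is_indel = logical(),
                  residues = list()))
  }
  r <- rle(differs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  purrr::map(runs, function(k) {
    cols <- starts[k]:ends[k]
    res <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    names(res) <- aln$label
    tibble(
      site = if (length(cols) == 1) paste0("site", cols) else
        paste0("site", cols[1], "_", cols[length(cols)]),
      start_col = cols[1],
      end_col = cols[length(cols)],
      is_indel = any(mat[, cols] == "-"),
      residues = list(res)
    )
  }) |> dplyr::bind_rows()
}

#' Band-size signature of a sequence under one enzyme
#'
#' Digest, resolve on the virtual gel, and report the canonical signature:
#' band sizes rounded to whole bp, in decreasing order. Deterministic.
#'
#' @param seq A single sequence (character).
#' @param enzyme A single enzyme (one-row tibble or name).
#' @param params A [gel_params()] object.
#' @return Numeric vector of band sizes, decreasing.
#' @export
pattern_signature <- function(seq, enzyme, params = gel_params()) {
  frags <- digest(c(x = seq), enzyme)
  round(resolve_bands(frags, params)$size)
}

signature_key <- function(sizes) paste(sizes, collapse = ",")

#' Discover enzymes that discriminate haplotypes
#'
#' Computes each candidate enzyme's band signature for every (ungapped)
#' haplotype and keeps enzymes whose signatures differ for at least one
#' haplotype pair. Each diagnostic enzyme is annotated with the variable
#' sites its differential recognition matches overlap (the CAPS polymorphism
#' responsible), the discriminated pairs, and the per-haplotype signatures.
#'
#' @param aln An alignment tibble (`label`, `seq`).
#' @param enzymes Candidate enzymes (tibble or character names; default the
#'   bundled table).
#' @param params A [gel_params()] object.
#' @return A tibble with columns `enzyme`, `n_pairs`, `pairs` (list),
#'   `signatures` (list of named size vectors) and `sites` (list of variable
#'   site names overlapped by differential matches), sorted by decreasing
#'   `n_pairs` then name. Zero rows if nothing discriminates.
#' @export
diagnostic_enzymes <- function(aln, enzymes = default_enzymes(),
                               params = gel_params()) {
  validate_alignment(aln)
  enzymes <- as_enzyme_table(enzymes)
  labs <- aln$label
  seqs <- stats::setNames(ungap(aln$seq), labs)
  vs <- find_variable_sites(aln)
  colmap <- lapply(stats::setNames(aln$seq, labs), aln_col_of_ungapped)

  out <- purrr::map(seq_len(nrow(enzymes)), function(k) {
    e <- enzymes[k, ]
    sigs <- lapply(seqs, pattern_signature, enzyme = e, params = params)
    keys <- vapply(sigs, signature_key, character(1))
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    disc <- purrr::keep(pairs, ~ keys[.x[1]] != keys[.x[2]])
    if (!length(disc)) return(NULL)
    # alignment-column intervals of recognition matches per haplotype
    L <- nchar(e$recognition)
    match_cols <- lapply(labs, function(lb) {
      hits <- find_recognition_sites(seqs[lb], e)
      if (!nrow(hits)) return(character(0))
      vapply(seq_len(nrow(hits)), function(i) {
        cols <- colmap[[lb]][hits$start[i]:(hits$start[i] + L - 1L)]
        paste(min(cols), max(cols), hits$strand[i], sep = ":")
      }, character(1))
    })
    names(match_cols) <- labs
    hit_sites <- character(0)
    for (pr in disc) {
      diffm <- c(setdiff(match_cols[[pr[1]]], match_cols[[pr[2]]]),
                 setdiff(match_cols[[pr[2]]], match_cols[[pr[1]]]))
      for (m in diffm) {
        f <- as.integer(strsplit(m, ":")[[1]][1:2])
        ov <- vs$site[vs$start_col <= f[2] & vs$end_col >= f[1]]
        hit_sites <- union(hit_sites, ov)
      }
    }
    tibble(
      enzyme = e$enzyme,
      n_pairs = length(disc),
      pairs = list(vapply(disc, paste, character(1), collapse = "|")),
      signatures = list(sigs),
      sites = list(hit_sites)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(out))
  if (!nrow(out)) return(out)
  dplyr::arrange(out, dplyr::desc(.data$n_pairs), .data$enzyme)
}

#' Enumerate genotype classes for an alignment
#'
#' All homozygotes plus all pairwise heterozygotes of the haplotypes in an
#' alignment. A heterozygote's label is `"<a>/<b>"`.
#'
#' @param labels Haplotype labels.
#' @return A tibble with columns `class` and `alleles` (list of label pairs).
#' @export
genotype_classes <- function(labels) {
  homo <- tibble(class = labels, alleles = lapply(labels, function(l) c(l, l)))
  if (length(labels) < 2) return(homo)
  hets <- utils::combn(labels, 2, simplify = FALSE)
  dplyr::bind_rows(homo, tibble(
    class = vapply(hets, paste, character(1), collapse = "/"),
    alleles = hets
  ))
}

# signature of a genotype class under one enzyme: 1:1 dosage union after gel
# resolution, sizes rounded and decreasing
class_signature <- function(alleles, seqs, enzyme, params) {
  frags <- digest_genotype(
    tibble(id = alleles, seq = unname(seqs[alleles]), dosage = 1),
    enzyme, uncut_fraction = 0
  )
  round(resolve_bands(frags, params)$size)
}

#' Select a minimal diagnostic enzyme panel
#'
#' Finds the smallest set of candidate enzymes whose joint band signatures
#' separate every distinguishable pair of genotype classes (all homozygotes
#' and pairwise heterozygotes of the alignment's haplotypes; a heterozygote's
#' signature is the 1:1 molar union of its alleles' signatures after gel
#' resolution). Pairs that no candidate separates are reported as
#' indistinguishable and excluded from the requirement. Search is exhaustive
#' over subsets for up to 12 candidates and greedy set-cover beyond; ties are
#' broken by fewest total bands across classes, then lexicographic names.
#'
#' @param aln An alignment tibble (`label`, `seq`).
#' @param candidates Candidate enzymes: a tibble from [diagnostic_enzymes()]
#'   or an enzyme tibble / character names.
#' @param params A [gel_params()] object.
#' @return A list of class `rflp_panel`: `panel` (character enzyme names),
#'   `class_signatures` (tibble class x enzyme -> signature key),
#'   `indistinguishable` (tibble of class pairs no candidate separates),
#'   `exhaustive` (logical).
#' @export
select_panel <- function(aln, candidates, params = gel_params()) {
  validate_alignment(aln)
  if (is.data.frame(candidates) && "enzyme" %in% names(candidates) &&
      !"recognition" %in% names(candidates)) {
    candidates <- candidates$enzyme
  }
  cand <- as_enzyme_table(candidates)
  if (nrow(cand) == 0) stop("no candidate enzymes", call. = FALSE)
  seqs <- stats::setNames(ungap(aln$seq), aln$label)
  classes <- genotype_classes(aln$label)

  sig <- purrr::map(seq_len(nrow(cand)), function(k) {
    vapply(classes$alleles,
           function(al) signature_key(class_signature(al, seqs, cand[k, ], params)),
           character(1))
  })
  names(sig) <- cand$enzyme
  sigtab <- tibble(class = classes$class, !!!sig)

  pairs <- utils::combn(seq_len(nrow(classes)), 2, simplify = FALSE)
  sep_by <- lapply(pairs, function(pr) {
    cand$enzyme[vapply(cand$enzyme, function(e) sig[[e]][pr[1]] != sig[[e]][pr[2]],
                       logical(1))]
  })
  separable <- lengths(sep_by) > 0
  indist <- tibble(
    class_a = vapply(pairs[!separable], function(pr) classes$class[pr[1]], character(1)),
    class_b = vapply(pairs[!separable], function(pr) classes$class[pr[2]], character(1))
  )
  need <- sep_by[separable]

  n_bands_total <- vapply(cand$enzyme, function(e) {
    sum(vapply(strsplit(sig[[e]], ","), length, integer(1)))
  }, numeric(1))

  covers_all <- function(set) {
    all(vapply(need, function(s) any(set %in% s), logical(1)))
  }
  exhaustive <- nrow(cand) <= 12
  panel <- if (!length(need)) {
    character(0)
  } else if (exhaustive) {
    found <- NULL
    for (k in seq_len(nrow(cand))) {
      subsets <- utils::combn(cand$enzyme, k, simplify = FALSE)
      ok <- purrr::keep(subsets, covers_all)
      if (length(ok)) {
        scores <- vapply(ok, function(s) sum(n_bands_total[s]), numeric(1))
        ok <- ok[scores == min(scores)]
        keys <- vapply(ok, function(s) paste(sort(s), collapse = ","), character(1))
        found <- ok[[order(keys)[1]]]
        break
      }
    }
    found
  } else {
    greedy_cover(need, cand$enzyme, n_bands_total)
  }
  structure(list(
    panel = sort(panel),
    class_signatures = sigtab,
    indistinguishable = indist,
    exhaustive = exhaustive
  ), class = "rflp_panel")
}

# greedy set cover: pick the enzyme separating the most uncovered pairs,
# ties broken by fewest total bands then name
greedy_cover <- function(need, enzymes, n_bands_total) {
  chosen <- character(0)
  uncovered <- need
  while (length(uncovered)) {
    gain <- vapply(enzymes, function(e) {
      sum(vapply(uncovered, function(s) e %in% s, logical(1)))
    }, numeric(1))
    gain[enzymes %in% chosen] <- -1
    best <- enzymes[order(-gain, n_bands_total, enzymes)][1]
    chosen <- c(chosen, best)
    uncovered <- purrr::discard(uncovered, ~ best %in% .x)
  }
  sort(chosen)
}

# greedy-only panel search over the same machinery as select_panel
# (used to cross-check the exhaustive search)
greedy_panel <- function(aln, candidates, params = gel_params()) {
  if (is.data.frame(candidates) && "enzyme" %in% names(candidates) &&
      !"recognition" %in% names(candidates)) {
    candidates <- candidates$enzyme
  }
  cand <- as_enzyme_table(candidates)
  seqs <- stats::setNames(ungap(aln$seq), aln$label)
  classes <- genotype_classes(aln$label)
  sig <- purrr::map(seq_len(nrow(cand)), function(k) {
    vapply(classes$alleles,
           function(al) signature_key(class_signature(al, seqs, cand[k, ], params)),
           character(1))
  })
  names(sig) <- cand$enzyme
  pairs <- utils::combn(seq_len(nrow(classes)), 2, simplify = FALSE)
  sep_by <- lapply(pairs, function(pr) {
    cand$enzyme[vapply(cand$enzyme, function(e) sig[[e]][pr[1]] != sig[[e]][pr[2]],
                       logical(1))]
  })
  need <- sep_by[lengths(sep_by) > 0]
  if (!length(need)) return(character(0))
  n_bands_total <- vapply(cand$enzyme, function(e) {
    sum(vapply(strsplit(sig[[e]], ","), length, integer(1)))
  }, numeric(1))
  greedy_cover(need, cand$enzyme, n_bands_total)
}

#' @export
print.rflp_panel <- function(x, ...) {
  cat("RFLP enzyme panel:", if (length(x$panel)) paste(x$panel, collapse = " + ")
      else "(none needed)", "\n")
  if (nrow(x$indistinguishable)) {
    cat("Indistinguishable class pairs:\n")
    for (i in seq_len(nrow(x$indistinguishable))) {
      cat("  ", x$indistinguishable$class_a[i], "~",
          x$indistinguishable$class_b[i], "\n")
    }
  }
  invisible(x)
}

#' Load a cleavage-type table
#'
#' Reads a tab-delimited table mapping cleavage-type labels to per-enzyme
#' band-size signatures (column `sizes` is comma-separated, decreasing).
#'
#' @param path Path to the table; default the bundled synthetic type table
#'   (types 1-4 for the licorice ITS assay: type 1 = Haplotype A pattern,
#'   type 2 = Haplotype B, type 3 = Haplotype C, type 4 = a fixture-defined
#'   relative with an extra SfaNI site).
#' @return A tibble with columns `type`, `enzyme`, `sizes` (list of numeric).
#' @export
load_cleavage_types <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cleavage_types_synthetic.tsv",
                        package = "rflpkit", mustWork = TRUE)
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "enzyme", "sizes") %in% names(x)))
  out <- tibble(
    type = as.character(x$type),
    enzyme = x$enzyme,
    sizes = lapply(strsplit(x$sizes, ","), function(s) sort(as.numeric(s),
                                                            decreasing = TRUE))
  )
  keys <- vapply(split(out, out$type), function(d) {
    paste(d$enzyme, vapply(d$sizes, signature_key, character(1)),
          collapse = ";")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("cleavage-type signatures are not pairwise distinct", call. = FALSE)
  }
  out
}

#' Classify a sequence into a cleavage type
#'
#' Computes the sequence's joint band signature under the panel enzymes and
#' matches it against a cleavage-type table: a type matches when, for every
#' panel enzyme, the band counts agree and each size agrees within a relative
#' tolerance. An unmatched signature is reported as `"novel"`.
#'
#' @param seq A single sequence (character).
#' @param panel Enzymes (tibble or character names).
#' @param table A cleavage-type tibble from [load_cleavage_types()].
#' @param params A [gel_params()] object.
#' @param size_tolerance Relative size tolerance per band.
#' @return A one-row tibble with columns `type` and `signature` (string).
#' @export
cleavage_type <- function(seq, panel, table = load_cleavage_types(),
                          params = gel_params(), size_tolerance = 0.05) {
  if (!nrow(table)) stop("empty cleavage-type table", call. = FALSE)
  panel <- as_enzyme_table(panel)
  sigs <- lapply(seq_len(nrow(panel)), function(k) {
    pattern_signature(seq, panel[k, ], params)
  })
  names(sigs) <- panel$enzyme
  sig_str <- paste(panel$enzyme, vapply(sigs, signature_key, character(1)),
                   sep = "=", collapse = "; ")
  match_sig <- function(obs, ref) {
    length(obs) == length(ref) && all(abs(obs - ref) / ref <= size_tolerance)
  }
  for (ty in unique(table$type)) {
    d <- table[table$type == ty, ]
    if (!all(panel$enzyme %in% d$enzyme)) next
    ok <- all(vapply(panel$enzyme, function(e) {
      match_sig(sigs[[e]], d$sizes[[match(e, d$enzyme)]])
    }, logical(1)))
    if (ok) return(tibble(type = ty, signature = sig_str))
  }
  tibble(type = "novel", signature = sig_str)
}
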