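#' Find primer binding sites
#'
#' Scans both strands of each template for windows matching the primer under
#' IUPAC set-intersection semantics with at most `max_mismatch` mismatching
#' positions. The primer's 3'-terminal base must match with no mismatch
#' (extension requires an annealed 3' end). A primer longer than the
#' template yields no hits (not an error).
#'
#' @param templates Templates: a (named) character vector or data frame with
#'   `id`/`label` and `seq` columns.
#' @param primer Primer sequence 5'->3' (single string, length >= 10), or a
#'   one-row tibble with `name`/`seq` as from [its_primers()].
#' @param max_mismatch Maximum number of mismatching positions (>= 0).
#' @return A tibble with columns `id`, `start` (1-based leftmost template
#'   position of the matched window on the plus strand), `strand` (`+` if
#'   the primer anneals to the minus strand and extends rightward; `-` if it
#'   anneals to the plus strand and extends leftward) and `mismatches`,
#'   sorted by `id` and `start`.
#' @export
find_primer_sites <- function(templates, primer, max_mismatch = 2) {
  stopifnot(max_mismatch >= 0)
  primer <- primer_seq(primer)
  templates <- as_seq_table(templates)
  L <- nchar(primer)
  prc <- revcomp(primer)
  out <- purrr::map2(templates$id, templates$seq, function(id, s) {
    # plus strand: primer sequence appears directly; 3' end is window end
    mm_p <- scan_mismatches(s, primer)
    # minus strand: reverse complement of primer appears on the plus strand;
    # the primer's 3' end maps to the window start
    mm_m <- scan_mismatches(s, prc)
    hit_p <- integer(0); hit_m <- integer(0)
    if (length(mm_p)) {
      ends_ok <- iupac_match(substring(s, seq_along(mm_p) + L - 1L,
                                       seq_along(mm_p) + L - 1L),
                             substr(primer, L, L))
      hit_p <- which(mm_p <= max_mismatch & ends_ok)
    }
    if (length(mm_m)) {
      starts_ok <- iupac_match(substring(s, seq_along(mm_m), seq_along(mm_m)),
                               substr(prc, 1, 1))
      hit_m <- which(mm_m <= max_mismatch & starts_ok)
    }
    tibble(
      id = id,
      start = c(hit_p, hit_m),
      strand = rep(c("+", "-"), c(length(hit_p), length(hit_m))),
      mismatches = c(mm_p[hit_p], mm_m[hit_m])
    )
  }) |> dplyr::bind_rows()
  dplyr::arrange(out, .data$id, .data$start)
}

primer_seq <- function(primer) {
  if (is.data.frame(primer)) {
    stopifnot("seq" %in% names(primer), nrow(primer) == 1)
    primer <- primer$seq
  }
  primer <- canonicalize_seq(primer)
  if (nchar(primer) < 10) stop("primer must be >= 10 nt", call. = FALSE)
  primer
}

#' Virtual PCR
#'
#' Pairs every forward-primer site on the plus strand with every
#' reverse-primer site on the minus strand lying downstream, and extracts the
#' product (reported on the forward strand, both primer-binding regions
#' included) when it does not exceed `max_len`. Zero or several products per
#' template are legal outcomes; the caller decides policy.
#'
#' @param templates Templates (character vector or data frame, as in
#'   [find_primer_sites()]).
#' @param fwd,rev Forward and reverse primers, 5'->3' (strings or one-row
#'   tibbles).
#' @param max_mismatch Mismatch budget per primer (3'-terminal base must
#'   match exactly).
#' @param max_len Maximum product length in bp.
#' @return A tibble with columns `template_id`, `start`, `end` (1-based
#'   inclusive on the template), `length` and `seq`.
#' @examples
#' \dontrun{
#' amplify(its_reference_haplotypes(), its_primers()[1, ], its_primers()[2, ])
#' }
#' @export
amplify <- function(templates, fwd, rev, max_mismatch = 2, max_len = 3000) {
  templates <- as_seq_table(templates)
  fwd <- primer_seq(fwd)
  rev <- primer_seq(rev)
  if (max_len <= max(nchar(fwd), nchar(rev))) {
    stop("max_len must exceed the primer lengths", call. = FALSE)
  }
  fh <- find_primer_sites(templates, fwd, max_mismatch)
  rh <- find_primer_sites(templates, rev, max_mismatch)
  Lf <- nchar(fwd); Lr <- nchar(rev)
  # the pair amplifies in either orientation: one primer extends rightward
  # from a plus-strand site, the other leftward from a minus-strand site
  pairings <- list(list(left = fh, llen = Lf, right = rh, rlen = Lr),
                   list(left = rh, llen = Lr, right = fh, rlen = Lf))
  out <- purrr::map2(templates$id, templates$seq, function(id, s) {
    prods <- purrr::map(pairings, function(pp) {
      f <- pp$left$start[pp$left$id == id & pp$left$strand == "+"]
      r <- pp$right$start[pp$right$id == id & pp$right$strand == "-"]
      if (!length(f) || !length(r)) return(NULL)
      grid <- expand.grid(f = f, r = r)
      grid <- grid[grid$r >= grid$f + pp$llen, , drop = FALSE]  # sites ordered
      grid$end <- grid$r + pp$rlen - 1L
      grid$len <- grid$end - grid$f + 1L
      grid[grid$len <= max_len, , drop = FALSE]
    })
    grid <- dplyr::distinct(dplyr::bind_rows(purrr::compact(prods)),
                            .data$f, .data$end, .keep_all = TRUE)
    if (!nrow(grid)) return(NULL)
    tibble(
      template_id = id,
      start = as.integer(grid$f),
      end = as.integer(grid$end),
      length = as.integer(grid$len),
      seq = substring(s, grid$f, grid$end)
    )
  }) |> dplyr::bind_rows()
  if (!nrow(out)) {
    return(tibble(template_id = character(), start = integer(),
                  end = integer(), length = integer(), seq = character()))
  }
  dplyr::arrange(out, .data$template_id, .data$start, .data$end)
}
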