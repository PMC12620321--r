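# canonical form of a site call: components uppercased, sorted, joined by "/"
normalize_site_call <- function(x) {
  vapply(strsplit(toupper(trimws(x)), "/"), function(p) {
    paste(sort(unique(trimws(p))), collapse = "/")
  }, character(1))
}

#' Call genotype classes from Sanger-style variable-site calls
#'
#' Applies the haplotype definitions at the two diagnostic ITS sites --
#' position 241 (`C` in Haplotype A, `T` in B and C) and positions 465-467
#' (`TGC` in A and C, `CAA` in B) -- to per-sample site calls. Mixed calls
#' (Sanger double peaks) are written `"C/T"`, `"CAA/TGC"` (component order
#' does not matter). The mapping:
#' (C, TGC) -> HapA; (T, CAA) -> HapB; (C/T or T, CAA/TGC) -> HetAB;
#' (C/T, TGC) -> HetAC; (T, TGC) -> HapC_or_other; anything else ->
#' Indeterminate.
#'
#' @param sites A data frame with columns `site241` and `site465_467` (one
#'   row per sample; extra columns are passed through).
#' @return The input tibble with `class` and `evidence` columns added.
#' @export
call_from_sites <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("site241", "site465_467") %in% names(sites)))
  s1 <- normalize_site_call(sites$site241)
  s2 <- normalize_site_call(sites$site465_467)
  ok1 <- s1 %in% c("C", "T", "C/T")
  ok2 <- s2 %in% c("TGC", "CAA", "CAA/TGC")
  key <- paste(s1, s2, sep = "|")
  class <- dplyr::case_when(
    !ok1 | !ok2 ~ "Indeterminate",
    key == "C|TGC" ~ "HapA",
    key == "T|CAA" ~ "HapB",
    key %in% c("C/T|CAA/TGC", "T|CAA/TGC") ~ "HetAB",
    key == "C/T|TGC" ~ "HetAC",
    key == "T|TGC" ~ "HapC_or_other",
    .default = "Indeterminate"
  )
  evidence <- dplyr::case_when(
    !ok1 | !ok2 ~ "site call outside the known alphabet",
    class == "HapA" ~ "site241=C and site465_467=TGC match Haplotype A",
    class == "HapB" ~ "site241=T and site465_467=CAA match Haplotype B",
    class == "HetAB" & key == "T|CAA/TGC" ~
      "mixed 465-467 with fixed T at 241: A x B heterozygote (241 below detection)",
    class == "HetAB" ~ "double peaks at both sites: A x B heterozygote",
    class == "HetAC" ~
      "double peak at 241 with fixed TGC: A x C heterozygote (no Haplotype B)",
    class == "HapC_or_other" ~
      "T with TGC matches Haplotype C; pure C was never observed, so 'or other'",
    .default = "site combination matches no known haplotype; not inventing one"
  )
  out <- as_tibble(sites)
  out$class <- class
  out$evidence <- evidence
  out
}

#' Reference band signatures of the bundled ITS assay
#'
#' Computes, at the stated gel parameters, the expected NaeI and SfaNI band
#' signatures of the three reference haplotypes and their pairwise
#' heterozygotes from the bundled synthetic amplicons. NaeI is read on a 2%
#' gel, SfaNI on a 3% gel, following the assay protocol.
#'
#' @param params_naei,params_sfani [gel_params()] for each enzyme's gel.
#' @return A named list `list(NaeI = <named list of signatures>, SfaNI = ...)`,
#'   each signature a decreasing numeric vector; class names are `HapA`,
#'   `HapB`, `HapC`, `HapA/HapB`, `HapA/HapC`, `HapB/HapC`.
#' @export
rflp_signatures <- function(params_naei = gel_params(2),
                            params_sfani = gel_params(3)) {
  aln <- its_reference_haplotypes(include_c = TRUE)
  seqs <- stats::setNames(aln$seq, aln$label)
  classes <- genotype_classes(aln$label)
  out <- lapply(stats::setNames(c("NaeI", "SfaNI"), c("NaeI", "SfaNI")),
                function(e) {
    params <- if (e == "NaeI") params_naei else params_sfani
    sigs <- lapply(classes$alleles, class_signature, seqs = seqs,
                   enzyme = default_enzymes(e), params = params)
    stats::setNames(sigs, classes$class)
  })
  out
}

# does the lane contain a (substantial / any) band within rel tolerance of size?
lane_has_band <- function(lane, size, tol, substantial = TRUE) {
  if (is.null(lane) || nrow(lane) == 0) return(FALSE)
  hit <- abs(lane$size - size) / size <= tol
  if (substantial) hit <- hit & !lane$weak
  any(hit)
}

#' Match an observed lane against expected class signatures
#'
#' Band-for-band matching: a class matches when every signature band is
#' matched by a distinct lane band within the relative size tolerance and
#' every non-weak lane band is explained; weak lane bands may remain
#' unmatched without penalty. Among matching classes, exact band-count
#' matches are preferred. Unexplained bands are returned as the residual.
#'
#' @param lane An observed lane: tibble with columns `size`, `intensity`
#'   and optionally `weak` (default: intensity < 5% of lane max).
#' @param expected A named list of signature size vectors, one per class.
#' @param size_tolerance Relative size tolerance.
#' @return A one-row tibble with columns `class` (best match, or
#'   `"Indeterminate"`), `residual` (list of unexplained sizes) and
#'   `n_matched`.
#' @export
match_pattern <- function(lane, expected, size_tolerance = 0.1) {
  if (!length(expected)) stop("empty expected signature map", call. = FALSE)
  lane <- as_tibble(lane)
  if (nrow(lane) && !"weak" %in% names(lane)) {
    lane$weak <- lane$intensity < 0.05 * max(lane$intensity)
  }
  score_class <- function(sig) {
    used <- rep(FALSE, nrow(lane))
    matched <- 0L
    for (s in sig) {
      cand <- which(!used & abs(lane$size - s) / s <= size_tolerance)
      if (length(cand)) {
        used[cand[which.min(abs(lane$size[cand] - s))]] <- TRUE
        matched <- matched + 1L
      }
    }
    residual <- lane$size[!used & !lane$weak]
    list(full = matched == length(sig) && length(residual) == 0,
         exact = matched == length(sig) && sum(!lane$weak) == length(sig),
         matched = matched, residual = lane$size[!used])
  }
  if (nrow(lane) == 0) {
    return(tibble(class = "Indeterminate", residual = list(numeric(0)),
                  n_matched = 0L))
  }
  scores <- lapply(expected, score_class)
  full <- vapply(scores, `[[`, logical(1), "full")
  if (!any(full)) {
    return(tibble(class = "Indeterminate",
                  residual = list(lane$size), n_matched = 0L))
  }
  cand <- names(expected)[full]
  exact <- vapply(scores[cand], `[[`, logical(1), "exact")
  best <- if (any(exact)) cand[exact][1] else cand[1]
  tibble(class = best, residual = list(scores[[best]]$residual),
         n_matched = scores[[best]]$matched)
}

#' Call a genotype from SfaNI and NaeI lanes
#'
#' The two-step identification workflow: SfaNI first excludes individuals
#' carrying the Haplotype B allele (its 465-467 `CAA` state removes one SfaNI
#' site, so B-containing lanes show the B-specific large band), then NaeI
#' confirms Haplotype A (its 241 `C` state creates the single NaeI site; a
#' fully cut lane with only residual uncut template below the intensity
#' threshold is A, while a substantial uncut band beside the cut bands
#' reveals a heterozygote). Marker band sizes are taken from `signatures`,
#' so the caller adapts to any re-computed reference.
#'
#' Decision table (A-bands = SfaNI bands unique to the A pattern; B-band =
#' SfaNI band unique to the B pattern; cut/uncut = NaeI 487+242 / 729):
#' * SfaNI B-only, NaeI uncut -> `HapB`
#' * SfaNI six-band (A+B), NaeI cut+uncut -> `HetAB`
#' * SfaNI B-only plus weak A-band -> `HetAB`, subtype `B-type`
#' * SfaNI A-only, NaeI cut with uncut/cut intensity ratio < threshold -> `HapA`
#' * SfaNI A-only, NaeI cut plus substantial uncut -> `HetAC`
#' * SfaNI A-only, NaeI uncut only -> `HapC_or_other`
#' * contradictory lanes -> `Indeterminate` (never a silent guess)
#'
#' One lane may be `NULL`; single-lane calls carry degraded confidence noted
#' in the evidence and fall back to `Indeterminate` where the single enzyme
#' cannot decide.
#'
#' @param sfani,naei Observed lanes: tibbles with columns `size`, `intensity`
#'   and optionally `weak`.
#' @param intensity_threshold Maximum uncut(729)/cut(487) NaeI area ratio for
#'   a pure Haplotype A call.
#' @param size_tolerance Relative band size tolerance.
#' @param signatures Reference signatures from [rflp_signatures()].
#' @return A one-row tibble: `class`, `subtype` (`A-type`/`B-type`/`even` or
#'   `NA`), `evidence` (list of rule firings).
#' @export
call_genotype <- function(sfani, naei, intensity_threshold = 0.2,
                          size_tolerance = 0.1,
                          signatures = rflp_signatures()) {
  prep <- function(lane) {
    if (is.null(lane)) return(NULL)
    lane <- as_tibble(lane)
    if (nrow(lane) && !"weak" %in% names(lane)) {
      lane$weak <- lane$intensity < 0.05 * max(lane$intensity)
    }
    lane
  }
  sfani <- prep(sfani)
  naei <- prep(naei)
  ev <- character(0)
  note <- function(msg) ev <<- c(ev, msg)

  sigA_sf <- signatures$SfaNI$HapA
  sigB_sf <- signatures$SfaNI$HapB
  a_marks <- setdiff(sigA_sf, sigB_sf)   # e.g. 276, 121
  b_marks <- setdiff(sigB_sf, sigA_sf)   # e.g. 397
  uncut_size <- max(signatures$NaeI$HapB)              # 729
  cut_sizes <- setdiff(signatures$NaeI$HapA, uncut_size)  # 487, 242
  cut_main <- max(cut_sizes)                            # 487

  # --- step 1: SfaNI reading ---------------------------------------------
  sf <- NA_character_
  if (!is.null(sfani)) {
    hasB <- any(vapply(b_marks, function(s)
      lane_has_band(sfani, s, size_tolerance), logical(1)))
    a_sub <- vapply(a_marks, function(s)
      lane_has_band(sfani, s, size_tolerance), logical(1))
    a_weak <- vapply(a_marks, function(s)
      lane_has_band(sfani, s, size_tolerance, substantial = FALSE), logical(1))
    if (nrow(sfani) == 0) {
      sf <- "empty"
      note("SfaNI lane empty")
    } else if (hasB && all(a_sub)) {
      sf <- "six_band"
      note("SfaNI: A- and B-specific bands both substantial (six-band pattern)")
    } else if (hasB && any(a_weak)) {
      sf <- "b_weak_a"
      note(paste0("SfaNI: B pattern plus weak A-specific band (",
                  paste(round(a_marks[a_weak & !a_sub]), collapse = "/"),
                  " bp); low-dosage A allele, possible allele imbalance"))
    } else if (hasB) {
      sf <- "b_only"
      note("SfaNI: B-specific band without A-specific bands")
    } else if (all(a_sub)) {
      sf <- "a_only"
      note("SfaNI: A-pattern only; Haplotype B excluded")
    } else {
      sf <- "other"
      note("SfaNI: pattern matches neither haplotype")
    }
  } else {
    note("no SfaNI lane: degraded confidence")
  }

  # --- step 2: NaeI reading ----------------------------------------------
  nv <- NA_character_
  ratio <- NA_real_
  if (!is.null(naei)) {
    has_cut <- all(vapply(cut_sizes, function(s)
      lane_has_band(naei, s, size_tolerance), logical(1)))
    has_uncut_any <- lane_has_band(naei, uncut_size, size_tolerance,
                                   substantial = FALSE)
    if (nrow(naei) == 0) {
      nv <- "empty"
      note("NaeI lane empty")
    } else if (has_cut) {
      iu <- naei$intensity[abs(naei$size - uncut_size) / uncut_size <= size_tolerance]
      ic <- naei$intensity[abs(naei$size - cut_main) / cut_main <= size_tolerance]
      ratio <- if (length(iu)) sum(iu) / sum(ic) else 0
      if (ratio < intensity_threshold) {
        nv <- "full_cut"
        note(sprintf("NaeI: cut bands with uncut/cut ratio %.3f < %.2f (full digestion pattern)",
                     ratio, intensity_threshold))
      } else {
        nv <- "partial"
        note(sprintf("NaeI: cut bands plus substantial uncut band (ratio %.3f >= %.2f)",
                     ratio, intensity_threshold))
      }
    } else if (has_uncut_any) {
      nv <- "uncut"
      note("NaeI: uncut band only")
    } else {
      nv <- "other"
      note("NaeI: pattern matches neither cut nor uncut template")
    }
  } else {
    note("no NaeI lane: degraded confidence")
  }

  # --- combine ------------------------------------------------------------
  call <- function(class, subtype = NA_character_) {
    tibble(class = class, subtype = subtype, evidence = list(ev))
  }
  indeterminate <- function(msg) { note(msg); call("Indeterminate") }

  if (is.null(sfani) && is.null(naei)) {
    return(indeterminate("no lanes supplied"))
  }
  if (is.null(naei)) {
    return(switch(sf,
      b_only = call("HapB"),
      six_band = call("HetAB"),
      b_weak_a = call("HetAB", "B-type"),
      a_only = indeterminate("SfaNI alone cannot separate HapA, HetAC and HapC"),
      indeterminate("uninterpretable SfaNI lane")))
  }
  if (is.null(sfani)) {
    return(switch(nv,
      full_cut = call("HapA"),
      uncut = indeterminate("NaeI uncut alone cannot separate HapB from HapC"),
      partial = indeterminate("NaeI heterozygous pattern alone cannot separate HetAB from HetAC"),
      indeterminate("uninterpretable NaeI lane")))
  }
  switch(sf,
    b_only = switch(nv,
      uncut = call("HapB"),
      full_cut = indeterminate("conflict: SfaNI shows Haplotype B but NaeI template fully cut"),
      partial = indeterminate("conflict: SfaNI shows pure B but NaeI shows cut bands"),
      indeterminate("uninterpretable NaeI lane beside SfaNI B pattern")),
    b_weak_a = switch(nv,
      uncut = call("HetAB", "B-type"),
      partial = call("HetAB", "B-type"),
      full_cut = indeterminate("conflict: SfaNI suggests B-skewed heterozygote but NaeI fully cut"),
      indeterminate("uninterpretable NaeI lane")),
    six_band = switch(nv,
      partial = call("HetAB"),
      uncut = indeterminate("conflict: SfaNI six-band proves A allele but NaeI shows no cutting"),
      full_cut = indeterminate("conflict: SfaNI six-band proves B allele but NaeI fully cut"),
      indeterminate("uninterpretable NaeI lane")),
    a_only = switch(nv,
      full_cut = call("HapA"),
      partial = call("HetAC"),
      uncut = { note("no heterozygote evidence; pure Haplotype C never observed")
                call("HapC_or_other") },
      indeterminate("uninterpretable NaeI lane beside SfaNI A pattern")),
    indeterminate("uninterpretable SfaNI lane"))
}

#' Subtype a heterozygote from allele peak proportions
#'
#' Sanger double peaks carry the relative dosage of the two alleles; the mean
#' Haplotype-A peak proportion over the variable sites classifies the
#' heterozygote as A-skewed, B-skewed or balanced.
#'
#' @param peak_ratios Numeric vector (optionally named by site) of
#'   Haplotype-A allele peak proportions, each in `[0, 1]`.
#' @param upper,lower Mean-proportion thresholds for `A-type` / `B-type`.
#' @return `"A-type"`, `"B-type"` or `"even"`.
#' @export
classify_het_subtype <- function(peak_ratios, upper = 0.6, lower = 0.4) {
  if (!length(peak_ratios)) stop("empty proportion map", call. = FALSE)
  if (any(peak_ratios < 0 | peak_ratios > 1)) {
    stop("proportions must be in [0, 1]", call. = FALSE)
  }
  m <- mean(peak_ratios)
  if (m > upper) "A-type" else if (m < lower) "B-type" else "even"
}

#' Call genotypes for a whole survey of lanes
#'
#' Groups an observed-lane table by individual and applies [call_genotype()]
#' to each individual's SfaNI and NaeI lanes.
#'
#' @param lanes A tibble with columns `id`, `enzyme`, `size`, `intensity`
#'   and optionally `weak` (e.g. from [simulate_survey()]).
#' @inheritParams call_genotype
#' @return A tibble with one row per `id`: `id`, `class`, `subtype`,
#'   `evidence`.
#' @export
call_population <- function(lanes, intensity_threshold = 0.2,
                            size_tolerance = 0.1,
                            signatures = rflp_signatures()) {
  stopifnot(all(c("id", "enzyme", "size", "intensity") %in% names(lanes)))
  ids <- unique(lanes$id)
  purrr::map(ids, function(i) {
    li <- lanes[lanes$id == i, ]
    pick <- function(e) {
      l <- li[li$enzyme == e, ]
      if (nrow(l) == 0) NULL else l
    }
    out <- call_genotype(pick("SfaNI"), pick("NaeI"),
                         intensity_threshold = intensity_threshold,
                         size_tolerance = size_tolerance,
                         signatures = signatures)
    dplyr::bind_cols(tibble(id = i), out)
  }) |> dplyr::bind_rows()
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize genotype calls over a population
#'
#' Per-class counts and percentages (one decimal place, round half up).
#'
#' @param calls A data frame with a `class` column (or a character vector of
#'   classes).
#' @return A tibble with columns `class`, `n`, `pct`, sorted by decreasing
#'   `n`.
#' @export
summarize_population <- function(calls) {
  cls <- if (is.data.frame(calls)) calls$class else as.character(calls)
  if (!length(cls)) stop("no calls to summarize", call. = FALSE)
  tab <- table(cls)
  tibble(
    class = names(tab),
    n = as.integer(tab),
    pct = round_half_up(100 * as.integer(tab) / length(cls), 1)
  ) |> dplyr::arrange(dplyr::desc(.data$n), .data$class)
}
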