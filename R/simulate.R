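#' Specify a SNP site for haplotype generation
#'
#' One variable site: a (run of) alignment column(s) starting at `at`, with a
#' per-haplotype residue string of equal length. An optional `context` string
#' is written into the shared background starting at `context_at` (1-based)
#' before the per-haplotype residues are applied, which is how a restriction
#' motif is implanted so that some haplotypes complete it and others destroy
#' it.
#'
#' @param at 1-based first column of the site.
#' @param ... Named per-haplotype residue strings (equal lengths), e.g.
#'   `HapA = "C", HapB = "T"`.
#' @param context Optional background string containing the site.
#' @param context_at 1-based start column of `context` (default `at`).
#' @return A one-row tibble consumed by [make_haplotypes()].
#' @export
snp_site <- function(at, ..., context = NULL, context_at = at) {
  res <- c(...)
  if (is.null(names(res)) || any(!nzchar(names(res)))) {
    stop("per-haplotype residues must be named", call. = FALSE)
  }
  if (length(unique(nchar(res))) != 1) {
    stop("residue strings must have equal length", call. = FALSE)
  }
  tibble(at = as.integer(at), residues = list(res),
         context = if (is.null(context)) NA_character_ else toupper(context),
         context_at = as.integer(context_at))
}

#' Generate a haplotype alignment with controlled SNPs
#'
#' Draws a shared random background (uniform A/C/G/T), writes any site
#' contexts into it, then applies each site's per-haplotype residues to
#' produce one row per haplotype. If `diagnostic_for` names enzymes, the
#' result is re-scanned and the background resampled (bounded retries) until
#' every named enzyme discriminates at least one haplotype pair -- this
#' verifies that implanted motifs survived and no background coincidence
#' neutralized them.
#'
#' @param base_length Alignment length in bp.
#' @param sites A tibble of [snp_site()] rows (may be empty / NULL for
#'   identical rows).
#' @param seed Integer seed; the result is a deterministic function of it.
#' @param labels Haplotype labels; default: the names used in `sites`
#'   (required if `sites` is empty).
#' @param diagnostic_for Character enzyme names that must come out diagnostic.
#' @param enzymes Enzyme table used for the verification scan.
#' @param params Gel parameters for the verification scan.
#' @param max_retries Maximum background resamples.
#' @return An alignment tibble (`label`, `seq`).
#' @export
make_haplotypes <- function(base_length, sites = NULL, seed = 1,
                            labels = NULL, diagnostic_for = NULL,
                            enzymes = default_enzymes(),
                            params = gel_params(), max_retries = 50) {
  if (is.null(sites) || !nrow(sites)) {
    if (is.null(labels)) stop("need labels when no sites given", call. = FALSE)
    sites <- tibble(at = integer(), residues = list(),
                    context = character(), context_at = integer())
  }
  if (is.null(labels)) {
    labels <- unique(unlist(lapply(sites$residues, names)))
  }
  site_end <- function(i) sites$at[i] + nchar(sites$residues[[i]][1]) - 1L
  if (nrow(sites) && any(vapply(seq_len(nrow(sites)), site_end, integer(1)) > base_length)) {
    stop("site columns exceed base_length", call. = FALSE)
  }
  build <- function(attempt) {
    bg <- withr::with_seed(seed + attempt, {
      paste(sample(c("A", "C", "G", "T"), base_length, replace = TRUE),
            collapse = "")
    })
    for (i in seq_len(nrow(sites))) {
      ctx <- sites$context[i]
      if (!is.na(ctx)) {
        a <- sites$context_at[i]
        substr(bg, a, a + nchar(ctx) - 1L) <- ctx
      }
    }
    rows <- vapply(labels, function(lb) {
      s <- bg
      for (i in seq_len(nrow(sites))) {
        res <- sites$residues[[i]]
        if (!lb %in% names(res)) {
          stop(sprintf("site at column %d has no residues for haplotype %s",
                       sites$at[i], lb), call. = FALSE)
        }
        substr(s, sites$at[i], site_end(i)) <- res[[lb]]
      }
      s
    }, character(1))
    tibble(label = labels, seq = unname(rows))
  }
  for (attempt in 0:max_retries) {
    aln <- build(attempt)
    if (is.null(diagnostic_for) || length(labels) < 2) return(aln)
    diag <- diagnostic_enzymes(aln, enzymes, params)
    if (all(diagnostic_for %in% diag$enzyme)) return(aln)
  }
  stop(sprintf("could not satisfy motif constraints within %d retries",
               max_retries), call. = FALSE)
}

#' Specify a simulated population
#'
#' @param freqs Named non-negative class frequencies summing to 1 (class
#'   labels are haplotype labels for homozygotes, or `HetXY` /
#'   `"<a>/<b>"` for heterozygotes).
#' @param n Number of individuals (>= 0).
#' @param seed Integer seed.
#' @param exact If `TRUE` (exact counts mode), class counts are the largest-
#'   remainder apportionment of `freqs * n` (deterministic composition);
#'   otherwise a multinomial draw (frequency mode).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(freqs, n, seed = 1, exact = TRUE) {
  if (is.null(names(freqs)) || any(!nzchar(names(freqs)))) {
    stop("freqs must be named by class", call. = FALSE)
  }
  if (any(freqs < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1", call. = FALSE)
  structure(list(freqs = freqs, n = as.integer(n), seed = as.integer(seed),
                 exact = exact), class = "population_spec")
}

#' Canonical commercial seed-lot composition
#'
#' The genotype-class composition observed when the assay was applied to 190
#' seedlings grown from a commercial seed lot: 4 Haplotype A, 59 Haplotype B,
#' 125 A x B heterozygotes and 2 A x C heterozygotes. Exact counts mode, so
#' the composition (and the 2.1% Haplotype A rate) is deterministic.
#'
#' @param seed Integer seed (affects only individual order and downstream
#'   noise draws).
#' @return A [population_spec()].
#' @export
seedlot_spec <- function(seed = 1) {
  population_spec(
    freqs = c(HapA = 4, HapB = 59, HetAB = 125, HetAC = 2) / 190,
    n = 190, seed = seed, exact = TRUE
  )
}

# resolve a class label to its two allele labels
class_alleles <- function(class, labels) {
  if (class %in% labels) return(c(class, class))
  if (grepl("/", class, fixed = TRUE)) {
    al <- strsplit(class, "/", fixed = TRUE)[[1]]
    if (length(al) == 2 && all(al %in% labels)) return(al)
  }
  if (grepl("^Het", class)) {
    suff <- strsplit(sub("^Het", "", class), "")[[1]]
    al <- paste0("Hap", suff)
    if (length(al) == 2 && all(al %in% labels)) return(al)
  }
  stop(sprintf("class label '%s' does not map to haplotypes in the alignment",
               class), call. = FALSE)
}

#' Draw a population of diploid individuals
#'
#' @param spec A [population_spec()].
#' @param alignment An alignment tibble providing the haplotype labels.
#' @return A tibble with columns `id`, `class`, `allele1`, `allele2` (ground
#'   truth carried along). In exact counts mode the class composition is the
#'   largest-remainder apportionment of `freqs * n`; in frequency mode it is
#'   multinomial. Individual order is shuffled under the spec seed.
#' @export
make_population <- function(spec, alignment) {
  stopifnot(inherits(spec, "population_spec"))
  labels <- alignment$label
  alleles <- lapply(names(spec$freqs), class_alleles, labels = labels)
  names(alleles) <- names(spec$freqs)
  if (spec$n == 0) {
    return(tibble(id = character(), class = character(),
                  allele1 = character(), allele2 = character()))
  }
  classes <- withr::with_seed(spec$seed, {
    if (spec$exact) {
      raw <- spec$freqs * spec$n
      base <- floor(raw)
      rem <- spec$n - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      sample(rep(names(spec$freqs), times = base))
    } else {
      sample(names(spec$freqs), spec$n, replace = TRUE, prob = spec$freqs)
    }
  })
  tibble(
    id = sprintf("ind%03d", seq_len(spec$n)),
    class = classes,
    allele1 = vapply(classes, function(cl) alleles[[cl]][1], character(1)),
    allele2 = vapply(classes, function(cl) alleles[[cl]][2], character(1))
  )
}

#' Simulate Sanger-style site calls for a population
#'
#' Reads each individual's residues at the alignment's variable sites:
#' homozygous sites give the plain residue string, heterozygous sites give a
#' mixed call (components sorted, joined by `/`, the double-peak notation).
#' With probability `dropout_prob` an individual suffers allele dropout: one
#' allele (chosen at random) is lost and all its sites read as homozygous for
#' the retained allele. Per-site first-allele peak proportions are drawn
#' around the 0.5 dosage with sd `prop_noise_sd` (clamped to `[0, 1]`;
#' homozygotes get 1).
#'
#' @param population A tibble from [make_population()].
#' @param alignment The alignment the alleles refer to.
#' @param dropout_prob Per-individual allele dropout probability.
#' @param prop_noise_sd Noise sd of heterozygote peak proportions.
#' @param seed Integer seed.
#' @return A tibble with `id`, one call column per variable site (named as in
#'   [find_variable_sites()]), and matching `prop_<site>` columns holding the
#'   allele-1 peak proportion.
#' @export
simulate_sites <- function(population, alignment, dropout_prob = 0,
                           prop_noise_sd = 0, seed = 1) {
  vs <- find_variable_sites(alignment)
  rows <- stats::setNames(alignment$seq, alignment$label)
  site_res <- function(allele, k) {
    vs$residues[[k]][[allele]]
  }
  withr::with_seed(seed, {
    purrr::map(seq_len(nrow(population)), function(i) {
      a1 <- population$allele1[i]
      a2 <- population$allele2[i]
      if (dropout_prob > 0 && stats::runif(1) < dropout_prob) {
        keep <- sample(c(a1, a2), 1)
        a1 <- keep; a2 <- keep
      }
      out <- list(id = population$id[i])
      for (k in seq_len(nrow(vs))) {
        r1 <- site_res(a1, k); r2 <- site_res(a2, k)
        het <- r1 != r2
        out[[vs$site[k]]] <- if (het) paste(sort(c(r1, r2)), collapse = "/") else r1
        prop <- if (het) {
          min(1, max(0, 0.5 + stats::rnorm(1, 0, prop_noise_sd)))
        } else 1
        out[[paste0("prop_", vs$site[k])]] <- prop
      }
      as_tibble(out)
    }) |> dplyr::bind_rows()
  })
}

#' Simulate a full PCR-RFLP survey
#'
#' End-to-end lane simulation for a population: each individual's alleles are
#' digested per enzyme ([digest_genotype()], with a per-enzyme uncut
#' fraction), resolved into bands on that enzyme's gel, rendered as a
#' densitometry profile with optional noise, peak-detected, and converted
#' back to an observed lane. Deterministic given `seed`.
#'
#' @param population A tibble from [make_population()].
#' @param alignment The alignment the alleles refer to (gaps removed before
#'   digestion).
#' @param enzymes Character enzyme names (resolved against the bundled
#'   table).
#' @param params Named list of [gel_params()] per enzyme; defaults to a 2%
#'   gel for NaeI and a 3% gel for SfaNI (and a 2% gel otherwise).
#' @param uncut_fraction Named per-enzyme uncut fraction (default 0).
#' @param noise Lane noise sd passed into the profiles.
#' @param seed Integer seed.
#' @return A list with elements `truth` (the population tibble), `lanes`
#'   (tibble `id`, `enzyme`, `size`, `intensity`, `weak`) and `sites` (from
#'   [simulate_sites()]).
#' @export
simulate_survey <- function(population, alignment,
                            enzymes = c("SfaNI", "NaeI"),
                            params = NULL,
                            uncut_fraction = c(NaeI = 0, SfaNI = 0),
                            noise = 0, seed = 1) {
  seqs <- stats::setNames(ungap(alignment$seq), alignment$label)
  if (is.null(params)) {
    params <- lapply(stats::setNames(enzymes, enzymes), function(e) {
      gel_params(if (e == "SfaNI") 3 else 2, run_noise_sd = noise)
    })
  }
  etab <- default_enzymes(enzymes)
  lanes <- purrr::map(seq_len(nrow(population)), function(i) {
    al <- c(population$allele1[i], population$allele2[i])
    purrr::map(enzymes, function(e) {
      uf <- if (e %in% names(uncut_fraction)) uncut_fraction[[e]] else 0
      frags <- digest_genotype(
        tibble(id = al, seq = unname(seqs[al]), dosage = 1),
        etab[etab$enzyme == e, ], uncut_fraction = uf
      )
      p <- params[[e]]
      bands <- resolve_bands(frags, p)
      prof <- synthesize_lane(bands, p,
                              seed = (seed + 7L * i + match(e, enzymes)) %% .Machine$integer.max)
      peaks <- detect_peaks(prof, peak_width = p$peak_sd)
      lane <- as_lane(peaks, p, enzyme = e)
      if (nrow(lane)) lane$id <- population$id[i]
      lane
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(lanes)) {
    lanes <- lanes[, c("id", "enzyme", "size", "intensity", "weak")]
  } else {
    lanes <- tibble(id = character(), enzyme = character(), size = numeric(),
                    intensity = numeric(), weak = logical())
  }
  sites <- if (nrow(population)) {
    simulate_sites(population, alignment, seed = seed)
  } else {
    tibble(id = character())
  }
  list(truth = population, lanes = lanes, sites = sites)
}
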