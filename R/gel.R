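#' Virtual gel parameters
#'
#' Collects the parameters of the virtual agarose gel: the migration ladder
#' (anchor sizes and distances; migration is piecewise-linear in log10 size
#' between anchors), the minimum relative size difference two fragments need
#' to run as separate bands, the densitometry peak width, and the lane noise
#' scale. Higher-percentage gels resolve small fragments better, so the
#' default resolution is 5% relative size at 2% agarose and 3% at >= 2.5%
#' agarose.
#'
#' @param agarose_pct Agarose concentration (percent w/v).
#' @param min_resolvable_rel_diff Bands whose relative size difference
#'   (gap / larger size) is below this merge into one band. Default depends on
#'   `agarose_pct` as described above.
#' @param ladder A tibble with numeric columns `size` (bp) and `distance`
#'   (migration, arbitrary units), sizes strictly decreasing with distance.
#'   Default: a 100 bp ladder, anchors 100-1000 bp.
#' @param run_noise_sd Standard deviation of additive intensity noise in
#'   synthesized lanes (intensity units; 0 = noiseless).
#' @param peak_sd Gaussian peak standard deviation in migration units.
#' @param grid_step Migration-grid step for synthesized lanes.
#' @param weak_frac Bands/peaks below this fraction of the lane maximum are
#'   flagged "weak".
#' @return An object of class `gel_params`.
#' @export
gel_params <- function(agarose_pct = 2,
                       min_resolvable_rel_diff = NULL,
                       ladder = default_ladder(),
                       run_noise_sd = 0,
                       peak_sd = 0.6,
                       grid_step = 0.05,
                       weak_frac = 0.05) {
  stopifnot(agarose_pct > 0)
  if (is.null(min_resolvable_rel_diff)) {
    min_resolvable_rel_diff <- if (agarose_pct >= 2.5) 0.03 else 0.05
  }
  stopifnot(min_resolvable_rel_diff > 0, min_resolvable_rel_diff < 1)
  stopifnot(is.data.frame(ladder), all(c("size", "distance") %in% names(ladder)))
  ladder <- ladder[order(ladder$size), ]
  if (any(diff(ladder$distance) >= 0)) {
    stop("ladder distances must strictly decrease with size", call. = FALSE)
  }
  structure(list(
    agarose_pct = agarose_pct,
    min_resolvable_rel_diff = min_resolvable_rel_diff,
    ladder = ladder,
    run_noise_sd = run_noise_sd,
    peak_sd = peak_sd,
    grid_step = grid_step,
    weak_frac = weak_frac
  ), class = "gel_params")
}

#' Default 100 bp migration ladder
#'
#' Anchors at 100-1000 bp, migration linear in log10 size between anchors
#' (1000 bp at 20 units, 100 bp at 60 units).
#'
#' @param sizes Anchor sizes in bp.
#' @return A tibble with columns `size` and `distance`.
#' @export
default_ladder <- function(sizes = seq(100, 1000, by = 100)) {
  tibble(size = sizes, distance = 20 + 40 * (3 - log10(sizes)))
}

#' Migration distance of a fragment
#'
#' Piecewise-linear interpolation of migration distance against log10(size)
#' between ladder anchors; strictly decreasing in size within the ladder span
#' and clamped (constant) beyond it.
#'
#' @param size Fragment size(s) in bp (> 0).
#' @param params A [gel_params()] object.
#' @return Numeric vector of distances.
#' @export
migration_distance <- function(size, params = gel_params()) {
  if (any(size <= 0)) stop("size must be > 0", call. = FALSE)
  lad <- params$ladder
  stats::approx(log10(lad$size), lad$distance, xout = log10(size),
                rule = 2, ties = "ordered")$y
}

# inverse of migration_distance (clamped outside the ladder span)
size_from_distance <- function(distance, params = gel_params()) {
  lad <- params$ladder[order(params$ladder$distance), ]
  10^stats::approx(lad$distance, log10(lad$size), xout = distance,
                   rule = 2, ties = "ordered")$y
}

#' Resolve fragments into gel bands
#'
#' Models co-migration: fragment sizes are merged by single linkage whenever
#' the relative gap between size-adjacent fragments is below
#' `min_resolvable_rel_diff`. Band intensity is mass-proportional
#' (`length * molarity`, as for ethidium bromide staining) normalized to the
#' lane maximum; the representative size is the molarity-weighted mean of the
#' members.
#'
#' @param fragments A tibble with columns `length` and `molarity` (from
#'   [digest()], [digest_genotype()] or [band_multiset()]; `molarity`
#'   defaults to 1 if absent).
#' @param params A [gel_params()] object.
#' @return A tibble with columns `size`, `intensity` (in (0, 1]), `mass`,
#'   `molarity`, `n_fragments` and `weak`, sorted by decreasing size. Empty
#'   input gives an empty tibble.
#' @export
resolve_bands <- function(fragments, params = gel_params()) {
  empty <- tibble(size = numeric(), intensity = numeric(), mass = numeric(),
                  molarity = numeric(), n_fragments = integer(),
                  weak = logical())
  if (is.null(fragments) || nrow(fragments) == 0) return(empty)
  if (!"molarity" %in% names(fragments)) fragments$molarity <- 1
  frg <- fragments[fragments$length > 0, c("length", "molarity")]
  if (nrow(frg) == 0) return(empty)
  frg <- frg[order(frg$length), ]
  s <- frg$length
  gap_rel <- if (length(s) > 1) diff(s) / s[-1] else numeric(0)
  grp <- cumsum(c(1L, as.integer(gap_rel >= params$min_resolvable_rel_diff)))
  out <- dplyr::summarise(
    dplyr::group_by(tibble(grp = grp, length = s, molarity = frg$molarity), .data$grp),
    size = stats::weighted.mean(.data$length, .data$molarity),
    mass = sum(.data$length * .data$molarity),
    molarity = sum(.data$molarity),
    n_fragments = dplyr::n(),
    .groups = "drop"
  )
  out$intensity <- out$mass / max(out$mass)
  out$weak <- out$intensity < params$weak_frac
  dplyr::arrange(out[, c("size", "intensity", "mass", "molarity",
                         "n_fragments", "weak")],
                 dplyr::desc(.data$size))
}

#' Synthesize a densitometry lane profile
#'
#' Renders bands as Gaussian peaks on a 1-D migration grid: each peak is
#' centred at the band's migration distance with area proportional to its
#' intensity, plus optional additive baseline noise (`run_noise_sd`), clamped
#' at zero. Reproducible given `seed`.
#'
#' @param bands A band tibble from [resolve_bands()] (columns `size`,
#'   `intensity`).
#' @param params A [gel_params()] object.
#' @param seed Integer seed for the noise draw (ignored at zero noise).
#' @return A tibble of class `lane_profile` with columns `position` and
#'   `intensity`.
#' @export
synthesize_lane <- function(bands, params = gel_params(), seed = 1) {
  lad <- params$ladder
  grid <- seq(max(0, min(lad$distance) - 10), max(lad$distance) + 10,
              by = params$grid_step)
  y <- numeric(length(grid))
  if (!is.null(bands) && nrow(bands) > 0) {
    mu <- migration_distance(bands$size, params)
    for (i in seq_len(nrow(bands))) {
      y <- y + bands$intensity[i] * stats::dnorm(grid, mu[i], params$peak_sd)
    }
  }
  if (params$run_noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(length(grid), 0, params$run_noise_sd))
    y <- pmax(y, 0)
  }
  structure(tibble(position = grid, intensity = y),
            class = c("lane_profile", "tbl_df", "tbl", "data.frame"))
}

# rolling minimum with edge padding (baseline estimate)
rolling_min <- function(y, width) {
  width <- max(3L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  zoo::rollapply(y, width, min, fill = NA, align = "center", partial = TRUE)
}

#' Detect and quantify peaks in a lane profile
#'
#' Subtracts a rolling-minimum baseline, finds local maxima above a threshold
#' (fraction of the corrected lane maximum), and integrates each peak's area
#' between its flanking minima by the trapezoid rule. If `peak_width` is
#' supplied (the nominal Gaussian sd of a single band), detections much wider
#' than one band are flagged as possible co-migrating merges.
#'
#' @param profile A `lane_profile` tibble (columns `position`, `intensity`).
#' @param baseline_window Rolling-minimum window in migration units.
#' @param threshold_frac Peak height threshold as a fraction of the corrected
#'   lane maximum.
#' @param peak_width Nominal single-band Gaussian sd (migration units), used
#'   only to flag merged peaks; `NULL` disables the flag.
#' @return A tibble with columns `position`, `height`, `area`, `fwhm`,
#'   `merged`, sorted by position. A flat profile gives zero rows.
#' @export
detect_peaks <- function(profile, baseline_window = 10, threshold_frac = 0.02,
                         peak_width = NULL) {
  stopifnot(all(c("position", "intensity") %in% names(profile)))
  x <- profile$position
  y <- profile$intensity
  if (!length(y) || max(y) <= 0) {
    return(tibble(position = numeric(), height = numeric(), area = numeric(),
                  fwhm = numeric(), merged = logical()))
  }
  step <- if (length(x) > 1) stats::median(diff(x)) else 1
  base <- rolling_min(y, baseline_window / step)
  yc <- pmax(y - base, 0)
  thr <- threshold_frac * max(yc)
  n <- length(yc)
  is_max <- c(FALSE, yc[2:(n - 1)] > yc[1:(n - 2)] & yc[2:(n - 1)] >= yc[3:n], FALSE)
  peaks_i <- which(is_max & yc >= thr & yc > 0)
  if (!length(peaks_i)) {
    return(tibble(position = numeric(), height = numeric(), area = numeric(),
                  fwhm = numeric(), merged = logical()))
  }
  # segment boundaries: minimum of yc between consecutive peaks
  bounds <- c(1L, purrr::map_int(seq_len(length(peaks_i) - 1), function(k) {
    lo <- peaks_i[k]; hi <- peaks_i[k + 1]
    lo + which.min(yc[lo:hi]) - 1L
  }), n)
  out <- purrr::map(seq_along(peaks_i), function(k) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    seg <- lo:hi
    floor_y <- min(yc[seg])
    area <- sum(diff(x[seg]) * (utils::head(yc[seg] - floor_y, -1) +
                                  utils::tail(yc[seg] - floor_y, -1)) / 2)
    h <- yc[peaks_i[k]]
    above <- seg[yc[seg] >= h / 2]
    fwhm <- if (length(above) > 1) x[max(above)] - x[min(above)] else step
    tibble(position = x[peaks_i[k]], height = h, area = area, fwhm = fwhm)
  }) |> dplyr::bind_rows()
  # two bands closer than ~1.2 sd produce one maximum; its FWHM exceeds a
  # single band's (2.3548 sd) by 20-40%, so 1.2x is the discriminating cut
  out$merged <- if (is.null(peak_width)) {
    FALSE
  } else {
    out$fwhm > 1.2 * 2.3548 * peak_width
  }
  out
}

#' Intensity ratio of two bands in a lane
#'
#' Looks up the detected peaks nearest the two target sizes (within a relative
#' size tolerance, sizes inferred from migration positions via the ladder) and
#' returns the ratio of their areas. A missing numerator peak gives 0; a
#' missing denominator peak is signalled as `NA` with a warning (the ratio is
#' undefined), never as 0.
#'
#' @param peaks A tibble from [detect_peaks()].
#' @param size_a,size_b Target band sizes in bp (numerator, denominator).
#' @param params A [gel_params()] object (for the position-to-size map).
#' @param tolerance Relative size tolerance for matching a peak to a target.
#' @return A single number: `area_a / area_b`, 0, or `NA` (undefined).
#' @export
band_intensity_ratio <- function(peaks, size_a, size_b,
                                 params = gel_params(), tolerance = 0.1) {
  match_area <- function(target) {
    if (nrow(peaks) == 0) return(NA_real_)
    sz <- size_from_distance(peaks$position, params)
    rel <- abs(sz - target) / target
    if (min(rel) > tolerance) return(NA_real_)
    sum(peaks$area[rel <= tolerance])
  }
  a <- match_area(size_a)
  b <- match_area(size_b)
  if (is.na(b) || b <= 0) {
    warning(sprintf("no peak matches denominator size %g bp: ratio undefined",
                    size_b), call. = FALSE)
    return(NA_real_)
  }
  if (is.na(a)) return(0)
  a / b
}

#' Convert detected peaks to an observed lane
#'
#' Maps peak positions back to sizes through the ladder and normalizes areas
#' to relative intensities, producing the observed-lane format consumed by
#' the genotype caller.
#'
#' @param peaks A tibble from [detect_peaks()].
#' @param params A [gel_params()] object.
#' @param enzyme Optional enzyme name annotated on the lane.
#' @return A tibble with columns `enzyme`, `size`, `intensity`, `weak`.
#' @export
as_lane <- function(peaks, params = gel_params(), enzyme = NA_character_) {
  if (nrow(peaks) == 0) {
    return(tibble(enzyme = character(), size = numeric(),
                  intensity = numeric(), weak = logical()))
  }
  intensity <- peaks$area / max(peaks$area)
  tibble(
    enzyme = enzyme,
    size = size_from_distance(peaks$position, params),
    intensity = intensity,
    weak = intensity < params$weak_frac
  )
}

#' Plot a lane profile
#'
#' @param object A `lane_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lane_profile
#' @export
autoplot.lane_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "migration distance", y = "signal intensity") +
    ggplot2::theme_minimal()
}

#' Draw a virtual gel from one or more lanes of bands
#'
#' @param lanes A tibble with columns `lane` (label), `size` and `intensity`.
#' @param params A [gel_params()] object.
#' @return A ggplot imitating a stained gel (band position by migration
#'   distance, alpha by intensity).
#' @export
plot_gel <- function(lanes, params = gel_params()) {
  stopifnot(all(c("lane", "size", "intensity") %in% names(lanes)))
  lanes$distance <- migration_distance(lanes$size, params)
  ggplot2::ggplot(lanes, ggplot2::aes(x = .data$lane, y = .data$distance,
                                      alpha = .data$intensity)) +
    ggplot2::geom_tile(width = 0.6, height = 0.6, fill = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_alpha(range = c(0.15, 1), guide = "none") +
    ggplot2::labs(x = NULL, y = "migration distance") +
    ggplot2::theme_dark()
}
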