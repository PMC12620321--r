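test_that("migration distance interpolates the ladder and decreases with size", {
  p <- gel_params()
  lad <- p$ladder
  expect_equal(migration_distance(lad$size, p), lad$distance)
  d <- migration_distance(seq(100, 1000, by = 50), p)
  expect_true(all(diff(d) < 0))
  # log-size midpoint of two anchors maps to the mean of their distances
  mid <- 10^mean(log10(c(300, 400)))
  expect_equal(migration_distance(mid, p),
               mean(migration_distance(c(300, 400), p)))
  # clamped beyond the ladder span
  expect_equal(migration_distance(50, p), migration_distance(100, p))
  expect_error(migration_distance(0, p), "size")
})

test_that("resolve_bands merges co-migrating fragments and conserves mass", {
  p <- gel_params(2)  # 5% resolution
  frg <- tibble::tibble(length = c(500, 501), molarity = c(1, 1))
  b <- resolve_bands(frg, p)
  expect_equal(nrow(b), 1)
  expect_equal(b$mass, 1001)
  expect_equal(b$n_fragments, 2L)
  # heterozygote NaeI multiset stays three bands at 2% defaults
  b3 <- resolve_bands(tibble::tibble(length = c(729, 487, 242),
                                     molarity = c(1, 1, 1)), p)
  expect_equal(nrow(b3), 3)
  expect_equal(b3$size, c(729, 487, 242))  # sorted descending
  expect_equal(sum(b3$mass), 729 + 487 + 242)
  expect_equal(nrow(resolve_bands(tibble::tibble(length = numeric(),
                                                 molarity = numeric()), p)), 0)
})

test_that("gel resolution threshold follows the agarose percentage", {
  expect_equal(gel_params(2)$min_resolvable_rel_diff, 0.05)
  expect_equal(gel_params(3)$min_resolvable_rel_diff, 0.03)
  frg <- tibble::tibble(length = c(480, 500), molarity = c(1, 1))  # 4% apart
  expect_equal(nrow(resolve_bands(frg, gel_params(2))), 1)
  expect_equal(nrow(resolve_bands(frg, gel_params(3))), 2)
})

test_that("synthesized lanes are deterministic, flat when empty, area-exact", {
  p <- gel_params()
  empty <- synthesize_lane(tibble::tibble(size = numeric(),
                                          intensity = numeric()), p)
  expect_true(all(empty$intensity == 0))
  one <- tibble::tibble(size = 500, intensity = 0.8)
  prof <- synthesize_lane(one, p)
  # numerically integrated area matches the requested area within 1%
  area <- sum(diff(prof$position) *
                (utils::head(prof$intensity, -1) + utils::tail(prof$intensity, -1)) / 2)
  expect_lt(abs(area - 0.8) / 0.8, 0.01)
  pn <- gel_params(run_noise_sd = 0.02)
  expect_identical(synthesize_lane(one, pn, seed = 9),
                   synthesize_lane(one, pn, seed = 9))
  expect_false(identical(synthesize_lane(one, pn, seed = 9)$intensity,
                         synthesize_lane(one, pn, seed = 10)$intensity))
})

test_that("detect_peaks round-trips well-separated bands within 5%", {
  p <- gel_params()
  expect_equal(nrow(detect_peaks(synthesize_lane(NULL, p))), 0)
  bands <- tibble::tibble(size = c(729, 487, 242), intensity = c(0.2, 1, 0.5))
  pk <- detect_peaks(synthesize_lane(bands, p), peak_width = p$peak_sd)
  expect_equal(nrow(pk), 3)
  want <- bands$intensity[order(migration_distance(bands$size, p))]
  expect_true(all(abs(pk$area - want) / want < 0.05))
  expect_false(any(pk$merged))
})

test_that("overlapping peaks closer than the peak width are flagged merged", {
  p <- gel_params()
  # ~1 migration unit apart vs sd 0.6: a single widened maximum
  b <- tibble::tibble(size = c(500, 530), intensity = c(0.5, 0.5))
  pk <- detect_peaks(synthesize_lane(b, p), peak_width = p$peak_sd)
  expect_equal(nrow(pk), 1)
  expect_true(pk$merged)
  single <- detect_peaks(synthesize_lane(b[1, ], p), peak_width = p$peak_sd)
  expect_false(single$merged)
})

test_that("band_intensity_ratio implements the uncut/cut intensity rule", {
  p <- gel_params()
  # no numerator peak -> 0
  pk <- detect_peaks(synthesize_lane(
    tibble::tibble(size = c(487, 242), intensity = c(1, 0.5)), p))
  expect_equal(band_intensity_ratio(pk, 729, 487, p), 0)
  # numerator = denominator -> 1
  expect_equal(band_intensity_ratio(pk, 487, 487, p), 1)
  # absent denominator is signalled, never returned as 0
  expect_warning(r <- band_intensity_ratio(pk, 487, 900, p), "undefined")
  expect_true(is.na(r))
  # a 10% uncut fraction leaves the 729 band under the 20% rule
  haps <- ref_haps()
  g <- digest_genotype(haps[1, ], "NaeI", uncut_fraction = 0.1)
  lane <- detect_peaks(synthesize_lane(resolve_bands(g, p), p))
  ratio <- band_intensity_ratio(lane, 729, 487, p)
  expect_gt(ratio, 0)
  expect_lt(ratio, 0.20)
})

test_that("as_lane maps peaks back to sizes and flags weak bands", {
  p <- gel_params()
  bands <- tibble::tibble(size = c(729, 487), intensity = c(0.03, 1))
  lane <- as_lane(detect_peaks(synthesize_lane(bands, p)), p)
  expect_equal(round(lane$size), c(729, 487))
  expect_equal(lane$weak, c(TRUE, FALSE))
})
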