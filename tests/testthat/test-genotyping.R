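test_that("site-call genotyping implements the haplotype definition table", {
  calls <- call_from_sites(tibble::tibble(
    site241     = c("C",   "T",   "C/T",     "T",       "C/T", "T",   "C",   "C",       "C/T"),
    site465_467 = c("TGC", "CAA", "CAA/TGC", "CAA/TGC", "TGC", "TGC", "CAA", "CAA/TGC", "CAA")
  ))
  expect_equal(calls$class,
               c("HapA", "HapB", "HetAB", "HetAB", "HetAC", "HapC_or_other",
                 "Indeterminate", "Indeterminate", "Indeterminate"))
  # component order in a mixed call is irrelevant; case is normalized
  expect_equal(call_from_sites(tibble::tibble(
    site241 = "t/c", site465_467 = "tgc/caa"))$class, "HetAB")
  # out-of-alphabet calls never guess
  expect_equal(call_from_sites(tibble::tibble(
    site241 = "G", site465_467 = "TGC"))$class, "Indeterminate")
})

test_that("match_pattern reads lanes band-for-band with tolerance", {
  sig <- rflp_signatures()
  expected <- sig$SfaNI
  # the published Haplotype B sizes match the B-containing class despite the
  # fixture's 227 -> 225 shared fragment (within the 10% tolerance)
  m <- match_pattern(lane_of(c(48, 59, 227, 397)), expected)
  expect_equal(m$class, "HapB")
  m6 <- match_pattern(lane_of(c(48, 59, 121, 227, 276, 397)), expected)
  expect_equal(m6$class, "HapA/HapB")
  expect_equal(match_pattern(lane_of(numeric(0)), expected)$class,
               "Indeterminate")
  # unexplained substantial bands land in the residual
  mres <- match_pattern(lane_of(c(48, 59, 227, 397, 800)), expected)
  expect_true(800 %in% mres$residual[[1]])
})

test_that("two-lane genotype calling follows the SfaNI-then-NaeI workflow", {
  sig <- rflp_signatures()
  sfA <- lane_of(c(276, 225, 121, 59, 48))
  sfB <- lane_of(c(397, 225, 59, 48))
  sf6 <- lane_of(c(397, 276, 225, 121, 59, 48))
  naeA <- lane_of(c(487, 242, 729), c(1, 0.5, 0.1))     # uncut at 10% of cut
  naeHet <- lane_of(c(729, 487, 242), c(1, 0.55, 0.27))
  naeU <- lane_of(729, 1)

  expect_equal(call_genotype(sfA, naeA, signatures = sig)$class, "HapA")
  expect_equal(call_genotype(sfB, naeU, signatures = sig)$class, "HapB")
  expect_equal(call_genotype(sf6, naeHet, signatures = sig)$class, "HetAB")
  expect_equal(call_genotype(sfA, naeHet, signatures = sig)$class, "HetAC")
  expect_equal(call_genotype(sfA, naeU, signatures = sig)$class, "HapC_or_other")

  # B pattern plus weak A-specific 276 band: B-skewed heterozygote
  sfBw <- lane_of(c(397, 276, 225, 59, 48), c(1, 0.03, 0.9, 0.2, 0.15))
  cw <- call_genotype(sfBw, naeU, signatures = sig)
  expect_equal(cw$class, "HetAB")
  expect_equal(cw$subtype, "B-type")

  # threshold behaviour of the 20% intensity rule
  nae25 <- lane_of(c(487, 242, 729), c(1, 0.5, 0.25))
  expect_equal(call_genotype(sfA, nae25, signatures = sig)$class, "HetAC")
})

test_that("contradictory lanes return Indeterminate, never a silent guess", {
  sig <- rflp_signatures()
  sfB <- lane_of(c(397, 225, 59, 48))
  naeA <- lane_of(c(487, 242), c(1, 0.5))
  cc <- call_genotype(sfB, naeA, signatures = sig)
  expect_equal(cc$class, "Indeterminate")
  expect_true(any(grepl("conflict", cc$evidence[[1]])))
  # six-band SfaNI vs uncut NaeI also conflicts
  sf6 <- lane_of(c(397, 276, 225, 121, 59, 48))
  expect_equal(call_genotype(sf6, lane_of(729), signatures = sig)$class,
               "Indeterminate")
})

test_that("single-lane calls degrade gracefully with evidence", {
  sig <- rflp_signatures()
  sfB <- lane_of(c(397, 225, 59, 48))
  one <- call_genotype(sfB, NULL, signatures = sig)
  expect_equal(one$class, "HapB")
  expect_true(any(grepl("degraded", one$evidence[[1]])))
  # SfaNI A-pattern alone cannot separate HapA / HetAC / HapC
  sfA <- lane_of(c(276, 225, 121, 59, 48))
  expect_equal(call_genotype(sfA, NULL, signatures = sig)$class,
               "Indeterminate")
  expect_equal(call_genotype(NULL, lane_of(c(487, 242), c(1, 0.5)),
                             signatures = sig)$class, "HapA")
})

test_that("heterozygote subtyping thresholds the mean allele proportion", {
  expect_equal(classify_het_subtype(c(0.5, 0.5)), "even")
  expect_equal(classify_het_subtype(c(0.8, 0.75)), "A-type")
  expect_equal(classify_het_subtype(c(0.2, 0.25)), "B-type")
  expect_equal(classify_het_subtype(0.55), "even")
  expect_error(classify_het_subtype(numeric(0)), "empty")
  expect_error(classify_het_subtype(c(0.5, 1.2)), "0, 1")
})

test_that("population summaries reproduce the worked survey percentages", {
  # the eight sequenced samples: 4 heterozygotes, 3 Haplotype B, 1 Haplotype A
  eight <- call_from_sites(tibble::tibble(
    site241     = c("C/T", "T",   "C/T", "T",       "C/T", "C",   "T",   "T"),
    site465_467 = c("CAA/TGC", "CAA", "CAA/TGC", "CAA/TGC", "CAA/TGC", "TGC", "CAA", "CAA")
  ))
  s8 <- summarize_population(eight)
  expect_equal(s8$pct[s8$class == "HetAB"], 50.0)
  expect_equal(s8$pct[s8$class == "HapB"], 37.5)
  expect_equal(s8$pct[s8$class == "HapA"], 12.5)

  # the 190-seedling composition: Haplotype A is 2.1%
  rows <- tibble::tibble(
    site241 = c("C", "T", "C/T", "C/T"),
    site465_467 = c("TGC", "CAA", "CAA/TGC", "TGC"),
    n = c(4L, 59L, 125L, 2L)
  )
  expanded <- call_from_sites(tidyr::uncount(rows, n))
  s190 <- summarize_population(expanded)
  expect_equal(sum(s190$n), 190L)
  expect_equal(s190$pct[s190$class == "HapA"], 2.1)
  expect_equal(s190$n[s190$class == "HetAB"], 125L)
  # rounded percentages stay within 0.1 of 100
  expect_lt(abs(sum(s190$pct) - 100), 0.1 + 1e-9)

  one <- summarize_population(c("HapA"))
  expect_equal(one$pct, 100.0)
})
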