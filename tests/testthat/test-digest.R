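test_that("recognition-site scanning matches the naive both-strand oracle", {
  motifs <- c("GCCGGC", "GCATC", "GANTC", "CTNAG", "GGATG")
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- random_seq(1000)
      for (m in motifs) {
        e <- tibble::tibble(enzyme = "E", recognition = m,
                            cut_top = 1L, cut_bottom = 1L)
        got <- find_recognition_sites(c(x = s), e)
        ref <- naive_both_strand(s, m)
        ref <- ref[order(ref$start), ]
        expect_equal(got$start, ref$start)
        expect_equal(got$strand, ref$strand)
      }
    }
  })
})

test_that("palindromic motifs are counted once per position", {
  hits <- find_recognition_sites(c(x = "GCCGGC"), "NaeI")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  # non-palindromic motif found on both strands by construction
  s <- paste0("TTTT", "GCATC", "TTTT", "GATGC", "TTTT")
  hits2 <- find_recognition_sites(c(x = s), "SfaNI")
  expect_equal(hits2$start, c(5L, 14L))
  expect_equal(hits2$strand, c("+", "-"))
})

test_that("cut positions follow the strand-specific offset mapping", {
  # SfaNI GCATC(5/9): plus-strand scission 10 after motif start,
  # minus-strand scission 9 left of the GATGC occurrence end
  s <- paste0(strrep("T", 10), "GCATC", strrep("T", 20))   # motif at 0-based 10
  cp <- cut_positions(c(x = s), "SfaNI")
  expect_equal(cp$cut_after, 20)
  s2 <- paste0(strrep("T", 20), "GATGC", strrep("T", 10))  # minus motif at 0-based 20
  cp2 <- cut_positions(c(x = s2), "SfaNI")
  expect_equal(cp2$cut_after, 20 + 5 - 14)
  expect_equal(cp2$strand, "-")
  # scission beyond the end is discarded
  s3 <- paste0(strrep("T", 10), "GCATC", "TT")
  expect_equal(nrow(cut_positions(c(x = s3), "SfaNI")), 0)
})

test_that("the reference haplotypes reproduce the published digestion patterns", {
  haps <- ref_haps()
  a <- haps[haps$label == "HapA", ]
  b <- haps[haps$label == "HapB", ]
  # NaeI: one site in A (242 + 487), none in B
  expect_setequal(digest(a, "NaeI")$length, c(242L, 487L))
  expect_equal(digest(b, "NaeI")$length, 729L)
  # SfaNI: 4 sites / 5 fragments in A, 3 sites / 4 fragments in B
  expect_equal(nrow(cut_positions(a, "SfaNI")), 4)
  expect_equal(nrow(cut_positions(b, "SfaNI")), 3)
  expect_equal(nrow(digest(a, "SfaNI")), 5)
  expect_equal(nrow(digest(b, "SfaNI")), 4)
  # the A-specific scission splits the B-specific large fragment exactly
  sa <- digest(a, "SfaNI")$length
  sb <- digest(b, "SfaNI")$length
  expect_setequal(setdiff(sb, sa), 397L)
  expect_equal(sum(setdiff(sa, sb)), 397L)
})

test_that("heterozygous digests union the allele patterns", {
  haps <- ref_haps()
  het <- tibble::tibble(id = haps$label, seq = haps$seq, dosage = 1)
  g_nae <- digest_genotype(het, "NaeI")
  expect_setequal(unique(g_nae$length), c(729L, 487L, 242L))
  expect_equal(length(unique(g_nae$length)), 3)
  g_sfa <- digest_genotype(het, "SfaNI")
  expect_equal(length(unique(g_sfa$length)), 6)
  # single allele with zero uncut fraction reduces to digest()
  one <- digest_genotype(haps[1, ], "NaeI")
  expect_equal(one$length, digest(haps[1, ], "NaeI")$length)
  expect_equal(one$molarity, c(1, 1))
})

test_that("uncut_fraction adds a full-length species and conserves molar mass", {
  haps <- ref_haps()
  g <- digest_genotype(haps[1, ], "NaeI", uncut_fraction = 0.1)
  expect_setequal(g$length, c(242L, 487L, 729L))
  expect_equal(g$molarity[g$length == 729], 0.1)
  expect_equal(sum(g$length * g$molarity), 729)
  # mass conservation holds for a 2-allele genotype at any uncut fraction
  het <- tibble::tibble(id = haps$label, seq = haps$seq, dosage = c(2, 1))
  for (uf in c(0, 0.25)) {
    g2 <- digest_genotype(het, "SfaNI", uncut_fraction = uf)
    expect_equal(sum(g2$length * g2$molarity), 3 * 729)
  }
  expect_error(digest_genotype(haps[0, ], "NaeI"), "empty allele")
  expect_error(digest_genotype(haps[1, ], "NaeI", uncut_fraction = 1),
               "uncut_fraction")
})

test_that("digestion conserves length and fragment count over random inputs", {
  tab <- default_enzymes()
  withr::with_seed(32, {
    for (i in 1:500) {
      s <- random_seq(sample(60:400, 1))
      e <- tab[sample(nrow(tab), 1), ]
      cuts <- cut_positions(c(x = s), e)
      frags <- digest(c(x = s), e)
      expect_equal(sum(frags$length), nchar(s))
      expect_equal(nrow(frags), nrow(cuts) + 1)
      expect_true(all(frags$length > 0))
      # fragments tile the sequence
      expect_equal(frags$start, c(1L, utils::head(frags$end, -1) + 1L))
    }
  })
})

test_that("blunt-cutter digestion is strand symmetric and idempotent", {
  tab <- default_enzymes()
  blunt <- tab[tab$blunt & tab$palindromic, ]
  withr::with_seed(33, {
    for (i in 1:20) {
      s <- random_seq(500)
      e <- blunt[sample(nrow(blunt), 1), ]
      f1 <- sort(digest(c(x = s), e)$length)
      f2 <- sort(digest(c(x = revcomp(s)), e)$length)
      expect_equal(f1, f2)
    }
    # idempotence: re-digesting the fragments yields no further cuts
    for (i in 1:10) {
      s <- random_seq(600)
      e <- tab[sample(nrow(tab), 1), ]
      frags <- digest(c(x = s), e)
      pieces <- substring(s, frags$start, frags$end)
      for (p in pieces) {
        expect_equal(digest(c(p = p), e)$length, nchar(p))
      }
    }
  })
})

test_that("no recognition site yields a single full-length fragment", {
  f <- digest(c(x = strrep("A", 100)), "NaeI")
  expect_equal(f$length, 100L)
  expect_equal(f$molarity, 1)
})
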