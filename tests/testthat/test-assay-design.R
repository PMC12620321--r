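test_that("variable sites are found as maximal runs with 1-based columns", {
  haps <- ref_haps()
  vs <- find_variable_sites(haps)
  expect_equal(vs$start_col, c(241L, 465L))
  expect_equal(vs$end_col, c(241L, 467L))
  expect_equal(vs$site, c("site241", "site465_467"))
  expect_equal(vs$residues[[1]][["HapA"]], "C")
  expect_equal(vs$residues[[1]][["HapB"]], "T")
  expect_equal(vs$residues[[2]][["HapA"]], "TGC")
  expect_equal(vs$residues[[2]][["HapB"]], "CAA")
  expect_false(any(vs$is_indel))
  # identical rows give no sites; a single row is an input error
  same <- tibble::tibble(label = c("a", "b"), seq = c("ACGT", "ACGT"))
  expect_equal(nrow(find_variable_sites(same)), 0)
  expect_error(find_variable_sites(same[1, ]), "at least 2 rows")
})

test_that("k implanted non-adjacent SNP columns give exactly k sites", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- 300
      bg <- random_seq(n)
      k <- sample(3:8, 1)
      cols <- sort(sample(seq(5, n - 5, by = 3), k))  # never adjacent
      other <- bg
      for (cc in cols) {
        cur <- substr(bg, cc, cc)
        alt <- setdiff(c("A", "C", "G", "T"), cur)[1]
        substr(other, cc, cc) <- alt
      }
      vs <- find_variable_sites(tibble::tibble(label = c("x", "y"),
                                               seq = c(bg, other)))
      expect_equal(vs$start_col, cols)
      expect_equal(vs$end_col, cols)
    }
  })
})

test_that("indel sites are flagged", {
  aln <- tibble::tibble(label = c("x", "y"),
                        seq = c("ACGTACGT", "ACG--CGT"))
  vs <- find_variable_sites(aln)
  expect_true(all(vs$is_indel))
})

test_that("pattern signatures reproduce the predicted band patterns", {
  haps <- ref_haps()
  a <- haps$seq[haps$label == "HapA"]
  b <- haps$seq[haps$label == "HapB"]
  expect_equal(pattern_signature(a, "NaeI"), c(487, 242))
  expect_equal(pattern_signature(b, "NaeI"), 729)
  expect_equal(pattern_signature(strrep("AT", 50), "NaeI"), 100)
  expect_equal(length(pattern_signature(a, "SfaNI", gel_params(3))), 5)
  expect_equal(length(pattern_signature(b, "SfaNI", gel_params(3))), 4)
})

test_that("diagnostic enzyme discovery finds the assay pair and its sites", {
  haps <- ref_haps()
  de <- diagnostic_enzymes(haps)
  expect_true(all(c("NaeI", "SfaNI") %in% de$enzyme))
  expect_equal(de$sites[[which(de$enzyme == "NaeI")]], "site241")
  expect_equal(de$sites[[which(de$enzyme == "SfaNI")]], "site465_467")
  # invariant to row order
  de2 <- diagnostic_enzymes(haps[2:1, ])
  expect_equal(de$enzyme, de2$enzyme)
  expect_equal(de$n_pairs, de2$n_pairs)
})

test_that("diagnostic list equals exhaustive digest comparison over the table", {
  withr::with_seed(42, {
    aln <- make_haplotypes(
      400,
      dplyr::bind_rows(
        snp_site(120, A = "C", B = "T", context = "GCCGGC", context_at = 119),
        snp_site(300, A = "TGC", B = "CAA", context = "GATGC", context_at = 298)
      ),
      seed = 7, diagnostic_for = c("NaeI", "SfaNI")
    )
    tab <- default_enzymes()
    de <- diagnostic_enzymes(aln, tab)
    brute <- tab$enzyme[vapply(seq_len(nrow(tab)), function(k) {
      sigs <- lapply(aln$seq, pattern_signature, enzyme = tab[k, ],
                     params = gel_params())
      length(unique(vapply(sigs, paste, character(1), collapse = ","))) > 1
    }, logical(1))]
    expect_setequal(de$enzyme, brute)
  })
})

test_that("homogenizing a variable site removes its diagnostic enzymes", {
  haps <- ref_haps()
  # overwrite the 465-467 site in HapB with the HapA residues
  b_fixed <- haps$seq[2]
  substr(b_fixed, 465, 467) <- substr(haps$seq[1], 465, 467)
  aln <- tibble::tibble(label = haps$label, seq = c(haps$seq[1], b_fixed))
  de <- diagnostic_enzymes(aln)
  expect_false("SfaNI" %in% de$enzyme)
  expect_true("NaeI" %in% de$enzyme)
})

test_that("select_panel needs both assay enzymes for the three-haplotype system", {
  haps <- ref_haps(include_c = TRUE)
  sel <- select_panel(haps, c("NaeI", "SfaNI"))
  expect_equal(sel$panel, c("NaeI", "SfaNI"))
  expect_equal(nrow(sel$indistinguishable), 0)
  # SfaNI alone cannot separate A from the A x C heterozygote
  solo <- select_panel(haps, "SfaNI")
  pairs <- paste(solo$indistinguishable$class_a, solo$indistinguishable$class_b)
  expect_true("HapA HapA/HapC" %in% pairs)
  # a single all-discriminating candidate is returned as a singleton
  two <- ref_haps()
  expect_equal(select_panel(two, c("NaeI", "SfaNI"))$panel |> length(), 1)
})

test_that("panel signatures are injective over distinguishable classes", {
  haps <- ref_haps(include_c = TRUE)
  sel <- select_panel(haps, c("NaeI", "SfaNI"))
  sig <- sel$class_signatures
  joint <- apply(sig[, sel$panel, drop = FALSE], 1, paste, collapse = ";")
  expect_equal(anyDuplicated(joint), 0)
})

test_that("exhaustive and greedy panel search agree on small random instances", {
  tab <- default_enzymes()
  withr::with_seed(43, {
    for (rep in 1:8) {
      aln <- make_haplotypes(
        250,
        dplyr::bind_rows(
          snp_site(60, X = "A", Y = "C", Z = "A"),
          snp_site(140, X = "G", Y = "G", Z = "T"),
          snp_site(200, X = "T", Y = "A", Z = "C")
        ),
        seed = 100 + rep
      )
      cand <- diagnostic_enzymes(aln, tab)
      if (nrow(cand) < 2 || nrow(cand) > 6) next
      ex <- select_panel(aln, cand)
      expect_true(ex$exhaustive)
      # a panel is valid when the only joint-signature collisions are the
      # provably indistinguishable class pairs
      covered <- function(panel) {
        sig <- ex$class_signatures
        joint <- apply(sig[, panel, drop = FALSE], 1, paste, collapse = ";")
        dup <- which(duplicated(joint) | duplicated(joint, fromLast = TRUE))
        all(vapply(dup, function(i) {
          any(ex$indistinguishable$class_a == sig$class[i] |
                ex$indistinguishable$class_b == sig$class[i])
        }, logical(1)))
      }
      expect_true(covered(ex$panel))
      greedy <- rflpkit:::greedy_panel(aln, cand, gel_params())
      expect_true(covered(greedy))
      expect_equal(length(ex$panel), length(greedy))
    }
  })
})

test_that("cleavage typing labels the reference haplotypes and flags novelty", {
  haps <- ref_haps(include_c = TRUE)
  panel <- c("NaeI", "SfaNI")
  expect_equal(cleavage_type(haps$seq[1], panel)$type, "Type1")
  expect_equal(cleavage_type(haps$seq[2], panel)$type, "Type2")
  expect_equal(cleavage_type(haps$seq[3], panel)$type, "Type3")
  # a sequence carrying no panel site types as novel with the uncut signature
  ct <- cleavage_type(strrep("AT", 150), panel)
  expect_equal(ct$type, "novel")
  expect_equal(ct$signature, "NaeI=300; SfaNI=300")
})
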