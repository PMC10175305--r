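test_that("motif scanning matches direct IUPAC rules on small cases", {
  ets <- cpd_motifs()$ETS
  hits <- scan_motifs("TTCCG", ets)
  expect_equal(hits$start, 0L)
  expect_equal(hits$strand, "+")
  hits2 <- scan_motifs("CGGAA", ets)        # reverse complement of TTCCG
  expect_equal(hits2$start, 0L)
  expect_equal(hits2$strand, "-")
  expect_equal(nrow(scan_motifs("TTCCA", ets)), 0L)   # A not in K
})

test_that("motif scanning agrees with a brute-force IUPAC oracle", {
  motifs <- cpd_motifs()
  for (seed in 1:5) {
    s <- random_acgt(1000, 400 + seed)
    for (m in names(motifs)) {
      got <- scan_motifs(s, motifs[[m]])[, c("start", "strand")]
      want <- oracle_iupac_scan(s, motifs[[m]]$iupac)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = m)
    }
  }
})

test_that("consensus diPy offsets and informativeness follow the realized sequence", {
  motifs <- cpd_motifs()
  # CArG with a non-pyrimidine third base: CT offset absent -> uninformative
  ref1 <- paste0("AAAA", "CCATTATTGG", "AAAA")
  a1 <- assign_dipy_offsets(list(start = 4L, strand = "+", width = 10L),
                            motifs$SRF, ref1)
  expect_false(a1$informative)
  expect_equal(a1$keys$present, c(TRUE, FALSE, TRUE))
  # classification-consensus CArG: all three present, trailing GG reads CC
  # on the opposite strand
  ref2 <- paste0("AAAA", "CCTTATTTGG", "AAAA")
  a2 <- assign_dipy_offsets(list(start = 4L, strand = "+", width = 10L),
                            motifs$SRF, ref2)
  expect_true(a2$informative)
  expect_equal(a2$keys$class, c("CC", "CT", "CC"))
  expect_equal(a2$keys$dipy_strand, c("+", "+", "-"))
  # ETS consensus forces all three offsets
  ref3 <- paste0("GG", "TTCCT", "GG")
  a3 <- assign_dipy_offsets(list(start = 2L, strand = "+", width = 5L),
                            motifs$ETS, ref3)
  expect_true(a3$informative)
  expect_equal(a3$keys$class, c("TT", "TC", "CC"))
  # NF-Y: CC on the motif strand plus TT opposite the central AA
  ref4 <- paste0("GG", "CCAAT", "GG")
  a4 <- assign_dipy_offsets(list(start = 2L, strand = "+", width = 5L),
                            motifs$NFY, ref4)
  expect_true(a4$informative)
  expect_equal(a4$keys$class, c("CC", "TT"))
  expect_equal(a4$keys$dipy_strand, c("+", "-"))
  expect_equal(a4$keys$pos, c(2L, 4L))
})

test_that("signatures are looked up at diPy keys in motif orientation", {
  ref <- paste0("GG", "TTCCT", "GG")
  prof <- data.frame(region = "r", pos = c(2L, 3L, 4L), strand = "+",
                     class = c("TT", "TC", "CC"),
                     log2fc_normalized = c(1, 2, 4))
  sig <- extract_signature(prof, list(start = 2L, strand = "+", width = 5L),
                           cpd_motifs()$ETS, ref)
  expect_equal(as.numeric(sig), c(1, 2, 4))
  expect_true(attr(sig, "informative"))

  # '-'-strand site: first motif base is the rightmost genomic base
  ref_rc <- revcomp(ref)   # "CCAGGAACC"
  prof_rc <- data.frame(region = "r", pos = 9L - 2L - c(2L, 3L, 4L),
                        strand = "-", class = c("TT", "TC", "CC"),
                        log2fc_normalized = c(1, 2, 4))
  sig_rc <- extract_signature(prof_rc,
                              list(start = 9L - 5L - 2L, strand = "-",
                                   width = 5L),
                              cpd_motifs()$ETS, ref_rc)
  expect_equal(as.numeric(sig_rc), c(1, 2, 4))

  # uninformative site: explicit not-classifiable, not a zero fill
  ref_u <- paste0("AAAA", "CCATTATTGG", "AAAA")
  prof_u <- data.frame(region = "r", pos = 4L, strand = "+", class = "CC",
                       log2fc_normalized = 0)
  sig_u <- extract_signature(prof_u,
                             list(start = 4L, strand = "+", width = 10L),
                             cpd_motifs()$SRF, ref_u)
  expect_false(attr(sig_u, "informative"))
  expect_true(all(is.na(sig_u)))
  expect_identical(classify_site(sig_u, default_exemplars()$SRF),
                   NA_character_)
})

test_that("nearest-neighbor classification follows distances with unbound ties", {
  ex <- make_exemplars("ETS", list(c(1, 2, 4)))
  expect_equal(classify_site(c(1, 2, 4), ex), "bound")      # zero distance
  expect_equal(classify_site(c(0, 0, 0), ex), "unbound")    # neutral exemplar
  # exact tie: midpoint between bound exemplar and neutral
  expect_equal(classify_site(c(0.5, 1, 2), ex), "unbound")
  expect_error(classify_site(c(0, 0, 0),
                             data.frame(label = character())[0, , drop = FALSE]))
})

test_that("signatures are invariant to reverse-complementing the region", {
  samples <- make_sample_sheet(2, 4, 0)
  cfg <- simulation_config(region_length = 3000, depth = 80, seed = 41)
  sim <- simulate_dataset(cfg, n_bound = c(ETS = 2, SRF = 1, NFY = 1),
                          n_unbound = c(ETS = 1, SRF = 1, NFY = 1),
                          samples = samples)
  prof <- compare_groups(sim$tracks, "cellular", "naked")
  prof_rc <- compare_groups(flip_track(sim$tracks), "cellular", "naked")
  seq_rc <- revcomp(sim$sequence)
  L <- nchar(sim$sequence)
  motifs <- cpd_motifs()
  for (k in seq_len(nrow(sim$truth$sites))) {
    st <- sim$truth$sites[k, ]
    sig <- extract_signature(prof, st, motifs[[st$motif]], sim$sequence)
    st2 <- list(start = L - st$width - st$start,
                strand = ifelse(st$strand == "+", "-", "+"),
                width = st$width)
    sig2 <- extract_signature(prof_rc, st2, motifs[[st$motif]], seq_rc)
    expect_equal(as.numeric(sig2), as.numeric(sig), tolerance = 1e-9)
  }
})

test_that("classification separates bound from unbound at realistic signal", {
  samples <- make_sample_sheet(3, 9, 0)
  cfg <- simulation_config(region_length = 16000, depth = 100, seed = 47)
  sim <- simulate_dataset(cfg, n_bound = c(ETS = 10, SRF = 10, NFY = 10),
                          n_unbound = c(ETS = 10, SRF = 10, NFY = 10),
                          samples = samples, min_gap = 150)
  prof <- compare_groups(sim$tracks, "cellular", "naked")
  motifs <- cpd_motifs()
  ex <- default_exemplars()
  sites <- sim$truth$sites
  pred <- vapply(seq_len(nrow(sites)), function(k) {
    st <- sites[k, ]
    sig <- extract_signature(prof, st, motifs[[st$motif]], sim$sequence)
    classify_site(sig, ex[[st$motif]])
  }, character(1))
  acc <- mean((pred == "bound") == sites$bound)
  expect_gte(acc, 0.9)
})
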