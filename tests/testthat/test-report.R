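test_that("window extrema report max, min and signed max-abs per tile", {
  prof <- data.frame(region = "r", pos = c(3L, 10L, 30L, 60L),
                     strand = "+", class = "TT",
                     log2fc_normalized = c(2, -3, 4, 0))
  w <- window_extrema(prof, window = 25, region_length = 70L)
  # tiling covers the region exactly once, last partial tile included
  expect_equal(w$window_start, c(0L, 25L, 50L))
  expect_equal(w$window_end, c(25L, 50L, 70L))
  expect_equal(w$max[1], 2); expect_equal(w$min[1], -3)
  expect_equal(w$signed_max_abs[1], -3)
  expect_equal(unlist(w[2, c("max", "min", "signed_max_abs")]),
               c(max = 4, min = 4, signed_max_abs = 4))
  expect_equal(w$signed_max_abs[3], 0)
})

test_that("sample PCA is deterministic and separates conditions", {
  # identical samples get identical coordinates
  counts <- matrix(c(5, 9, 2, 5, 9, 2, 1, 1, 9), ncol = 3)
  ts <- toy_track(counts, conditions = c("cellular-untreated",
                                         "cellular-untreated", "naked"))
  pc <- pca_samples(ts)
  expect_equal(pc$PC1[1], pc$PC1[2], tolerance = 1e-12)
  # single sample: zero-dimensional embedding
  ts1 <- toy_track(matrix(c(5, 9, 2), ncol = 1))
  pc1 <- pca_samples(ts1)
  expect_true(all(pc1$PC1 == 0))
  # invariance to sample order (up to the fixed sign convention)
  ts_perm <- toy_track(counts[, c(3, 1, 2)],
                       conditions = c("naked", "cellular-untreated",
                                      "cellular-untreated"))
  pc_perm <- pca_samples(ts_perm)   # old s1/s2 now in rows 2 and 3
  expect_equal(pc_perm$PC1[2:3], pc$PC1[1:2], tolerance = 1e-9)
  # simulated cellular vs naked groups separate on PC1
  cfg <- simulation_config(region_length = 3000, depth = 60, seed = 59)
  sim <- simulate_dataset(cfg, n_bound = c(ETS = 3, SRF = 2, NFY = 2),
                          n_unbound = 0, samples = make_sample_sheet(3, 9, 0))
  pc2 <- pca_samples(sim$tracks)
  cell <- startsWith(pc2$condition, "cellular")
  expect_true(max(pc2$PC1[cell]) < min(pc2$PC1[!cell]) ||
              min(pc2$PC1[cell]) > max(pc2$PC1[!cell]))
})

test_that("QQ data pairs sorted P with expected quantiles on -log10 scale", {
  q1 <- qq_data(1)
  expect_equal(q1$expected, -log10(0.5))
  expect_equal(q1$observed, 0)
  withr::with_seed(61, {
    p <- runif(10000)
    qq <- qq_data(p)
    expect_lt(max(abs(10^-qq$observed - 10^-qq$expected)), 0.03)
  })
  # one injected tiny P among nulls tops the plot far above the diagonal
  qq2 <- qq_data(c(1e-12, runif(99)))   # row 1 holds the smallest P
  expect_gt(qq2$observed[1] - qq2$expected[1], 6)
})

test_that("mutation hotspots require strictly more than 3 mutations", {
  prof <- data.frame(region = "r", pos = c(5L, 9L, 14L), strand = "+",
                     class = "TT", log2fc_normalized = 0)
  mut <- data.frame(pos = c(5L, 9L), count = c(4L, 3L))
  ov <- mutation_overlay(prof, mut)
  expect_equal(ov$hotspot, c(TRUE, FALSE, FALSE))
  expect_equal(ov$mutation_count, c(4L, 3L, 0L))
  ov0 <- mutation_overlay(prof, mut[0, ])
  expect_false(any(ov0$hotspot))
})

test_that("qPCR relative expression linearizes delta-Ct against the baseline", {
  ct <- rbind(
    data.frame(sample = c("u1", "u2"), condition = "untreated",
               gene = "EGR1", ct = c(25, 25)),
    data.frame(sample = c("u1", "u2"), condition = "untreated",
               gene = "GAPDH", ct = c(25, 25)),
    data.frame(sample = "st1", condition = "stimulated",
               gene = "EGR1", ct = 24),
    data.frame(sample = "st1", condition = "stimulated",
               gene = "GAPDH", ct = 25))
  out <- qpcr_relative_expression(ct, "EGR1")
  expect_equal(out$relative[out$condition == "untreated"], c(1, 1))
  expect_equal(out$relative[out$sample == "st1"], 2)  # one cycle lower
  # technical duplicates are averaged on the Ct scale first
  ct2 <- rbind(ct, data.frame(sample = "st1", condition = "stimulated",
                              gene = "EGR1", ct = 23))
  out2 <- qpcr_relative_expression(ct2, "EGR1")
  expect_equal(out2$relative[out2$sample == "st1"], 2^(25 - 23.5))
})

test_that("wig export is 1-based and round-trips through a wig reader", {
  skip_if_not_installed("rtracklayer")
  prof <- data.frame(region = "chrT", pos = c(4L, 9L, 50L), strand = "+",
                     class = "TT", log2fc_normalized = c(1.5, -2.25, 0.125))
  path <- withr::local_tempfile(fileext = ".wig")
  export_wig(prof, path)
  gr <- rtracklayer::import(path, format = "wig")
  expect_equal(BiocGenerics::start(gr), prof$pos + 1L)
  expect_equal(gr$score, prof$log2fc_normalized)
  # empty profile: header-only track
  path2 <- withr::local_tempfile(fileext = ".wig")
  export_wig(prof[0, ], path2)
  expect_equal(length(readLines(path2)), 1L)
})

test_that("count tracks round-trip through the long-format TSV", {
  cfg <- simulation_config(region_length = 400, depth = 10, seed = 63)
  s <- generate_region_sequence(400, 0.5, seed = 63)
  ts <- simulate_cpd_counts(cfg, s, NULL, make_sample_sheet(1, 2, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(ts, path)
  back <- read_counts_tsv(path, ts$samples)[[ts$region]]
  expect_identical(back$counts, ts$counts)
  expect_equal(back$positions, ts$positions)
  expect_equal(back$region_length, ts$region_length)
})

test_that("detection BED and profile TSV writers round-trip", {
  ts <- toy_track(matrix(c(0, 3, 1, 2, 0, 0), ncol = 2))
  path <- withr::local_tempfile(fileext = ".bed")
  write_detection_bed(ts, path)
  bed <- read_bed6(path)
  expect_equal(sum(bed$score), sum(ts$counts))
  expect_equal(unique(bed$end - bed$start), 2L)

  prof <- data.frame(region = "r", pos = 1L, strand = "+", class = "TT",
                     log2fc_normalized = 0.5)
  class(prof) <- c("cpd_damage_profile", "data.frame")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, p2)
  back <- read_profile_tsv(p2)
  expect_equal(back$log2fc_normalized, 0.5)
})
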