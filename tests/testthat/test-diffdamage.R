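test_that("size factors recover known library-size ratios", {
  withr::with_seed(5, {
    base <- rpois(500, 50) + 1
    counts <- cbind(s1 = base, s2 = 2L * base)
    f <- size_factors(counts)
    expect_equal(unname(f["s2"] / f["s1"]), 2, tolerance = 1e-12)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    expect_equal(unname(size_factors(cbind(a = base, b = base))), c(1, 1))
    expect_equal(unname(size_factors(cbind(a = base))), 1)
  })
})

test_that("the moment dispersion estimator recovers alpha", {
  withr::with_seed(7, {
    # Poisson data: alpha ~ 0
    k <- matrix(rpois(4 * 3000, 80), ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    a0 <- estimate_dispersion(k, stats::setNames(rep(1, 4), colnames(k)),
                              list(colnames(k)))
    expect_lt(a0, 0.004)
    # NB alpha = 0.1, 2000+ positions: within +/-50%
    mu <- 100
    k2 <- matrix(rnbinom(4 * 3000, mu = mu, size = 10), ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
    a1 <- estimate_dispersion(k2, stats::setNames(rep(1, 4), colnames(k2)),
                              list(colnames(k2)))
    expect_gt(a1, 0.05)
    expect_lt(a1, 0.15)
    # constant counts: floored at zero
    k3 <- matrix(5L, 100, 3, dimnames = list(NULL, paste0("s", 1:3)))
    expect_equal(estimate_dispersion(k3, stats::setNames(rep(1, 3), colnames(k3)),
                                     list(colnames(k3))), 0)
  })
})

test_that("the exact test gives P = 1 for perfectly balanced splits", {
  p <- nb_exact_test(matrix(c(10, 10), 1), matrix(c(10, 10), 1),
                     c(1, 1), c(1, 1), dispersion = 0)
  expect_equal(p, 1)
})

test_that("exact-test P matches brute-force enumeration for totals <= 20", {
  withr::with_seed(13, {
    for (rep in 1:200) {
      ka <- sample(0:12, 1); kb <- sample(0:(20 - ka), 1)
      na <- sample(1:3, 1); nb <- sample(1:3, 1)
      sa <- runif(na, 0.5, 2); sb <- runif(nb, 0.5, 2)
      # spread the totals arbitrarily over replicates
      ca <- t(rmultinom(1, ka, rep(1, na)))
      cb <- t(rmultinom(1, kb, rep(1, nb)))
      p_impl <- nb_exact_test(ca, cb, sa, sb, dispersion = 0, pseudocount = 0)
      p_oracle <- oracle_exact_p(ka, kb, sum(sa), sum(sb))
      expect_equal(p_impl, p_oracle, tolerance = 1e-10)
    }
  })
})

test_that("the exact test rejects invalid inputs", {
  expect_error(nb_exact_test(matrix(-1), matrix(1), 1, 1, 0), "negative")
  expect_error(nb_exact_test(matrix(1), matrix(1), 1, 1, -0.1), "dispersion")
})

test_that("local window correction removes constant and smooth bias", {
  pos <- 0:999
  # constant two-fold bias: corrected ratios collapse to zero
  mean_a <- rep(4, 1000); mean_b <- rep(2, 1000)
  raw <- log2(mean_a / mean_b)
  corr <- local_ratio_correction(raw, pos, mean_a, mean_b, window = 250)
  expect_equal(max(abs(corr)), 0, tolerance = 1e-12)

  # single 16-fold spike on a flat background: closed form
  mean_a2 <- rep(2, 1000); mean_a2[501] <- 32   # spike at pos 500
  raw2 <- log2(mean_a2 / 2)
  corr2 <- local_ratio_correction(raw2, pos, mean_a2, rep(2, 1000),
                                  window = 250)
  win_a <- sum(mean_a2[pos >= 500 - 125 & pos <= 500 + 125])
  expected <- 4 - log2(win_a / (251 * 2))
  expect_equal(corr2[501], expected, tolerance = 1e-12)
  expect_error(local_ratio_correction(raw, pos, mean_a, mean_b, window = 0))
})

test_that("class normalization centers every diPy class and is idempotent", {
  withr::with_seed(3, {
    classes <- sample(c("TT", "TC", "CT", "CC"), 400, TRUE)
    v <- rnorm(400) + as.numeric(factor(classes))
    z <- dipy_class_normalization(v, classes)
    expect_true(all(abs(tapply(z, classes, mean)) < 1e-9))
    expect_equal(dipy_class_normalization(z, classes), z, tolerance = 1e-12)
  })
})

test_that("BH q-values match the hand-computed example", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(bh_qvalues(0.2), 0.2)
  p <- c(0.001, 0.3, 0.04, 0.9)
  q <- bh_qvalues(p)
  expect_true(all(q >= p))
})

test_that("comparing a group against itself is exactly null", {
  cfg <- simulation_config(region_length = 1500, depth = 50, seed = 17)
  samples <- make_sample_sheet(1, 3, 0)
  s <- generate_region_sequence(1500, 0.5, seed = 17)
  ts <- simulate_cpd_counts(cfg, s, NULL, samples)
  naked <- group_samples(ts, "naked")
  prof <- compare_groups(ts, naked, naked)
  expect_true(all(abs(prof$log2fc_normalized) < 1e-9))
  expect_true(all(prof$pvalue == 1))
})

test_that("swapping groups negates ratios and leaves P unchanged", {
  cfg <- simulation_config(region_length = 2000, depth = 60, seed = 23)
  samples <- make_sample_sheet(2, 4, 0)
  sim <- simulate_dataset(cfg, n_bound = c(ETS = 1), n_unbound = c(ETS = 0),
                          samples = samples)
  ab <- compare_groups(sim$tracks, "cellular", "naked")
  ba <- compare_groups(sim$tracks, "naked", "cellular")
  expect_equal(ba$log2fc_normalized, -ab$log2fc_normalized, tolerance = 1e-9)
  expect_equal(ba$log2fc_raw, -ab$log2fc_raw, tolerance = 1e-9)
  expect_equal(ba$pvalue, ab$pvalue, tolerance = 1e-12)
})

test_that("a planted 16x modulation is recovered with q < 0.05", {
  samples <- make_sample_sheet(3, 9, 0)
  cfg <- simulation_config(region_length = 4000, depth = 100, seed = 29)
  sim <- simulate_dataset(cfg, motifs = cpd_motifs()["ETS"],
                          n_bound = c(ETS = 2), n_unbound = c(ETS = 0),
                          samples = samples,
                          templates = list(ETS = c(1, 1, 16)))
  prof <- compare_groups(sim$tracks, "cellular", "naked")
  off <- sim$truth$offsets[sim$truth$offsets$modulation == 16, ]
  i <- match(paste(off$pos, off$dipy_strand), paste(prof$pos, prof$strand))
  expect_true(all(abs(prof$log2fc_normalized[i] - 4) < 0.4))
  expect_true(all(prof$qvalue[i] < 0.05))
})

test_that("class normalization undoes the naked TT skew in profiles", {
  cfg <- simulation_config(region_length = 6000, depth = 80, seed = 31)
  samples <- make_sample_sheet(3, 9, 0)
  s <- generate_region_sequence(6000, 0.5, seed = 31)
  ts <- simulate_cpd_counts(cfg, s, NULL, samples)
  prof <- compare_groups(ts, "cellular", "naked")
  tt <- prof$class == "TT"
  # raw cellular/naked TT ratios are globally depressed (naked TT elevated)
  expect_lt(mean(prof$log2fc_raw[tt]), -0.1)
  # after class normalization the TT mean is exactly zero
  expect_lt(abs(mean(prof$log2fc_normalized[tt])), 1e-9)
})
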