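# Per-position differential CPD statistics between sample groups.
#
# The model follows standard count-based differential testing: per-sample
# library-size factors by median-of-ratios, a single method-of-moments
# overdispersion per region (variance = mu + alpha mu^2), and a two-sided
# exact test that conditions on each position's total count and sums the
# probability of all group-sum splits no more likely than the observed one,
# with negative-binomial group-sum marginals matched by mean and variance.
# One pseudocount is added to every count before ratios and tests.  Log2
# fold changes are corrected for local ratio bias against a sliding 250-bp
# window baseline and then centered per diPy class within each region.

#' Median-of-ratios size factors
#'
#' @param counts positions x samples matrix (typically pseudocounted so the
#'   geometric-mean reference is finite everywhere).
#' @return named per-sample scale factors with geometric mean 1.
#' @export
size_factors <- function(counts) {
  k <- as.matrix(counts)
  if (ncol(k) == 1L)
    return(stats::setNames(1, colnames(k)))
  logk <- log(k)
  ref <- rowMeans(logk)
  use <- is.finite(ref) & apply(is.finite(logk), 1, all)
  if (!any(use)) stop("no position with finite counts in all samples; ",
                      "apply a pseudocount first")
  f <- apply(logk[use, , drop = FALSE], 2,
             function(col) stats::median(col - ref[use]))
  stats::setNames(exp(f - mean(f)), colnames(k))
}

#' Pooled method-of-moments dispersion estimate
#'
#' A single overdispersion alpha (variance = mu + alpha mu^2) is estimated
#' per region by pooling normalized within-group moments across positions:
#' `alpha = sum_i (v_i - m_i * mean(1/s_j)) / sum_i m_i^2`, floored at 0.
#'
#' @param counts positions x samples matrix of raw counts.
#' @param factors named per-sample size factors.
#' @param groups list of character vectors of sample ids; moments are pooled
#'   within each group (so group mean differences do not inflate alpha).
#' @param pseudocount added to all counts first (as in the test).
#' @return single non-negative alpha.
#' @export
estimate_dispersion <- function(counts, factors, groups, pseudocount = 1) {
  counts <- as.matrix(counts)
  num <- 0; den <- 0
  for (g in groups) {
    if (length(g) < 2L) next
    k <- counts[, g, drop = FALSE] + pseudocount
    s <- factors[g]
    q <- sweep(k, 2, s, "/")
    n <- length(g)
    m <- rowMeans(q)
    v <- (rowSums(q^2) - n * m^2) / (n - 1)
    num <- num + sum(v - m * mean(1 / s))
    den <- den + sum(m^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Two-sided per-position NB exact test
#'
#' For each position, one pseudocount is added to every count, group sums
#' are formed, and the two-sided P-value is the summed probability of all
#' splits of the position total whose probability does not exceed that of
#' the observed split, normalized by the total probability.  Group-sum
#' marginals are negative binomial with mean `mu * S_g` (S_g = summed size
#' factors; mu estimated from the pooled total) and variance
#' `mu * S_g + alpha * mu^2 * sum(s_j^2)`; alpha = 0 gives Poisson marginals.
#'
#' @param counts_a,counts_b positions x samples matrices of raw counts.
#' @param factors_a,factors_b per-sample size factors.
#' @param dispersion common overdispersion alpha (>= 0).
#' @param pseudocount added to every count (default 1).
#' @return numeric vector of P-values in (0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b, factors_a, factors_b,
                          dispersion = 0, pseudocount = 1) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (dispersion < 0) stop("dispersion must be >= 0")
  ka <- rowSums(counts_a + pseudocount)
  kb <- rowSums(counts_b + pseudocount)
  SA <- sum(factors_a); SB <- sum(factors_b)
  size_a <- SA^2 / (dispersion * sum(factors_a^2))
  size_b <- SB^2 / (dispersion * sum(factors_b^2))
  n <- length(ka)
  p <- numeric(n)
  for (i in seq_len(n)) {
    ks <- ka[i] + kb[i]
    mu <- ks / (SA + SB)
    a <- 0:ks
    if (dispersion == 0) {
      pa <- stats::dpois(a, mu * SA)
      pb <- stats::dpois(ks - a, mu * SB)
    } else {
      pa <- stats::dnbinom(a, mu = mu * SA, size = size_a)
      pb <- stats::dnbinom(ks - a, mu = mu * SB, size = size_b)
    }
    probs <- pa * pb
    pobs <- probs[ka[i] + 1L]
    p[i] <- min(1, sum(probs[probs <= pobs * (1 + 1e-8)]) / sum(probs))
  }
  p
}

#' Correct log2 ratios against a local sliding-window baseline
#'
#' Per position, the baseline is the log2 ratio of the two groups' summed
#' normalized mean counts over a window centered on the position and
#' spanning `window/2` bases on each side (truncated at region edges); the
#' corrected ratio is the raw ratio minus this baseline.  The symmetric
#' span keeps corrected profiles exactly invariant under reverse
#' complementation.  Removes smooth local (GC-linked) ratio bias.
#'
#' @param raw_log2 per-position raw log2 ratios (group A over group B).
#' @param pos 0-based genomic positions, sorted increasing.
#' @param mean_a,mean_b per-position normalized (pseudocounted) group mean
#'   counts.
#' @param window window size in bases (default 250).
#' @return corrected log2 ratios, with the per-position baseline attached as
#'   attribute `"baseline"`.
#' @export
local_ratio_correction <- function(raw_log2, pos, mean_a, mean_b,
                                   window = 250L) {
  if (window < 1) stop("window must be >= 1")
  if (is.unsorted(pos)) stop("positions must be sorted")
  ca <- cumsum(mean_a); cb <- cumsum(mean_b)
  lo <- pos - floor(window / 2)
  hi <- pos + floor(window / 2)
  i1 <- findInterval(lo - 0.5, pos)      # positions strictly before window
  i2 <- findInterval(hi + 0.5, pos)      # last position inside window
  suma <- ca[i2] - c(0, ca)[i1 + 1L]
  sumb <- cb[i2] - c(0, cb)[i1 + 1L]
  baseline <- log2(suma / sumb)
  out <- raw_log2 - baseline
  attr(out, "baseline") <- baseline
  out
}

#' Center log2 ratios per diPy class
#'
#' Subtracts the per-region, per-class mean so each diPy class (TT, TC, CT,
#' CC) has average log2 fold change zero within the region.  Corrects the
#' class-level skew between conditions (notably elevated TT damage in naked
#' samples).
#'
#' @param values per-position log2 ratios.
#' @param classes per-position diPy class labels.
#' @return centered values (class means exactly 0).
#' @export
dipy_class_normalization <- function(values, classes) {
  as.numeric(values) - stats::ave(as.numeric(values), classes, FUN = mean)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p vector of P-values.
#' @return vector of BH-adjusted values (monotone in P, q >= P).
#' @export
bh_qvalues <- function(p) stats::p.adjust(p, method = "BH")

#' Per-position differential damage profile between two groups
#'
#' Composes the full statistical pipeline: size factors (median-of-ratios
#' over both groups), pooled dispersion estimate, per-position NB exact
#' test, raw log2 ratios of normalized pseudocounted group means (oriented
#' as log2(A/B)), local window correction, per-class centering, and BH
#' q-values.
#'
#' @param tracks a [cpd_track_set()].
#' @param group_a,group_b sample ids or condition selectors (see
#'   [group_samples()]); e.g. `"cellular"` vs `"naked"`.
#' @param window local-correction window in bases (default 250).
#' @param pseudocount added to all counts (default 1).
#' @param dispersion fixed overdispersion alpha, or NULL (default) to
#'   estimate it from the data.
#' @return data.frame of class `cpd_damage_profile` with columns `region`,
#'   `pos`, `strand`, `class`, `mean_a`, `mean_b`, `log2fc_raw`,
#'   `log2fc_corrected`, `log2fc_normalized`, `pvalue`, `qvalue`;
#'   attributes `group_a`, `group_b`, `window`, `dispersion`,
#'   `size_factors`.
#' @export
compare_groups <- function(tracks, group_a, group_b, window = 250L,
                           pseudocount = 1, dispersion = NULL) {
  ts <- tracks
  stopifnot(inherits(ts, "cpd_track_set"))
  ids_a <- group_samples(ts, group_a)
  ids_b <- group_samples(ts, group_b)
  ids <- c(ids_a, ids_b)
  k <- ts$counts[, ids, drop = FALSE] + pseudocount
  sf <- size_factors(k)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(ts$counts[, ids, drop = FALSE], sf,
                                      groups = list(ids_a, ids_b),
                                      pseudocount = pseudocount)
  pvals <- nb_exact_test(ts$counts[, ids_a, drop = FALSE],
                         ts$counts[, ids_b, drop = FALSE],
                         sf[ids_a], sf[ids_b], dispersion, pseudocount)
  mean_a <- rowMeans(sweep(k[, ids_a, drop = FALSE], 2, sf[ids_a], "/"))
  mean_b <- rowMeans(sweep(k[, ids_b, drop = FALSE], 2, sf[ids_b], "/"))
  raw <- log2(mean_a / mean_b)
  corrected <- local_ratio_correction(raw, ts$positions$pos, mean_a, mean_b,
                                      window)
  normalized <- dipy_class_normalization(as.numeric(corrected),
                                         ts$positions$class)
  out <- data.frame(region = ts$region,
                    pos = ts$positions$pos,
                    strand = ts$positions$strand,
                    class = ts$positions$class,
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc_raw = raw,
                    log2fc_corrected = as.numeric(corrected),
                    log2fc_normalized = normalized,
                    pvalue = pvals,
                    qvalue = bh_qvalues(pvals),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "group_a") <- ids_a
  attr(out, "group_b") <- ids_b
  attr(out, "window") <- window
  attr(out, "dispersion") <- dispersion
  attr(out, "size_factors") <- sf
  attr(out, "region_length") <- ts$region_length
  class(out) <- c("cpd_damage_profile", "data.frame")
  out
}
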