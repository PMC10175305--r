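# Region-level overviews and exports: windowed fold-change extrema, sample
# PCA, P-value QQ data, somatic-mutation hotspot overlay, and qPCR relative
# expression.

#' Windowed fold-change extrema
#'
#' Tiles the region in non-overlapping windows from the region start and
#' reports, per window, the maximum and minimum normalized log2 fold change
#' and the signed maximum-absolute value (the extremum of larger magnitude
#' with its sign preserved), so positive and negative changes are equally
#' considered.  The last partial tile is included.  Windows without diPy
#' positions report 0.
#'
#' @param profile a `cpd_damage_profile`.
#' @param window tile width in bases (default 25).
#' @param value which profile column to summarize (default the
#'   class-normalized, window-corrected log2 ratio).
#' @param region_length region length in bases (default from the profile).
#' @return data.frame: `region`, `window_start`, `window_end`, `max`, `min`,
#'   `signed_max_abs`, `n_positions`.
#' @export
window_extrema <- function(profile, window = 25L,
                           value = "log2fc_normalized",
                           region_length = NULL) {
  region_length <- region_length %||% attr(profile, "region_length") %||%
    (max(profile$pos) + 2L)
  starts <- seq(0L, region_length - 1L, by = window)
  idx <- findInterval(profile$pos, starts)
  v <- profile[[value]]
  mx <- mn <- rep(0, length(starts))
  np <- integer(length(starts))
  agg_max <- tapply(v, idx, max)
  agg_min <- tapply(v, idx, min)
  agg_n <- tapply(v, idx, length)
  i <- as.integer(names(agg_max))
  mx[i] <- agg_max; mn[i] <- agg_min; np[i] <- agg_n
  signed <- ifelse(abs(mx) >= abs(mn), mx, mn)
  data.frame(region = unique(profile$region),
             window_start = starts,
             window_end = pmin(starts + window, region_length),
             max = mx, min = mn, signed_max_abs = signed,
             n_positions = np)
}

#' PCA of per-sample CPD count vectors
#'
#' Sample vectors are the per-position counts, depth-normalized within the
#' region (divided by the sample total), transformed log2(x + 1), and
#' mean-centered per position.  Coordinates come from the singular value
#' decomposition; each component's sign is fixed so that its largest-
#' magnitude loading is positive, making the embedding invariant to sample
#' ordering.
#'
#' @param tracks a [cpd_track_set()].
#' @param samples sample ids to include (default all).
#' @param n_components number of components to return.
#' @return data.frame: `sample`, `condition`, `PC1`, `PC2`, ...; attribute
#'   `variance_explained`.
#' @export
pca_samples <- function(tracks, samples = NULL, n_components = 2L) {
  ts <- tracks
  ids <- samples %||% ts$samples$sample
  k <- ts$counts[, ids, drop = FALSE]
  tot <- colSums(k)
  tot[tot == 0] <- 1
  x <- log2(sweep(k, 2, tot / mean(tot), "/") + 1)
  x <- t(x - rowMeans(x))            # samples x positions, centered per position
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  cond <- ts$samples$condition[match(ids, ts$samples$sample)]
  if (n_components < 1L) {
    out <- data.frame(sample = ids, condition = cond, PC1 = 0)
    attr(out, "variance_explained") <- numeric(0)
    return(out)
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (j in seq_len(n_components)) {      # deterministic sign convention
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PC", seq_len(n_components))
  out <- data.frame(sample = ids, condition = cond, coords)
  attr(out, "variance_explained") <- sv$d[seq_len(n_components)]^2 / sum(sv$d^2)
  out
}

#' Expected/observed quantile pairs for a P-value QQ plot
#'
#' @param p vector of (uncorrected) P-values.
#' @return data.frame with `expected` = -log10((i - 0.5)/m) and `observed` =
#'   -log10 of the sorted P-values, largest expected quantile first.
#' @export
qq_data <- function(p) {
  p <- sort(as.numeric(p))
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(p))
}

#' Overlay somatic mutation counts on a damage profile
#'
#' Joins per-position mutation counts onto the profile coordinates and flags
#' hotspots (more than 3 mutations).
#'
#' @param profile a `cpd_damage_profile`.
#' @param mutations data.frame with columns `pos` and `count` (per-position
#'   mutation counts; positions not listed count 0), optionally `region`.
#' @param hotspot_min_count positions with strictly more mutations than this
#'   are hotspots (default 3).
#' @return the profile with added columns `mutation_count` and `hotspot`.
#' @export
mutation_overlay <- function(profile, mutations, hotspot_min_count = 3L) {
  out <- as.data.frame(profile)
  counts <- rep(0L, nrow(out))
  if (!is.null(mutations) && nrow(mutations)) {
    if (!is.null(mutations$region))
      mutations <- mutations[mutations$region %in% unique(out$region), ,
                             drop = FALSE]
    i <- match(out$pos, mutations$pos)
    counts[!is.na(i)] <- mutations$count[i[!is.na(i)]]
  }
  out$mutation_count <- counts
  out$hotspot <- counts > hotspot_min_count
  out
}

#' Relative expression from qPCR Ct values
#'
#' Technical duplicates are averaged on the Ct scale; expression is
#' normalized to the reference gene by Ct subtraction and linearized as
#' 2^-(delta Ct), then scaled so that the baseline condition has mean 1.
#'
#' @param ct data.frame with columns `sample`, `condition`, `gene`, `ct`
#'   (one row per technical replicate measurement).
#' @param target target gene name.
#' @param reference reference gene name (default "GAPDH").
#' @param baseline baseline condition whose mean is normalized to 1.
#' @return data.frame: `sample`, `condition`, `delta_ct`, `expression`
#'   (2^-dCt), `relative` (baseline mean = 1).
#' @export
qpcr_relative_expression <- function(ct, target, reference = "GAPDH",
                                     baseline = "untreated") {
  stopifnot(all(c("sample", "condition", "gene", "ct") %in% names(ct)))
  avg <- stats::aggregate(list(ct = ct$ct),
    by = list(sample = ct$sample, condition = ct$condition, gene = ct$gene),
    FUN = mean)
  tg <- avg[avg$gene == target, ]
  rf <- avg[avg$gene == reference, ]
  out <- merge(tg[, c("sample", "condition", "ct")],
               rf[, c("sample", "ct")], by = "sample",
               suffixes = c("_target", "_reference"))
  out$delta_ct <- out$ct_target - out$ct_reference
  out$expression <- 2^(-out$delta_ct)
  base <- out$expression[out$condition == baseline]
  if (!length(base)) stop("no samples in baseline condition '", baseline, "'")
  out$relative <- out$expression / mean(base)
  out[, c("sample", "condition", "delta_ct", "expression", "relative")]
}
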