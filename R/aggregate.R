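# Average TF damage signatures from sparse genome-wide CPD detections.
#
# Bound sites are motif matches supported by ChIP-derived site calls and
# open chromatin; unbound sites are motif matches lacking any overlap with
# an exclusion set (clustered TF binding sites) or accessible chromatin,
# down-sampled to 10x the bound count.  Detections are summarized per motif
# offset in motif orientation, depth-normalized per condition, and adjusted
# by per-diPy-class correction factors that equalize the genome-wide
# class frequency distributions of the two conditions.

.sites_gr <- function(sites) {
  chrom <- if (!is.null(sites$chrom)) sites$chrom else "region"
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(sites$start + 1L, sites$start + sites$width))
}

.intervals_gr <- function(x) {
  chrom <- if (!is.null(x$chrom)) x$chrom else "region"
  GenomicRanges::GRanges(chrom, IRanges::IRanges(x$start + 1L, x$end))
}

.overlaps_any <- function(sites, intervals) {
  if (is.null(intervals) || !nrow(intervals)) return(rep(FALSE, nrow(sites)))
  IRanges::overlapsAny(.sites_gr(sites), .intervals_gr(intervals))
}

#' Label motif sites bound or unbound for aggregation
#'
#' Bound = motif matches overlapping both the ChIP-derived site calls and
#' the accessibility peaks.  Unbound = motif matches with no overlap with
#' any exclusion interval set nor with the accessibility peaks.  Unbound
#' sites are down-sampled to `sample_ratio` times the bound count (all are
#' kept if there are fewer).
#'
#' @param sites data.frame of motif matches (`start`, `width`, `strand`,
#'   optionally `chrom`, `factor`); 0-based.
#' @param chip_sites interval data.frame (`start`, `end`, optionally
#'   `chrom`), 0-based half-open.
#' @param accessibility interval data.frame, same format.
#' @param exclusion list of interval data.frames (clustered binding sites
#'   etc.); defaults to `list(chip_sites)`.
#' @param sample_ratio unbound:bound sampling ratio (default 10).
#' @param seed integer seed for the unbound down-sampling.
#' @return `sites` rows that received a label, with a `label` column
#'   ("bound"/"unbound").
#' @export
define_bound_unbound_sites <- function(sites, chip_sites, accessibility,
                                       exclusion = list(chip_sites),
                                       sample_ratio = 10L, seed = 1L) {
  stopifnot(all(c("start", "width", "strand") %in% names(sites)))
  in_chip <- .overlaps_any(sites, chip_sites)
  in_acc <- .overlaps_any(sites, accessibility)
  in_excl <- Reduce(`|`, lapply(exclusion, function(x) .overlaps_any(sites, x)),
                    accumulate = FALSE, init = rep(FALSE, nrow(sites)))
  bound <- sites[in_chip & in_acc, , drop = FALSE]
  unbound <- sites[!in_excl & !in_acc, , drop = FALSE]
  n_take <- min(nrow(unbound), sample_ratio * nrow(bound))
  unbound <- withr::with_seed(seed,
    unbound[sample.int(nrow(unbound), n_take), , drop = FALSE])
  if (nrow(bound)) bound$label <- "bound"
  if (nrow(unbound)) unbound$label <- "unbound"
  out <- rbind(bound, unbound)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize sparse CPD detections at motif offsets
#'
#' Assigns each detection falling inside a labeled site to its motif offset
#' in motif orientation (for a '-'-strand site the first motif base is the
#' rightmost genomic base) and records the diPy strand relative to the motif
#' and, when a reference is given, the diPy class.
#'
#' @param sites labeled sites from [define_bound_unbound_sites()] (needs
#'   `start`, `width`, `strand`, `label`, optionally `chrom`, `factor`).
#' @param detections named list of detection data.frames per condition
#'   (e.g. `list(cellular = ..., naked = ...)`), each with columns `start`
#'   (0-based dinucleotide start), `strand`, `count`, optionally `chrom`.
#' @param reference optional named character vector of forward sequences per
#'   chromosome, for diPy class annotation.
#' @return data.frame: `condition`, `label`, `factor`, `offset`,
#'   `rel_strand`, `class`, `count`; plus attribute `n_sites` (table of site
#'   counts per label).
#' @export
summarize_detections <- function(sites, detections, reference = NULL) {
  stopifnot(is.list(detections), !is.null(names(detections)))
  gr_sites <- .sites_gr(sites)
  out <- list()
  for (cond in names(detections)) {
    d <- detections[[cond]]
    if (is.null(d) || !nrow(d)) next
    if (is.null(d$count)) d$count <- 1L
    chrom <- if (!is.null(d$chrom)) d$chrom else rep("region", nrow(d))
    gr_d <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(d$start + 1L, d$start + 2L))
    hits <- GenomicRanges::findOverlaps(gr_d, gr_sites, type = "within")
    if (!length(hits)) next
    di <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    s_start <- sites$start[si]; s_width <- sites$width[si]
    s_strand <- sites$strand[si]
    offset <- ifelse(s_strand == "+", d$start[di] - s_start,
                     s_start + s_width - 2L - d$start[di])
    rel <- ifelse(d$strand[di] == s_strand, "same", "opposite")
    cls <- if (!is.null(reference)) {
      fwd <- substring(reference[chrom[di]], d$start[di] + 1L, d$start[di] + 2L)
      ifelse(d$strand[di] == "+", fwd, revcomp(fwd))
    } else rep(".", length(di))
    fac <- if (!is.null(sites$factor)) sites$factor[si] else "site"
    agg <- stats::aggregate(list(count = d$count[di]),
      by = list(condition = rep(cond, length(di)), label = sites$label[si],
                factor = fac, offset = offset, rel_strand = rel, class = cls),
      FUN = sum)
    out[[cond]] <- agg
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(condition = character(), label = character(),
               factor = character(), offset = integer(),
               rel_strand = character(), class = character(),
               count = numeric())
  rownames(res) <- NULL
  attr(res, "n_sites") <- table(sites$label)
  res
}

#' Per-class correction factors equalizing diPy frequency distributions
#'
#' Given global (genome-wide) detection tallies per diPy class and
#' condition, returns multiplicative factors such that after correction both
#' conditions have the same four-class frequency distribution — the pooled
#' (count-weighted) distribution.  Ratios downstream are invariant to the
#' choice of common target distribution.
#'
#' @param tallies matrix or data.frame of counts, classes (TT/TC/CT/CC) in
#'   rows and conditions in columns.
#' @return matrix of positive factors, same shape as `tallies`.
#' @export
dipy_correction_factors <- function(tallies) {
  m <- as.matrix(tallies)
  if (any(m < 0)) stop("negative class tallies")
  pooled <- rowSums(m) / sum(m)
  frac <- sweep(m, 2, colSums(m), "/")
  if (any(frac == 0 & pooled > 0))
    stop("a diPy class is absent in one condition; correction factor undefined")
  f <- pooled / frac               # recycles pooled down each column
  f[pooled == 0, ] <- 1
  dimnames(f) <- dimnames(m)
  f
}

#' Aggregate per-offset log2 damage ratios
#'
#' Per factor, label, motif offset, and relative strand: applies the
#' per-class correction factors to the summed detection counts, adds one
#' pseudocount to each raw (summed) count, depth-normalizes per condition,
#' and takes the log2 cellular/naked ratio.
#'
#' @param summaries output of [summarize_detections()]; must contain the two
#'   conditions named in `conditions`.
#' @param depth_totals named numeric: total detections per condition
#'   (genome-wide), used for depth normalization.
#' @param correction_factors matrix from [dipy_correction_factors()]
#'   (classes x conditions), or NULL to skip class correction.
#' @param conditions length-2 character: numerator and denominator
#'   condition (default cellular, naked).
#' @param pseudocount added to summed raw counts (default 1).
#' @return data.frame: `factor`, `label`, `offset`, `rel_strand`,
#'   numerator/denominator corrected counts, `log2_ratio`, `n_sites`.
#' @export
aggregate_log2_ratios <- function(summaries, depth_totals,
                                  correction_factors = NULL,
                                  conditions = c("cellular", "naked"),
                                  pseudocount = 1) {
  stopifnot(length(conditions) == 2,
            all(conditions %in% names(depth_totals)))
  s <- summaries[summaries$condition %in% conditions, , drop = FALSE]
  if (!is.null(correction_factors)) {
    f <- correction_factors[cbind(match(s$class, rownames(correction_factors)),
                                  match(s$condition, colnames(correction_factors)))]
    f[is.na(f)] <- 1
    s$count <- s$count * f
  }
  agg <- stats::aggregate(list(count = s$count),
    by = list(condition = s$condition, label = s$label, factor = s$factor,
              offset = s$offset, rel_strand = s$rel_strand), FUN = sum)
  key <- c("label", "factor", "offset", "rel_strand")
  num <- agg[agg$condition == conditions[1], c(key, "count")]
  den <- agg[agg$condition == conditions[2], c(key, "count")]
  names(num)[5] <- "count_num"; names(den)[5] <- "count_den"
  out <- merge(num, den, by = key, all = TRUE)
  out$count_num[is.na(out$count_num)] <- 0
  out$count_den[is.na(out$count_den)] <- 0
  out$log2_ratio <- log2(((out$count_num + pseudocount) / depth_totals[[conditions[1]]]) /
                         ((out$count_den + pseudocount) / depth_totals[[conditions[2]]]))
  n_sites <- attr(summaries, "n_sites")
  out$n_sites <- as.integer(n_sites[out$label])
  out <- out[order(out$factor, out$label, out$offset, out$rel_strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
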