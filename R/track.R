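# Container for per-base CPD count tracks.
#
# A cpd_track_set holds, for one region, the full diPy grid (every
# dipyrimidine start with its strand and class) and a positions x samples
# count matrix, together with the sample sheet.  Zero counts are kept so the
# per-position tests see every assayed diPy.

#' Construct a CPD count track set
#'
#' @param positions data.frame with columns `pos` (0-based dinucleotide
#'   start), `strand`, `class`; one row per diPy of the region, as produced
#'   by [dipy_index()].
#' @param counts integer/numeric matrix, `nrow(positions)` rows and one
#'   column per sample (column names = sample ids).
#' @param samples data.frame with at least columns `sample` and `condition`;
#'   conditions follow the study design: `cellular-untreated`,
#'   `cellular-starved`, `cellular-stimulated`, `naked`, `noUV`.
#' @param region region name (single string).
#' @param region_length region length in bases (used for windowing and wig
#'   export).
#' @return object of class `cpd_track_set`.
#' @export
cpd_track_set <- function(positions, counts, samples, region = "region",
                          region_length = NULL) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(positions),
            all(c("pos", "strand", "class") %in% names(positions)),
            nrow(counts) == nrow(positions),
            is.data.frame(samples),
            all(c("sample", "condition") %in% names(samples)),
            ncol(counts) == nrow(samples))
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  stopifnot(identical(colnames(counts), samples$sample))
  # strand exclusivity: a dinucleotide start carries a diPy on one strand only
  if (anyDuplicated(positions$pos))
    stop("duplicate dinucleotide start in positions: only one strand can ",
         "contain a diPy at each position")
  if (is.null(region_length)) region_length <- max(positions$pos) + 2L
  structure(list(region = region, region_length = as.integer(region_length),
                 positions = positions, counts = counts, samples = samples),
            class = "cpd_track_set")
}

#' @export
print.cpd_track_set <- function(x, ...) {
  cat(sprintf("cpd_track_set: region '%s' (%d bp), %d diPy positions, %d samples\n",
              x$region, x$region_length, nrow(x$positions), ncol(x$counts)))
  cat("conditions:", paste(sprintf("%s (%d)", names(table(x$samples$condition)),
                                   table(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Samples belonging to a condition group
#'
#' Convenience selector: `"cellular"` matches all three cellular conditions.
#'
#' @param x a `cpd_track_set`.
#' @param group condition name, or `"cellular"` for the union of cellular
#'   conditions, or a character vector of sample ids.
#' @return character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  stopifnot(inherits(x, "cpd_track_set"))
  if (all(group %in% x$samples$sample)) return(group)
  cond <- x$samples$condition
  keep <- if (identical(group, "cellular")) startsWith(cond, "cellular")
          else cond %in% group
  if (!any(keep)) stop("no samples match group: ", paste(group, collapse = ", "))
  x$samples$sample[keep]
}
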