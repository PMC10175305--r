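# CPD extraction from mate-1 alignment records, and its inverse.
#
# The library chemistry places the mate-1 5' end two bases downstream of the
# dimer on the opposite strand, so a CPD is recovered from a mate-1 record
# as the two bases upstream and on the opposite strand of the mate-1 5' end:
#
#   '+' record with leftmost 0-based position p  ->  diPy (p-2, p-1) on '-'
#   '-' record with half-open end q              ->  diPy (q,  q+1)  on '+'
#
# All coordinates are 0-based half-open (BED convention).

#' Emit mate-1 alignment records from a CPD count track
#'
#' Inverse of [extract_cpd_positions()]: writes one BED6 mate-1 record per
#' detection such that applying the extraction rule recovers the track
#' exactly.  A detection on the '-' strand at dinucleotide start `s` becomes
#' a '+' record with leftmost position `s + 2`; a '+'-strand detection at
#' `s` becomes a '-' record ending (half-open) at `s`.
#'
#' @param x a [cpd_track_set()] (counts at diPy positions), or a data.frame
#'   with columns `sample`, `pos`, `strand`, `count`.
#' @param region_length region length in bases (taken from `x` when it is a
#'   track set).
#' @param read_length alignment span in bases; record spans are truncated at
#'   region boundaries on the non-defining side.
#' @param region region/chromosome name for the BED `chrom` field.
#' @param include_nondipy also emit records for the track set's non-diPy
#'   detections (element `nondipy`), if present.
#' @return data.frame in BED6 column order: `chrom`, `start`, `end`, `name`
#'   (sample id), `score` (1), `strand`; one row per detection.
#' @export
emit_read_pairs <- function(x, region_length = NULL, read_length = 36L,
                            region = NULL, include_nondipy = TRUE) {
  if (inherits(x, "cpd_track_set")) {
    region_length <- region_length %||% x$region_length
    region <- region %||% x$region
    det <- data.frame(
      sample = rep(colnames(x$counts), each = nrow(x$positions)),
      pos = rep(x$positions$pos, ncol(x$counts)),
      strand = rep(x$positions$strand, ncol(x$counts)),
      count = as.vector(x$counts))
    if (include_nondipy && !is.null(x$nondipy) && nrow(x$nondipy))
      det <- rbind(det, x$nondipy[, c("sample", "pos", "strand", "count")])
  } else {
    det <- x
    stopifnot(all(c("sample", "pos", "strand", "count") %in% names(det)),
              !is.null(region_length))
    region <- region %||% "region"
  }
  det <- det[det$count > 0, , drop = FALSE]
  if (!nrow(det)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character()))
  }
  bad <- (det$strand == "-" & det$pos + 2L > region_length - 1L) |
         (det$strand == "+" & det$pos < 1L)
  if (any(bad))
    stop(sum(bad), " detection(s) too close to the region boundary to encode",
         " as mate-1 records")
  det <- det[rep(seq_len(nrow(det)), det$count), , drop = FALSE]
  # detection on '-' -> '+' mate-1; detection on '+' -> '-' mate-1
  mate_strand <- ifelse(det$strand == "-", "+", "-")
  start <- ifelse(det$strand == "-", det$pos + 2L,
                  pmax(0L, det$pos - read_length))
  end <- ifelse(det$strand == "-",
                pmin(region_length, det$pos + 2L + read_length), det$pos)
  out <- data.frame(chrom = region, start = as.integer(start),
                    end = as.integer(end), name = det$sample, score = 1L,
                    strand = mate_strand, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$start, out$end, out$name), , drop = FALSE]
}

#' Extract CPD positions from mate-1 alignment records
#'
#' Applies the extraction rule (two bases upstream and on the opposite
#' strand of the mate-1 5' end) to deduplicated mate-1 BED6 records and
#' keeps detections whose implied dinucleotide falls inside a region.
#'
#' @param records data.frame of BED6 mate-1 records (`chrom`, `start`,
#'   `end`, `name` = sample id, `score`, `strand`), 0-based half-open.
#' @param regions data.frame of regions (`chrom`, `start`, `end`, `name`),
#'   0-based half-open; detections outside all regions are dropped and
#'   tallied.
#' @return data.frame of detections (`chrom`, `region`, `pos`, `strand`,
#'   `sample`) with attribute `dropped` = number of out-of-region records.
#' @export
extract_cpd_positions <- function(records, regions) {
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(records)),
            all(c("chrom", "start", "end", "name") %in% names(regions)))
  if (!nrow(records)) {
    out <- data.frame(chrom = character(), region = character(),
                      pos = integer(), strand = character(),
                      sample = character())
    attr(out, "dropped") <- 0L
    return(out)
  }
  pos <- ifelse(records$strand == "+", records$start - 2L, records$end)
  strand <- ifelse(records$strand == "+", "-", "+")
  det <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(pos + 1L, pos + 2L))
  reg <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L, regions$end))
  hit <- GenomicRanges::findOverlaps(det, reg, type = "within", select = "first")
  keep <- !is.na(hit)
  out <- data.frame(chrom = records$chrom[keep],
                    region = regions$name[hit[keep]],
                    pos = as.integer(pos[keep]), strand = strand[keep],
                    sample = records$name[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Filter detections to dipyrimidine sites and build count tracks
#'
#' Keeps detections whose reference dinucleotide, read 5'->3' on the
#' detection strand, is a dipyrimidine (TT, TC, CT or CC); all others are
#' rejected and tallied by the dinucleotide observed on the detection strand
#' (detections overlapping an N are tallied under `"N"`).  Kept detections
#' are accumulated on the full diPy grid of each region, so positions with
#' zero detections are retained.
#'
#' @param detections data.frame from [extract_cpd_positions()].
#' @param reference named character vector or `DNAStringSet`: forward
#'   sequence per region (region-local, i.e. position 0 of the sequence is
#'   the region start).
#' @param regions optional regions data.frame (`name`, `start`); when given,
#'   detection positions are shifted by the region start before sequence
#'   lookup.  Defaults to region start 0 (region-local records).
#' @param samples sample sheet data.frame (`sample`, `condition`, ...);
#'   defaults to one `cellular-untreated` row per sample id present.
#' @return list with one [cpd_track_set()] per region (named by region) and
#'   attribute-like element `rejected`: a named tally of rejected detections
#'   per observed dinucleotide.
#' @export
filter_dipy <- function(detections, reference, regions = NULL, samples = NULL) {
  if (is(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  stopifnot(is.character(reference), !is.null(names(reference)))
  region_names <- unique(detections$region)
  if (is.null(samples)) {
    ids <- sort(unique(detections$sample))
    samples <- data.frame(sample = ids, condition = "cellular-untreated",
                          replicate = seq_along(ids))
  }
  missing_ref <- setdiff(region_names, names(reference))
  if (length(missing_ref))
    stop("reference does not cover region(s): ",
         paste(missing_ref, collapse = ", "))

  offsets <- stats::setNames(rep(0L, length(reference)), names(reference))
  if (!is.null(regions))
    offsets[regions$name] <- as.integer(regions$start)

  rejected <- integer(0)
  tracks <- list()
  for (rg in names(reference)) {
    seq_rg <- reference[[rg]]
    grid <- dipy_index(seq_rg)
    d <- detections[detections$region == rg, , drop = FALSE]
    d$pos <- d$pos - offsets[[rg]]
    counts <- matrix(0L, nrow(grid), nrow(samples),
                     dimnames = list(NULL, samples$sample))
    if (nrow(d)) {
      fwd <- substring(seq_rg, d$pos + 1L, d$pos + 2L)
      obs <- ifelse(d$strand == "+", fwd, revcomp(fwd))
      obs[grepl("[^ACGT]", obs)] <- "N"
      is_dipy <- obs %in% c("TT", "TC", "CT", "CC")
      if (any(!is_dipy)) {
        tal <- table(obs[!is_dipy])
        for (nm in names(tal))
          rejected[nm] <- (if (nm %in% names(rejected)) rejected[nm] else 0L) +
            tal[[nm]]
      }
      kept <- d[is_dipy, , drop = FALSE]
      if (nrow(kept)) {
        i <- match(paste(kept$pos, kept$strand),
                   paste(grid$pos, grid$strand))
        stopifnot(!anyNA(i))  # diPy-classified detections must be on the grid
        j <- match(kept$sample, samples$sample)
        if (anyNA(j)) stop("detection sample not in sample sheet")
        tab <- table(factor(i, seq_len(nrow(grid))),
                     factor(j, seq_len(nrow(samples))))
        counts <- counts + matrix(as.integer(tab), nrow(grid), nrow(samples))
      }
    }
    tracks[[rg]] <- cpd_track_set(grid, counts, samples, region = rg,
                                  region_length = nchar(seq_rg))
  }
  list(tracks = tracks, rejected = rejected)
}

#' Mean detections per diPy site, by dinucleotide class
#'
#' For a group of samples, reports per region and per diPy class the total
#' number of detections divided by the number of sites of that class.
#' Classes with zero sites in a region are absent from the output rather
#' than reported as zero.
#'
#' @param tracks a [cpd_track_set()] or a list of them (one per region).
#' @param group sample ids or a condition selector (see [group_samples()]).
#' @return data.frame with columns `region`, `class`, `n_sites`, `total`,
#'   `mean`.
#' @export
per_dinucleotide_summary <- function(tracks, group = "cellular") {
  if (inherits(tracks, "cpd_track_set")) tracks <- list(tracks)
  out <- lapply(tracks, function(ts) {
    ids <- group_samples(ts, group)
    tot <- rowSums(ts$counts[, ids, drop = FALSE])
    agg <- stats::aggregate(list(total = tot),
                            by = list(class = ts$positions$class), FUN = sum)
    n <- table(ts$positions$class)[agg$class]
    data.frame(region = ts$region, class = agg$class,
               n_sites = as.integer(n), total = agg$total,
               mean = agg$total / as.integer(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
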