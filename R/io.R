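# Plain-text interchange: BED6, FASTA, sample sheets, profile TSV, wig.
# All BED intervals are 0-based half-open on disk and in memory; wig export
# is 1-based variableStep as the format requires.

#' Read a BED6 file of intervals or mate-1 records
#'
#' @param path BED file path (3-6 columns, tab-separated, no header).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with defaults).
#' @export
read_bed6 <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = cols[seq_len(max(utils::count.fields(path, sep = "\t")))])
  for (j in setdiff(cols, names(d)))
    d[[j]] <- switch(j, name = ".", score = 0L, strand = "*")
  d[, cols]
}

#' Write intervals as BED6
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed6 <- function(x, path) {
  d <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                  name = if (!is.null(x$name)) x$name else ".",
                  score = if (!is.null(x$score)) x$score else 0L,
                  strand = if (!is.null(x$strand)) x$strand else "*")
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write CPD detections as BED (one line per detection)
#'
#' Each detection spans its dinucleotide: `chrom`, `pos`, `pos + 2`, sample,
#' count, diPy strand.
#'
#' @param tracks a [cpd_track_set()].
#' @param path output path.
#' @export
write_detection_bed <- function(tracks, path) {
  ts <- tracks
  nz <- which(ts$counts > 0, arr.ind = TRUE)
  d <- data.frame(chrom = ts$region,
                  start = ts$positions$pos[nz[, 1]],
                  end = ts$positions$pos[nz[, 1]] + 2L,
                  name = colnames(ts$counts)[nz[, 2]],
                  score = ts$counts[nz],
                  strand = ts$positions$strand[nz[, 1]])
  d <- d[order(d$start, d$name), ]
  write_bed6(d, path)
}

#' Read a FASTA file as named character sequences
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write a damage profile as TSV
#'
#' @param profile a `cpd_damage_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a damage profile TSV
#'
#' @param path TSV written by [write_profile_tsv()].
#' @return `cpd_damage_profile` data.frame.
#' @export
read_profile_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(d) <- c("cpd_damage_profile", "data.frame")
  d
}

#' Write per-position count tracks as a long-format TSV
#'
#' One row per (region, position, strand, class, sample) with the detection
#' count; zero counts are kept so the grid is recoverable.
#'
#' @param tracks a [cpd_track_set()] or list of them.
#' @param path output path.
#' @export
write_counts_tsv <- function(tracks, path) {
  if (inherits(tracks, "cpd_track_set")) tracks <- list(tracks)
  rows <- lapply(tracks, function(ts) {
    data.frame(region = ts$region,
               region_length = ts$region_length,
               pos = rep(ts$positions$pos, ncol(ts$counts)),
               strand = rep(ts$positions$strand, ncol(ts$counts)),
               class = rep(ts$positions$class, ncol(ts$counts)),
               sample = rep(colnames(ts$counts), each = nrow(ts$positions)),
               count = as.vector(ts$counts))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read count tracks written by [write_counts_tsv()]
#'
#' @param path TSV path.
#' @param samples sample sheet data.frame; defaults to cellular-untreated
#'   for every sample id found.
#' @return named list of [cpd_track_set()], one per region.
#' @export
read_counts_tsv <- function(path, samples = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (is.null(samples)) {
    ids <- sort(unique(d$sample))
    samples <- data.frame(sample = ids, condition = "cellular-untreated",
                          replicate = seq_along(ids))
  }
  out <- lapply(split(d, d$region), function(dr) {
    grid <- unique(dr[order(dr$pos), c("pos", "strand", "class")])
    rownames(grid) <- NULL
    counts <- matrix(0L, nrow(grid), nrow(samples),
                     dimnames = list(NULL, samples$sample))
    i <- match(dr$pos, grid$pos)
    j <- match(dr$sample, samples$sample)
    counts[cbind(i, j)] <- dr$count
    cpd_track_set(grid, counts, samples, region = dr$region[1],
                  region_length = dr$region_length[1])
  })
  out
}

#' Export a per-position signal as a wig track
#'
#' Writes 1-based variableStep records (span 1) for one region; positions
#' are the 0-based dinucleotide starts shifted to 1-based. Values round-trip
#' through a wig reader.
#'
#' @param profile a `cpd_damage_profile` (or any data.frame with `region`,
#'   `pos` and the value column).
#' @param path output path.
#' @param value column to export (default `log2fc_normalized`).
#' @param label track name for the header.
#' @return the path, invisibly.
#' @export
export_wig <- function(profile, path, value = "log2fc_normalized",
                       label = value) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=wiggle_0 name="%s"', label), con)
  for (rg in unique(profile$region)) {
    d <- profile[profile$region == rg, , drop = FALSE]
    writeLines(sprintf("variableStep chrom=%s span=1", rg), con)
    if (nrow(d))
      writeLines(sprintf("%d %.6g", d$pos + 1L, d[[value]]), con)
  }
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with header columns `sample`, `condition`, `replicate`.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition") %in% names(d)))
  d
}

#' Write a simulated dataset to an output directory
#'
#' Writes the region FASTA, mate-1 BED6 records, the truth tables, and the
#' sample sheet.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(sim$sequence, sim$tracks$region),
              file.path(dir, "region.fa"))
  write_bed6(emit_read_pairs(sim$tracks), file.path(dir, "mate1.bed"))
  utils::write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$offsets, file.path(dir, "truth_offsets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$tracks$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: generates the background sequence, plants motif
#' sites, and simulates CPD counts for the default (or supplied) sample
#' sheet.  Sub-seeds for the three stages are derived from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param motifs motif set for planting (default [cpd_motifs()]).
#' @param n_bound,n_unbound planted site counts (see [plant_motif_sites()]).
#' @param samples sample sheet (default [make_sample_sheet()]).
#' @param templates modulation templates (default [signature_templates()]).
#' @param min_gap minimum distance between planted sites.
#' @return list: `sequence`, `truth`, `tracks` (a [cpd_track_set()] with
#'   `$nondipy`).
#' @export
simulate_dataset <- function(config, motifs = cpd_motifs(),
                             n_bound = 1L, n_unbound = 1L,
                             samples = make_sample_sheet(),
                             templates = signature_templates(),
                             min_gap = 250L) {
  s0 <- config$seed %% 2000000000L
  sequence <- generate_region_sequence(config$region_length,
                                       config$gc_fraction, seed = s0)
  planted <- plant_motif_sites(sequence, motifs, n_bound, n_unbound,
                               seed = s0 + 1L, templates = templates,
                               min_gap = min_gap)
  cfg <- config
  cfg$seed <- s0 + 2L
  tracks <- simulate_cpd_counts(cfg, planted$sequence, planted$truth, samples)
  list(sequence = planted$sequence, truth = planted$truth, tracks = tracks)
}
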