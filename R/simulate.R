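# Synthetic Capture CPD-seq data generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# negative-binomial per-diPy detection counts with condition-specific
# diPy-class rates (naked TT elevated relative to cellular), a smooth local
# coverage/ratio bias per condition, copy-number scaling, planted TF binding
# sites whose bound instances multiply the CPD rate at their consensus diPy
# offsets in cellular samples only, and near-zero no-UV background.  Ground
# truth (site locations and per-offset modulation factors) is recorded for
# parameter-recovery and classifier tests.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: 3-5 kb promoter-scale
#' regions sequenced to a depth of ~100 detections per diPy site, nine
#' cellular and nine naked UV-exposed replicates plus three no-UV controls,
#' thymine-dimer-dominated class rates with the naked TT class elevated
#' relative to cellular, and mild replicate overdispersion.
#'
#' @param region_length region length in bases.
#' @param gc_fraction G+C proportion of the random background sequence.
#' @param dipy_rates list with elements `cellular` and `naked`, each a named
#'   vector over TT/TC/CT/CC of relative detection rates (TT = 1 scale).
#' @param depth expected detections per diPy site (at class rate 1) per
#'   sample.
#' @param dispersion NB overdispersion alpha (variance = mu + alpha mu^2);
#'   0 gives Poisson counts.
#' @param bias_smoothness correlation length (bases) of the smooth
#'   multiplicative coverage bias field.
#' @param bias_log_sd standard deviation of the log bias field.
#' @param copy_number positive copy-number scale factor for the region.
#' @param noUV_rate detection rate of no-UV control samples, as a
#'   proportion of `depth`.
#' @param non_dipy_rate proportion of detections placed at non-diPy sites
#'   (sequencing/alignment noise retained for QC of the diPy filter).
#' @param sample_depth_sd lognormal sd of per-sample library-size factors.
#' @param read_length mate-1 read length used when emitting alignments.
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(region_length = 4000,
                              gc_fraction = 0.5,
                              dipy_rates = list(
                                cellular = c(TT = 1.0, TC = 0.55, CT = 0.30, CC = 0.35),
                                naked    = c(TT = 1.3, TC = 0.50, CT = 0.30, CC = 0.35)),
                              depth = 100,
                              dispersion = 0.01,
                              bias_smoothness = 500,
                              bias_log_sd = 0.2,
                              copy_number = 1,
                              noUV_rate = 0.005,
                              non_dipy_rate = 0.01,
                              sample_depth_sd = 0.1,
                              read_length = 36L,
                              seed = 1L) {
  classes <- c("TT", "TC", "CT", "CC")
  stopifnot(region_length >= 1,
            gc_fraction > 0, gc_fraction < 1,
            is.list(dipy_rates),
            all(c("cellular", "naked") %in% names(dipy_rates)),
            all(vapply(dipy_rates, function(r) all(classes %in% names(r)) &&
                         all(r >= 0), logical(1))),
            depth >= 0, dispersion >= 0, copy_number > 0,
            noUV_rate >= 0, non_dipy_rate >= 0, sample_depth_sd >= 0,
            bias_smoothness >= 1)
  structure(list(region_length = as.integer(region_length),
                 gc_fraction = gc_fraction,
                 dipy_rates = lapply(dipy_rates, function(r) r[classes]),
                 depth = depth, dispersion = dispersion,
                 bias_smoothness = bias_smoothness, bias_log_sd = bias_log_sd,
                 copy_number = copy_number, noUV_rate = noUV_rate,
                 non_dipy_rate = non_dipy_rate,
                 sample_depth_sd = sample_depth_sd,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default sample sheet for the emulated study design
#'
#' Three cellular conditions in triplicate (untreated, serum-starved,
#' serum-stimulated), nine naked DNA replicates, and three no-UV controls.
#'
#' @param n_cellular replicates per cellular condition.
#' @param n_naked naked DNA replicates.
#' @param n_nouv no-UV control replicates.
#' @return data.frame with columns `sample`, `condition`, `replicate`.
#' @export
make_sample_sheet <- function(n_cellular = 3L, n_naked = 9L, n_nouv = 3L) {
  rows <- rbind(
    expand.grid(replicate = seq_len(n_cellular),
                condition = c("cellular-untreated", "cellular-starved",
                              "cellular-stimulated"),
                stringsAsFactors = FALSE),
    if (n_naked > 0) data.frame(replicate = seq_len(n_naked), condition = "naked"),
    if (n_nouv > 0) data.frame(replicate = seq_len(n_nouv), condition = "noUV"))
  data.frame(sample = paste(sub("^cellular-", "", rows$condition),
                            rows$replicate, sep = "_"),
             condition = rows$condition,
             replicate = rows$replicate,
             stringsAsFactors = FALSE)
}

#' Synthetic per-offset damage modulation templates
#'
#' Multiplicative CPD-rate factors applied at each consensus diPy offset of a
#' bound site in cellular samples.  These are synthetic defaults that follow
#' the observed direction and scale of real footprints: ETS sites stimulate
#' damage moderately at the TT/TC diPys and strongly (~16x) at the third
#' (CC) diPy; SRF/CArG boxes stimulate the leading CC and (strongly) the CT
#' while protecting the trailing diPy; NF-Y inhibits the leading CC and
#' strongly stimulates the TT opposite the central AA.
#'
#' @return named list: per factor, numeric modulation factors ordered as the
#'   consensus offsets of [cpd_motifs()].
#' @export
signature_templates <- function() {
  list(ETS = c(2, 4, 16),
       SRF = c(2, 8, 0.125),
       NFY = c(0.35, 8))
}

# map a motif offset table to genomic diPy keys for a placed site
.offset_keys <- function(start, strand, width, offsets) {
  if (strand == "+") {
    pos <- start + offsets$offset
    dipy_strand <- ifelse(offsets$strand == "same", "+", "-")
  } else {
    pos <- start + width - 2L - offsets$offset
    dipy_strand <- ifelse(offsets$strand == "same", "-", "+")
  }
  data.frame(offset = offsets$offset, rel_strand = offsets$strand,
             pos = as.integer(pos), dipy_strand = dipy_strand,
             stringsAsFactors = FALSE)
}

# realize an IUPAC string by sampling each ambiguity code uniformly
.realize_iupac <- function(iupac) {
  codes <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(iupac, "")[[1]]], "")
  paste(vapply(codes, function(ch) ch[sample.int(length(ch), 1L)], character(1)),
        collapse = "")
}

#' Plant transcription-factor motif sites into a sequence
#'
#' Writes non-overlapping realizations of the factors' classification motifs
#' into the sequence at random positions and strands, and records ground
#' truth.  Bound sites carry the per-offset modulation factors of
#' `templates`; unbound sites carry factors of 1 everywhere.
#'
#' @param sequence background sequence (string).
#' @param motifs named list of [motif_def()]; defaults to [cpd_motifs()].
#' @param n_bound,n_unbound number of bound / unbound sites to plant; a
#'   single count (recycled over factors) or a named vector per factor.
#' @param seed integer seed.
#' @param templates per-factor modulation factors, as [signature_templates()].
#' @param min_gap minimum distance in bases between planted sites.
#' @param margin keep planted sites at least this far from region edges.
#' @return list with elements `sequence` (modified string) and `truth`
#'   (class `simulation_truth`: `$sites` and `$offsets` data.frames).
#' @export
plant_motif_sites <- function(sequence, motifs = cpd_motifs(),
                              n_bound = 1L, n_unbound = 1L, seed = 1L,
                              templates = signature_templates(),
                              min_gap = 250L, margin = 10L) {
  stopifnot(is.list(motifs), length(motifs) >= 1)
  if (is.null(names(n_bound))) n_bound <- stats::setNames(
    rep(n_bound, length.out = length(motifs)), names(motifs))
  if (is.null(names(n_unbound))) n_unbound <- stats::setNames(
    rep(n_unbound, length.out = length(motifs)), names(motifs))
  req <- do.call(rbind, lapply(names(motifs), function(m) {
    nb <- if (m %in% names(n_bound)) n_bound[[m]] else 0
    nu <- if (m %in% names(n_unbound)) n_unbound[[m]] else 0
    if (nb + nu == 0) return(NULL)
    data.frame(motif = m, bound = rep(c(TRUE, FALSE), c(nb, nu)))
  }))
  if (is.null(req) || nrow(req) == 0)
    return(list(sequence = sequence, truth = .empty_truth()))

  withr::with_seed(seed, {
    req <- req[sample.int(nrow(req)), , drop = FALSE]
    L <- nchar(sequence)
    chars <- .seq_chars(sequence)
    placed <- data.frame(start = integer(), end = integer())
    sites <- vector("list", nrow(req))
    offs <- vector("list", nrow(req))
    for (k in seq_len(nrow(req))) {
      m <- motifs[[req$motif[k]]]
      w <- nchar(m$classification_iupac)
      lo <- margin; hi <- L - w - margin
      if (hi < lo) stop("sequence too short to host requested sites")
      start <- NA_integer_
      for (try in seq_len(2000L)) {
        cand <- sample(lo:hi, 1L)
        if (!nrow(placed) ||
            all(cand + w + min_gap <= placed$start |
                cand >= placed$end + min_gap)) { start <- cand; break }
      }
      if (is.na(start))
        stop("sequence too short to host requested sites (no non-overlapping ",
             "placement found)")
      strand <- sample(c("+", "-"), 1L)
      realization <- .realize_iupac(m$classification_iupac)
      genomic <- if (strand == "+") realization else revcomp(realization)
      chars[(start + 1):(start + w)] <- strsplit(genomic, "")[[1]]
      placed <- rbind(placed, data.frame(start = start, end = start + w))
      keys <- .offset_keys(start, strand, w, m$offsets)
      fac <- if (req$bound[k]) {
        tm <- templates[[req$motif[k]]]
        if (is.null(tm) || length(tm) != nrow(keys))
          stop("no modulation template of matching length for factor ",
               req$motif[k])
        tm
      } else rep(1, nrow(keys))
      sid <- sprintf("%s_%s_%03d", req$motif[k],
                     if (req$bound[k]) "b" else "u", k)
      sites[[k]] <- data.frame(site_id = sid, factor = m$factor,
                               motif = req$motif[k], start = start,
                               strand = strand, width = w,
                               bound = req$bound[k], stringsAsFactors = FALSE)
      offs[[k]] <- cbind(data.frame(site_id = sid, factor = m$factor,
                                    bound = req$bound[k]),
                         keys, modulation = fac)
    }
    truth <- structure(list(sites = do.call(rbind, sites),
                            offsets = do.call(rbind, offs)),
                       class = "simulation_truth")
    rownames(truth$sites) <- rownames(truth$offsets) <- NULL
    list(sequence = paste(chars, collapse = ""), truth = truth)
  })
}

.empty_truth <- function() {
  structure(list(
    sites = data.frame(site_id = character(), factor = character(),
                       motif = character(), start = integer(),
                       strand = character(), width = integer(),
                       bound = logical()),
    offsets = data.frame(site_id = character(), factor = character(),
                         bound = logical(), offset = integer(),
                         rel_strand = character(), pos = integer(),
                         dipy_strand = character(), modulation = numeric())),
    class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d planted sites (%d bound), %d consensus diPy offsets\n",
              nrow(x$sites), sum(x$sites$bound), nrow(x$offsets)))
  invisible(x)
}

# smooth multiplicative bias field: exponentiated, kernel-smoothed Gaussian
# walk with correlation length ~ smoothness, scaled to log-sd `log_sd` and
# mean-normalized to 1 over the region
.bias_field <- function(length, smoothness, log_sd) {
  if (log_sd <= 0) return(rep(1, length))
  k <- max(3L, as.integer(smoothness))
  z <- cumsum(stats::rnorm(length + 2L * k))
  kern <- stats::dnorm(seq(-3, 3, length.out = 2L * k + 1L))
  kern <- kern / sum(kern)
  sm <- stats::filter(z, kern, sides = 2)
  sm <- as.numeric(sm[(k + 1L):(k + length)])
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (is.na(s) || s == 0) return(rep(1, length))
  b <- exp(sm / s * log_sd)
  b / mean(b)
}

.condition_class <- function(condition) {
  ifelse(startsWith(condition, "cellular"), "cellular",
         ifelse(condition == "naked", "naked",
                ifelse(condition == "noUV", "noUV", NA_character_)))
}

#' Simulate per-diPy CPD detection counts
#'
#' Counts at each diPy position are drawn from a negative binomial with
#' mean `depth * copy_number * bias(pos) * class_rate(diPy, condition) *
#' modulation(pos, condition)` and variance `mu + dispersion * mu^2`.
#' Modulation factors from bound planted sites apply in cellular conditions
#' only; no-UV samples are scaled by `noUV_rate`.  Each condition class
#' (cellular vs naked) gets an independent smooth bias field, so the
#' cell/naked ratio carries the local bias the 250-bp window correction is
#' designed to remove.  A `non_dipy_rate` fraction of detections is placed
#' at non-diPy dinucleotides and returned separately (it is removed by the
#' diPy filter downstream).
#'
#' DiPy positions too close to the region boundary to be encoded as mate-1
#' records (the first '+'-strand and the last '-'-strand dinucleotide) are
#' assigned zero rate so that emitted reads always round-trip exactly.
#'
#' @param config a [simulation_config()].
#' @param sequence region sequence (typically from [plant_motif_sites()]).
#' @param truth a `simulation_truth` (or NULL for no modulation).
#' @param samples sample sheet data.frame (see [make_sample_sheet()]).
#' @return a [cpd_track_set()] with an extra element `nondipy`: a data.frame
#'   (`sample`, `pos`, `strand`, `count`) of non-diPy detections.
#' @export
simulate_cpd_counts <- function(config, sequence, truth = NULL,
                                samples = make_sample_sheet()) {
  stopifnot(inherits(config, "simulation_config"))
  cond_class <- .condition_class(samples$condition)
  if (anyNA(cond_class))
    stop("unknown condition label: ",
         paste(unique(samples$condition[is.na(cond_class)]), collapse = ", "))
  grid <- dipy_index(sequence)
  L <- nchar(sequence)

  withr::with_seed(config$seed, {
    bias <- list(cellular = .bias_field(L, config$bias_smoothness, config$bias_log_sd),
                 naked    = .bias_field(L, config$bias_smoothness, config$bias_log_sd))
    bias$noUV <- bias$cellular
    jitter <- if (config$sample_depth_sd > 0)
      exp(stats::rnorm(nrow(samples), 0, config$sample_depth_sd)) else
      rep(1, nrow(samples))

    mod <- rep(1, nrow(grid))
    if (!is.null(truth) && nrow(truth$offsets)) {
      key <- paste(grid$pos, grid$strand)
      hit <- match(paste(truth$offsets$pos, truth$offsets$dipy_strand), key)
      ok <- !is.na(hit)
      mod[hit[ok]] <- mod[hit[ok]] * truth$offsets$modulation[ok]
    }

    encodable <- !((grid$strand == "+" & grid$pos < 1L) |
                   (grid$strand == "-" & grid$pos > L - 3L))
    base <- config$depth * config$copy_number
    counts <- matrix(0L, nrow(grid), nrow(samples),
                     dimnames = list(NULL, samples$sample))
    for (j in seq_len(nrow(samples))) {
      cc <- cond_class[j]
      rates <- if (cc == "naked") config$dipy_rates$naked else config$dipy_rates$cellular
      mu <- base * bias[[cc]][grid$pos + 1L] * rates[grid$class] * jitter[j]
      if (cc == "cellular") mu <- mu * mod
      if (cc == "noUV") mu <- mu * config$noUV_rate
      mu[!encodable] <- 0
      counts[, j] <- as.integer(if (config$dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      else stats::rpois(length(mu), mu))
    }

    nondipy <- .simulate_nondipy(config, sequence, samples, cond_class, jitter)
    ts <- cpd_track_set(grid, counts, samples, region = "simregion",
                        region_length = L)
    ts$nondipy <- nondipy
    ts
  })
}

# uniform non-diPy detections over mixed (YR/RY) dinucleotide starts
.simulate_nondipy <- function(config, sequence, samples, cond_class, jitter) {
  empty <- data.frame(sample = character(), pos = integer(),
                      strand = character(), count = integer())
  if (config$non_dipy_rate <= 0) return(empty)
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 4L) return(empty)
  b1 <- chars[-n]; b2 <- chars[-1L]
  mixed <- which(!((b1 %in% PYRIMIDINES & b2 %in% PYRIMIDINES) |
                   (b1 %in% PURINES & b2 %in% PURINES))) - 1L
  # keep encodable range on both strands
  mixed <- mixed[mixed >= 1L & mixed <= n - 3L]
  if (!length(mixed)) return(empty)
  mean_rate <- mean(config$dipy_rates$cellular)
  out <- lapply(seq_len(nrow(samples)), function(j) {
    scale <- if (cond_class[j] == "noUV") config$noUV_rate else 1
    lambda <- config$non_dipy_rate * config$depth * config$copy_number *
      mean_rate * length(mixed) * jitter[j] * scale
    ndet <- stats::rpois(1L, lambda)
    if (ndet == 0) return(empty)
    pos <- sample(mixed, ndet, replace = TRUE)
    strand <- sample(c("+", "-"), ndet, replace = TRUE)
    agg <- stats::aggregate(list(count = rep(1L, ndet)),
                            by = list(pos = pos, strand = strand), FUN = sum)
    data.frame(sample = samples$sample[j], agg)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
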