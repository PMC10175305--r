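# Damage-signature extraction at motif sites and nearest-neighbor occupancy
# classification.
#
# A site's signature is the vector of class-normalized cell/naked log2 fold
# changes at its consensus diPy offsets, ordered in motif orientation.  The
# classifier compares the signature's Euclidean distance to bound exemplars
# and to a theoretical neutral site (the all-zero vector, i.e. no damage
# modulation at any informative position); ties go to unbound.

#' Assign genomic diPy keys and informativeness to a motif site
#'
#' For each consensus diPy offset of the site's motif, records the genomic
#' dinucleotide start and strand if the realized reference sequence carries
#' a diPy there on the required strand, and marks the offset absent
#' otherwise.  A site is informative when every consensus offset is present
#' (display-motif matches, e.g. a CArG box with a non-pyrimidine in a key
#' position, can be uninformative).
#'
#' @param site one-row data.frame (or list) with `start`, `strand` and
#'   optionally `width`; coordinates are region-local, 0-based.
#' @param motif the site's [motif_def()].
#' @param reference forward region sequence (string).
#' @return list with `keys`: data.frame (`offset`, `rel_strand`, `pos`,
#'   `dipy_strand`, `class`, `present`), and `informative` flag.
#' @export
assign_dipy_offsets <- function(site, motif, reference) {
  width <- if (!is.null(site$width)) site$width else nchar(motif$iupac)
  keys <- .offset_keys(site$start, site$strand, width, motif$offsets)
  fwd <- substring(reference, keys$pos + 1L, keys$pos + 2L)
  present <- ifelse(keys$dipy_strand == "+",
                    grepl("^[CT][CT]$", fwd),
                    grepl("^[AG][AG]$", fwd))
  cls <- ifelse(keys$dipy_strand == "+", fwd, revcomp(fwd))
  cls[!present] <- NA_character_
  keys$class <- cls
  keys$present <- present
  list(keys = keys, informative = all(present))
}

#' Extract a damage-signature vector at a motif site
#'
#' Looks up the class-normalized log2 fold change at each of the site's
#' consensus diPy keys, ordered by motif offset.  Uninformative sites are
#' not classifiable and yield an explicit failure rather than a zero-filled
#' vector.
#'
#' @param profile a `cpd_damage_profile` from [compare_groups()].
#' @param site as in [assign_dipy_offsets()].
#' @param motif the site's [motif_def()].
#' @param reference forward region sequence.
#' @return numeric signature vector (length = number of consensus offsets)
#'   with attributes `keys` and `informative`; for an uninformative site the
#'   vector is all-NA with `informative = FALSE`, an explicit
#'   not-classifiable result rather than a silent zero fill.
#' @export
extract_signature <- function(profile, site, motif, reference) {
  asg <- assign_dipy_offsets(site, motif, reference)
  if (!asg$informative) {
    out <- rep(NA_real_, nrow(asg$keys))
    attr(out, "informative") <- FALSE
    attr(out, "keys") <- asg$keys
    return(out)
  }
  i <- match(paste(asg$keys$pos, asg$keys$dipy_strand),
             paste(profile$pos, profile$strand))
  if (anyNA(i))
    stop("site diPy key not present in damage profile (site at ",
         site$start, site$strand, ")")
  out <- profile$log2fc_normalized[i]
  attr(out, "informative") <- TRUE
  attr(out, "keys") <- asg$keys
  out
}

#' Classify one signature vector as bound or unbound
#'
#' Nearest-neighbor rule: the distance to a class is the minimum Euclidean
#' distance over that class's exemplars; the neutral class (all-zero
#' exemplar by definition) maps to "unbound" and bound exemplars to
#' "bound".  Exact distance ties are resolved as "unbound".
#'
#' @param signature numeric signature vector.
#' @param exemplars data.frame with columns `factor`, `label` ("bound" or
#'   "neutral") and a list-column `values` (numeric vectors), or a list of
#'   such vectors per label; must contain at least one exemplar.
#' @return "bound" or "unbound" (NA for an uninformative signature).
#' @export
classify_site <- function(signature, exemplars) {
  if (isFALSE(attr(signature, "informative")) || anyNA(signature))
    return(NA_character_)
  stopifnot(is.data.frame(exemplars), nrow(exemplars) >= 1,
            all(c("label", "values") %in% names(exemplars)))
  d <- vapply(exemplars$values, function(v) {
    stopifnot(length(v) == length(signature))
    sqrt(sum((as.numeric(signature) - v)^2))
  }, numeric(1))
  d_bound <- suppressWarnings(min(d[exemplars$label == "bound"]))
  d_neutral <- suppressWarnings(min(d[exemplars$label == "neutral"]))
  if (!is.finite(d_bound) && !is.finite(d_neutral))
    stop("no exemplars for factor")
  if (is.finite(d_bound) && d_bound < d_neutral) "bound" else "unbound"
}

#' Build an exemplar table for a factor
#'
#' Always includes the theoretical neutral site (all-zero vector: no damage
#' modulation at any informative position) alongside the supplied bound
#' exemplars.
#'
#' @param factor factor id.
#' @param bound list of numeric vectors (one or two positive examples with
#'   ChIP support, or synthetic template signatures).
#' @return exemplar data.frame for [classify_site()].
#' @export
make_exemplars <- function(factor, bound) {
  if (!is.list(bound)) bound <- list(bound)
  if (!length(bound)) stop("no exemplars for factor")
  len <- unique(lengths(bound))
  stopifnot(length(len) == 1)
  out <- data.frame(factor = factor,
                    label = c(rep("bound", length(bound)), "neutral"))
  out$values <- c(bound, list(rep(0, len)))
  out
}

#' Synthetic default exemplars from the generator's signature templates
#'
#' Log2 of the per-offset modulation factors of [signature_templates()];
#' synthetic stand-ins, labeled as such, for ChIP-supported real exemplars.
#'
#' @return named list of exemplar data.frames, one per factor key.
#' @export
default_exemplars <- function() {
  tm <- signature_templates()
  stats::setNames(lapply(names(tm), function(m)
    make_exemplars(m, list(log2(tm[[m]])))), names(tm))
}

#' Scan, extract signatures, and classify all motif sites in a region
#'
#' @param profile a `cpd_damage_profile` (cellular vs naked comparison).
#' @param reference forward region sequence.
#' @param motifs named list of [motif_def()] (default [cpd_motifs()]).
#' @param exemplars named list of exemplar data.frames per motif key
#'   (default [default_exemplars()]).
#' @param chip_peaks optional named list of lists of peak interval
#'   data.frames (`start`, `end`, 0-based half-open, region-local) per motif
#'   key; a site is ChIP-supported when it overlaps a peak in *every*
#'   supplied file for its factor.
#' @return site table data.frame: `region`, `start`, `strand`, `factor`,
#'   `informative`, `signature` (list-column), `predicted`, `chip_overlap`.
#' @export
classify_sites <- function(profile, reference, motifs = cpd_motifs(),
                           exemplars = default_exemplars(),
                           chip_peaks = NULL) {
  region <- unique(profile$region)
  rows <- list()
  for (m in names(motifs)) {
    sites <- scan_motifs(reference, motifs[[m]])
    if (!nrow(sites)) next
    for (k in seq_len(nrow(sites))) {
      site <- sites[k, ]
      sig <- extract_signature(profile, site, motifs[[m]], reference)
      pred <- if (isTRUE(attr(sig, "informative")))
        classify_site(sig, exemplars[[m]]) else NA_character_
      chip <- if (!is.null(chip_peaks) && !is.null(chip_peaks[[m]]))
        all(vapply(chip_peaks[[m]], function(pk)
          any(pk$start < site$start + site$width & pk$end > site$start),
          logical(1))) else NA
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, start = site$start, strand = site$strand,
        factor = motifs[[m]]$factor, motif = m,
        informative = isTRUE(attr(sig, "informative")),
        predicted = pred, chip_overlap = chip, stringsAsFactors = FALSE)
      rows[[length(rows)]]$signature <- list(as.numeric(sig))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
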