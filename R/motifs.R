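# Motif definitions and IUPAC scanning.
#
# Each factor carries two motif strings: a permissive "display" motif used to
# enumerate candidate sites, and a stricter "classification" motif whose
# consensus forces a diPy at every informative offset.  Candidate sites from
# the display motif whose realized sequence lacks a diPy at a classification
# offset are flagged uninformative and are not classifiable.

#' Define a transcription-factor motif for CPD footprinting
#'
#' @param factor factor identifier (e.g. "ETS").
#' @param iupac display motif as an IUPAC string; all matches on either
#'   strand are candidate sites.
#' @param classification_iupac stricter motif whose consensus forces the
#'   diPys used for classification; defaults to `iupac`.
#' @param offsets data.frame with columns `offset` (0-based position of the
#'   leftmost base of each consensus diPy, in motif orientation) and
#'   `strand` ("same" or "opposite", relative to the motif strand).
#' @return object of class `motif_def`.
#' @export
motif_def <- function(factor, iupac, offsets, classification_iupac = iupac) {
  stopifnot(is.character(factor), is.character(iupac),
            is.data.frame(offsets),
            all(c("offset", "strand") %in% names(offsets)),
            all(offsets$strand %in% c("same", "opposite")),
            all(offsets$offset >= 0),
            all(offsets$offset + 2 <= nchar(classification_iupac)))
  structure(list(factor = factor, iupac = toupper(iupac),
                 classification_iupac = toupper(classification_iupac),
                 offsets = offsets),
            class = "motif_def")
}

#' @export
print.motif_def <- function(x, ...) {
  cat(sprintf("motif_def %s: %s (classification %s), %d consensus diPy offsets\n",
              x$factor, x$iupac, x$classification_iupac, nrow(x$offsets)))
  invisible(x)
}

#' Built-in motif set for ETS, SRF/CArG and NF-Y
#'
#' ETS sites match TTCCK with three consensus diPys (TT, TC, CC) on the
#' motif strand.  SRF/CArG sites are enumerated with the permissive CArG box
#' CCW6GG; classification uses the stricter CCTW5GG whose consensus carries
#' CC and CT on the motif strand plus the trailing GG, a CC diPy on the
#' opposite strand.  NF-Y sites match CCAAT with the leading CC on the motif
#' strand and the TT opposite the central AA.
#'
#' @param set `"classification"` (default) for footprint classification,
#'   `"aggregate"` for the stricter non-degenerate motifs used when
#'   summarizing sparse genome-wide detections (SRF CCTTW4GG, ETS YYTTCCK,
#'   NF-Y CCAAT).
#' @return named list of [motif_def()] objects.
#' @export
cpd_motifs <- function(set = c("classification", "aggregate")) {
  set <- match.arg(set)
  if (set == "classification") {
    list(
      ETS = motif_def("ETS", "TTCCK",
        offsets = data.frame(offset = c(0L, 1L, 2L),
                             strand = c("same", "same", "same"))),
      SRF = motif_def("SRF", "CCWWWWWWGG",
        classification_iupac = "CCTWWWWWGG",
        offsets = data.frame(offset = c(0L, 1L, 8L),
                             strand = c("same", "same", "opposite"))),
      NFY = motif_def("NF-Y", "CCAAT",
        offsets = data.frame(offset = c(0L, 2L),
                             strand = c("same", "opposite")))
    )
  } else {
    list(
      ETS = motif_def("ETS", "YYTTCCK",
        offsets = data.frame(offset = c(2L, 3L, 4L),
                             strand = c("same", "same", "same"))),
      SRF = motif_def("SRF", "CCTTWWWWGG",
        offsets = data.frame(offset = c(0L, 1L, 2L, 8L),
                             strand = c("same", "same", "same", "opposite"))),
      NFY = motif_def("NF-Y", "CCAAT",
        offsets = data.frame(offset = c(0L, 2L),
                             strand = c("same", "opposite")))
    )
  }
}

#' Scan a sequence for motif matches on both strands
#'
#' Reports every match of the motif's display IUPAC string on either strand,
#' including overlapping matches.  Matching uses [Biostrings::matchPattern()]
#' with IUPAC ambiguity codes enabled.
#'
#' @param sequence forward region sequence (string or `DNAString`).
#' @param motif a [motif_def()] object, or a plain IUPAC string.
#' @param use which motif string to scan with: `"display"` (default) or
#'   `"classification"`.
#' @return data.frame with columns `start` (0-based genomic start of the
#'   match), `strand` ("+"/"-"), `factor`, `width`, ordered by start.
#'   A '-' match means the reverse complement of the forward sequence at
#'   \[start, start+width) equals the motif.
#' @export
scan_motifs <- function(sequence, motif, use = c("display", "classification")) {
  use <- match.arg(use)
  if (is.character(motif)) motif <- motif_def("motif", motif,
    offsets = data.frame(offset = integer(), strand = character()))
  pat <- if (use == "display") motif$iupac else motif$classification_iupac
  subject <- if (is(sequence, "DNAString")) sequence else Biostrings::DNAString(toupper(sequence))
  if (nchar(pat) > length(subject)) {
    return(data.frame(start = integer(), strand = character(),
                      factor = character(), width = integer()))
  }
  fixed <- c(pattern = FALSE, subject = TRUE)  # N in the subject never matches
  fwd <- Biostrings::matchPattern(pat, subject, fixed = fixed)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(pat)),
    subject, fixed = fixed)
  n <- length(fwd) + length(rev)
  out <- data.frame(
    start = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    factor = rep(motif$factor, n),
    width = rep(nchar(pat), n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
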