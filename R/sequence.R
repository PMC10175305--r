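# Sequence-level utilities: dipyrimidine indexing and random region synthesis.
#
# CPDs form exclusively at dipyrimidines (diPy: TT, TC, CT, CC read 5'->3' on
# one strand).  On the forward reference a diPy on '+' is a YY dinucleotide
# and a diPy on '-' is an RR dinucleotide (its reverse complement is YY), so
# the two strands can never carry a diPy at the same dinucleotide start.

PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

.seq_chars <- function(sequence) {
  if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)[1L]
  stopifnot(is.character(sequence), length(sequence) == 1L)
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Index all dipyrimidine positions of a sequence
#'
#' Lists every dinucleotide start (0-based, leftmost base) that is a
#' dipyrimidine on either strand, together with the strand and the diPy
#' class (TT, TC, CT or CC) read 5'->3' on the diPy strand.  A dinucleotide
#' containing an N (or any non-ACGT code) is never a diPy.
#'
#' @param sequence character string, `DNAString`, or first element of a
#'   `DNAStringSet`; the forward reference sequence of the region.
#' @return data.frame with columns `pos` (0-based dinucleotide start),
#'   `strand` ("+" or "-") and `class` (factor-free character, one of
#'   TT/TC/CT/CC), ordered by position.
#' @export
dipy_index <- function(sequence) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 2L) {
    return(data.frame(pos = integer(), strand = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  b1 <- chars[-n]
  b2 <- chars[-1L]
  y1 <- b1 %in% PYRIMIDINES; y2 <- b2 %in% PYRIMIDINES
  r1 <- b1 %in% PURINES;     r2 <- b2 %in% PURINES
  plus <- which(y1 & y2)
  minus <- which(r1 & r2)
  cls_plus <- paste0(b1[plus], b2[plus])
  # on '-' the diPy reads as the reverse complement of the forward dinucleotide
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cls_minus <- paste0(comp[b2[minus]], comp[b1[minus]])
  out <- data.frame(
    pos = c(plus, minus) - 1L,
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    class = c(cls_plus, cls_minus),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of bases that are part of at least one diPy
#'
#' A base pair is potentially informative for CPD footprinting when it is
#' part of a dipyrimidine on either strand; by purine/pyrimidine
#' complementarity this covers roughly three quarters of a random genome.
#'
#' @inheritParams dipy_index
#' @return single numeric proportion in \[0, 1\].
#' @export
dipy_coverage_fraction <- function(sequence) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n == 0L) return(NA_real_)
  idx <- dipy_index(sequence)
  covered <- logical(n)
  covered[idx$pos + 1L] <- TRUE
  covered[idx$pos + 2L] <- TRUE
  mean(covered)
}

#' Generate a random region sequence
#'
#' Bases are drawn i.i.d. with G+C probability `gc_fraction` (G and C
#' equiprobable, likewise A and T).
#'
#' @param length region length in bases (>= 1).
#' @param gc_fraction target G+C proportion in \[0, 1\].
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return character string over A/C/G/T of the requested length.
#' @export
generate_region_sequence <- function(length, gc_fraction = 0.5, seed = 1L) {
  if (length < 1L) stop("region length must be >= 1")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  withr::with_seed(seed,
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
}
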