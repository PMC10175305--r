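# Independent brute-force oracles and small fixture builders used across the
# suite.  These deliberately avoid the package's own code paths.

# all-offsets IUPAC scan using regex character classes
oracle_iupac_scan <- function(sequence, iupac) {
  iupac_regex <- function(s) {
    map <- Biostrings::IUPAC_CODE_MAP
    paste0(vapply(strsplit(s, "")[[1]],
                  function(ch) paste0("[", map[[ch]], "]"), character(1)),
           collapse = "")
  }
  rc_pat <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
  w <- nchar(iupac)
  L <- nchar(sequence)
  if (w > L) return(data.frame(start = integer(), strand = character()))
  hits <- list()
  for (s in 0:(L - w)) {
    sub <- substr(sequence, s + 1, s + w)
    if (grepl(paste0("^", iupac_regex(iupac), "$"), sub))
      hits[[length(hits) + 1]] <- data.frame(start = s, strand = "+")
    if (grepl(paste0("^", iupac_regex(rc_pat), "$"), sub))
      hits[[length(hits) + 1]] <- data.frame(start = s, strand = "-")
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), strand = character())
  out[order(out$start, out$strand), , drop = FALSE]
}

# exact two-sided conditional test via binomial enumeration (Poisson model);
# the implementation normalizes a product of two Poisson pmfs, which equals
# this by the binomial-conditioning identity
oracle_exact_p <- function(ka, kb, sa, sb) {
  ks <- ka + kb
  probs <- stats::dbinom(0:ks, ks, sa / (sa + sb))
  pobs <- probs[ka + 1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-8)]))
}

# per-start dipyrimidine check by direct substring inspection
oracle_dipy_index <- function(sequence) {
  L <- nchar(sequence)
  rows <- list()
  for (s in 0:(L - 2)) {
    d <- substr(sequence, s + 1, s + 2)
    b <- strsplit(d, "")[[1]]
    if (all(b %in% c("C", "T"))) {
      rows[[length(rows) + 1]] <- data.frame(pos = s, strand = "+", class = d)
    } else if (all(b %in% c("A", "G"))) {
      rc <- chartr("ACGT", "TGCA", paste(rev(b), collapse = ""))
      rows[[length(rows) + 1]] <- data.frame(pos = s, strand = "-", class = rc)
    }
  }
  if (!length(rows)) return(data.frame(pos = integer(), strand = character(),
                                       class = character()))
  do.call(rbind, rows)
}

# reverse-complement a track set: mirror coordinates, flip strands
flip_track <- function(ts) {
  L <- ts$region_length
  pos2 <- L - 2L - ts$positions$pos
  strand2 <- ifelse(ts$positions$strand == "+", "-", "+")
  o <- order(pos2)
  out <- cpd_track_set(
    data.frame(pos = pos2, strand = strand2,
               class = ts$positions$class)[o, ],
    ts$counts[o, , drop = FALSE], ts$samples, ts$region, L)
  out
}

# small deterministic track set built by hand
toy_track <- function(counts, positions = NULL, conditions = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(positions))
    positions <- data.frame(pos = seq_len(n) - 1L,
                            strand = rep(c("+", "-"), length.out = n),
                            class = rep(c("TT", "TC", "CT", "CC"),
                                        length.out = n))
  ids <- paste0("s", seq_len(ncol(counts)))
  colnames(counts) <- ids
  if (is.null(conditions)) conditions <- rep("cellular-untreated", ncol(counts))
  cpd_track_set(positions, counts,
                data.frame(sample = ids, condition = conditions,
                           replicate = seq_along(ids)),
                region = "toy", region_length = max(positions$pos) + 2L)
}

random_acgt <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}
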