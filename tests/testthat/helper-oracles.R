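# Independent oracles used across the suite. These re-derive expected values
# by routes disjoint from the implementation under test: Biostrings for
# reverse complementation, an exhaustive all-windows scorer for motif calls,
# and per-residue elemental compositions for peptide masses.

bs_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# exhaustive all-windows scorer for the default reference/degeneracy rule;
# classifies every window carrying the (degenerate) hexamer at the anchor
# offset and picks the best call by the stated tie-break
oracle_scan <- function(seq, ref = reference_motif(),
                        max_dev_full = 7L) {
  seq <- toupper(seq)
  L <- ref$length
  n <- nchar(seq)
  refc <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  h <- ref$hexamer_offset
  calls <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") seq else bs_revcomp(seq)
    if (n < L) break
    for (a in 0:(n - L)) {
      win <- substr(oriented, a + 1L, a + L)
      hex <- substr(win, h + 1L, h + 6L)
      if (substr(hex, 2L, 6L) != "AGAAT") next
      if (!substr(hex, 1L, 1L) %in% c("A", "C", "T")) next
      w <- strsplit(win, "", fixed = TRUE)[[1L]]
      dev <- w != refc
      if (w[h + 1L] %in% c("A", "C", "T")) dev[h + 1L] <- FALSE
      dev[w == "N"] <- TRUE
      dev <- sum(dev)
      core <- grepl("TGACG", win, fixed = TRUE) ||
        grepl("CGTCA", win, fixed = TRUE)
      calls[[length(calls) + 1L]] <- data.frame(
        window_start = if (strand == "+") a else n - L - a,
        strand = strand, deviations = dev, core_present = core,
        motif_class = if (core && dev <= max_dev_full) "FULL" else "PARTIAL",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    return(data.frame(window_start = NA_integer_, strand = NA_character_,
                      deviations = NA_integer_, core_present = NA,
                      motif_class = "ABSENT", stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, calls))
  rank <- c(FULL = 3L, PARTIAL = 2L, ABSENT = 1L)
  df[order(-rank[df$motif_class], df$deviations, df$window_start,
           df$strand != "+"), ][1L, ]
}

# elemental compositions of the 20 residues (C, H, N, O, S atom counts)
residue_elements <- list(
  A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
  M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
  Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0))

# monoisotopic atomic masses (C, H, N, O, S)
atomic_mono <- c(12, 1.00782503207, 14.0030740048, 15.9949146196, 31.97207100)

elemental_peptide_mass <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  counts <- Reduce(`+`, residue_elements[ch])
  counts <- counts + c(0, 2, 0, 1, 0)  # one water
  sum(counts * atomic_mono)
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_peptide <- function(len) {
  paste(sample(names(residue_elements), len, replace = TRUE), collapse = "")
}
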