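#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement, reversed. `N` maps to `N`. Needed because the
#' TGACG core of the AAGAAT-type element sits on the reverse strand of the
#' reference element, so candidate windows on either strand must be brought
#' into a common orientation.
#'
#' @param seq Single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return The reverse complement, upper case.
#' @examples
#' revcomp("TGACG")   # "CGTCA"
#' revcomp("AAGAAT")  # "ATTCTT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  }
  chars <- strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1L]]
  paste(rev(chars), collapse = "")
}

#' Reference AAGAAT-type regulatory element
#'
#' Describes the fixed-length window against which candidates are compared:
#' the element sequence, where the anchoring AAGAAT hexamer sits inside it,
#' the TGACG core, and which window positions are degenerate (by default the
#' first hexamer position, where A may be replaced by C or T).
#'
#' The 33-bp element of the Arabidopsis *AGAMOUS* second intron is not
#' bundled; supply it via `sequence` (or a YAML config, see
#' [read_motif_config()]). The default is a synthetic 33-nt element with the
#' hexamer at the 5' end and the core in reverse-complement orientation
#' (`CGTCA` on the given strand), mirroring the architecture of the natural
#' element, and is intended for simulation and testing.
#'
#' @param sequence Nucleotide string of length `L` containing `AAGAAT` at
#'   `hexamer_offset`.
#' @param hexamer_offset 0-based index of the AAGAAT hexamer within the
#'   window.
#' @param core Core recognition sequence (default `"TGACG"`, the minimal
#'   TGA-factor binding site).
#' @param degenerate_positions Named list mapping 0-based window index to a
#'   character vector of allowed nucleotides. Default: the first hexamer
#'   position allows `A`, `C`, `T`.
#' @return An object of class `reference_motif`.
#' @export
reference_motif <- function(sequence = NULL,
                            hexamer_offset = 0L,
                            core = "TGACG",
                            degenerate_positions = NULL) {
  if (is.null(sequence)) sequence <- .default_ref_sequence
  sequence <- toupper(sequence)
  core <- toupper(core)
  L <- nchar(sequence)
  hexamer_offset <- as.integer(hexamer_offset)
  if (grepl("[^ACGTN]", sequence)) stop("reference sequence contains non-nucleotide characters")
  if (hexamer_offset < 0L || hexamer_offset + 6L > L) {
    stop("hexamer_offset + 6 must lie within the window")
  }
  if (substr(sequence, hexamer_offset + 1L, hexamer_offset + 6L) != "AAGAAT") {
    stop("reference sequence must carry AAGAAT at hexamer_offset")
  }
  if (is.null(degenerate_positions)) {
    degenerate_positions <- stats::setNames(
      list(c("A", "C", "T")), as.character(hexamer_offset))
  }
  structure(
    list(sequence = sequence, length = L, hexamer_offset = hexamer_offset,
         core = core, degenerate_positions = degenerate_positions),
    class = "reference_motif")
}

# synthetic stand-in element: AAGAAT anchor at offset 0, CGTCA (reverse-strand
# TGACG core) central, no secondary hexamer or core occurrences on either strand
.default_ref_sequence <- "AAGAATGTATTACATCGTCATTGGCTAATCACG"

#' @export
print.reference_motif <- function(x, ...) {
  cat("Reference motif (", x$length, " nt)\n", sep = "")
  cat("  sequence:       ", x$sequence, "\n", sep = "")
  cat("  hexamer offset: ", x$hexamer_offset, " (0-based)\n", sep = "")
  cat("  core:           ", x$core, "\n", sep = "")
  dg <- vapply(names(x$degenerate_positions), function(p)
    sprintf("%s:{%s}", p, paste(x$degenerate_positions[[p]], collapse = ",")),
    character(1))
  cat("  degenerate:     ", paste(dg, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Classifier parameters for motif calling
#'
#' @param max_dev_full Maximum number of nucleotide deviations from the
#'   reference window still compatible with a full motif (default 7).
#' @param min_dev_partial_report Deviation count above which a partial motif
#'   is flagged as a canonical partial motif (default 15); descriptive, not a
#'   gate.
#' @param core_both_strands Search the core (and the hexamer anchor) on both
#'   strands (default `TRUE`).
#' @param count_degenerate_as_match Treat a window letter within a degenerate
#'   position's allowed set as a match (default `TRUE`).
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(max_dev_full = 7L,
                              min_dev_partial_report = 15L,
                              core_both_strands = TRUE,
                              count_degenerate_as_match = TRUE) {
  max_dev_full <- as.integer(max_dev_full)
  min_dev_partial_report <- as.integer(min_dev_partial_report)
  if (max_dev_full < 0L || max_dev_full >= min_dev_partial_report) {
    stop("need 0 <= max_dev_full < min_dev_partial_report")
  }
  structure(list(max_dev_full = max_dev_full,
                 min_dev_partial_report = min_dev_partial_report,
                 core_both_strands = core_both_strands,
                 count_degenerate_as_match = count_degenerate_as_match),
            class = "classifier_params")
}

# degenerate-aware hexamer regex, e.g. "[ACT]AGAAT" for the default rule
.hexamer_pattern <- function(ref) {
  hex <- strsplit("AAGAAT", "")[[1L]]
  idx <- ref$hexamer_offset + seq_len(6L) - 1L  # 0-based window indices
  parts <- vapply(seq_len(6L), function(i) {
    allowed <- ref$degenerate_positions[[as.character(idx[i])]]
    if (is.null(allowed) || !any(allowed != hex[i])) hex[i]
    else paste0("[", paste(sort(unique(c(hex[i], allowed))), collapse = ""), "]")
  }, character(1))
  paste(parts, collapse = "")
}

.find_pattern_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L  # 0-based
}

#' Locate (degenerate) AAGAAT hexamer anchors
#'
#' Finds every occurrence of the hexamer anchor, with the degeneracy rule
#' applied (default: first position may be A, C or T), on the forward strand
#' and, when `both_strands`, on the reverse strand. Reverse-strand hits are
#' reported in forward 0-based coordinates of the hexamer start.
#'
#' @param seq Nucleotide string (length >= 6).
#' @param ref A [reference_motif()].
#' @param both_strands Search the reverse strand too (default `TRUE`).
#' @return `data.frame(position, strand)` sorted by position, `+` before `-`
#'   at ties; zero rows when there is no hit.
#' @export
find_hexamer_sites <- function(seq, ref = reference_motif(), both_strands = TRUE) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 6L)
  pat <- .hexamer_pattern(ref)
  fwd <- .find_pattern_starts(seq, pat)
  out <- data.frame(position = fwd,
                    strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    n <- nchar(seq)
    rev_hits <- .find_pattern_starts(revcomp(seq), pat)
    if (length(rev_hits)) {
      out <- rbind(out, data.frame(position = n - rev_hits - 6L,
                                   strand = "-", stringsAsFactors = FALSE))
    }
  }
  out[order(out$position, out$strand != "+"), , drop = FALSE]
}

#' Extract the reference-frame window around a hexamer hit
#'
#' Returns the `L`-nt window, in reference orientation, whose hexamer aligns
#' with `ref$hexamer_offset`; `NULL` when the window would overrun either end
#' of the sequence. For minus-strand hits the window is the reverse
#' complement of the corresponding forward slice.
#'
#' @param seq Nucleotide string.
#' @param position 0-based forward-strand start of the hexamer hit.
#' @param strand `"+"` or `"-"`.
#' @param ref A [reference_motif()].
#' @return `list(window_seq, window_start)` or `NULL`.
#' @export
extract_window <- function(seq, position, strand, ref = reference_motif()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  L <- ref$length
  h <- ref$hexamer_offset
  a <- if (strand == "+") position - h else position - (L - h - 6L)
  if (a < 0L || a + L > n) return(NULL)
  win <- substr(seq, a + 1L, a + L)
  if (strand == "-") win <- revcomp(win)
  list(window_seq = win, window_start = a)
}

#' Count nucleotide deviations from the reference window
#'
#' Ungapped per-position (Hamming) comparison over the fixed window frame.
#' A position listed as degenerate matches whenever the window letter is in
#' its allowed set (unless `count_degenerate_as_match` is off). `N` always
#' counts as a deviation.
#'
#' @param window_seq Window of length `ref$length`.
#' @param ref A [reference_motif()].
#' @param params A [classifier_params()].
#' @return Integer deviation count.
#' @export
count_deviations <- function(window_seq, ref = reference_motif(),
                             params = classifier_params()) {
  window_seq <- toupper(window_seq)
  if (nchar(window_seq) != ref$length) {
    stop(sprintf("window length %d != reference length %d",
                 nchar(window_seq), ref$length))
  }
  w <- strsplit(window_seq, "", fixed = TRUE)[[1L]]
  r <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  dev <- w != r
  dev[w == "N"] <- TRUE
  if (params$count_degenerate_as_match) {
    for (p in names(ref$degenerate_positions)) {
      i <- as.integer(p) + 1L
      if (w[i] %in% ref$degenerate_positions[[p]] && w[i] != "N") dev[i] <- FALSE
    }
  }
  sum(dev)
}

#' Test for the TGACG core in a window
#'
#' The core is required anywhere in the window, on either strand when
#' `core_both_strands`: `TGACG` on the plus strand or its reverse complement
#' `CGTCA` (the natural element carries the core in reverse-complement
#' orientation). When both occur, the strand of the leftmost occurrence is
#' reported.
#'
#' @inheritParams count_deviations
#' @return `list(core_present, core_strand)` with strand `"+"`, `"-"` or
#'   `"none"`.
#' @export
has_tga_core <- function(window_seq, ref = reference_motif(),
                         params = classifier_params()) {
  window_seq <- toupper(window_seq)
  stopifnot(nchar(window_seq) == ref$length)
  fwd <- regexpr(ref$core, window_seq, fixed = TRUE)
  rev <- if (params$core_both_strands) {
    regexpr(revcomp(ref$core), window_seq, fixed = TRUE)
  } else -1L
  if (fwd < 0L && rev < 0L) return(list(core_present = FALSE, core_strand = "none"))
  if (rev < 0L || (fwd > 0L && fwd <= rev)) {
    list(core_present = TRUE, core_strand = "+")
  } else {
    list(core_present = TRUE, core_strand = "-")
  }
}

#' Classify a candidate window as full or partial motif
#'
#' A window is a FULL motif when the TGA core is present and the deviation
#' count does not exceed `max_dev_full` (default 7); otherwise it is a
#' PARTIAL motif (the hexamer anchor matched by construction). Partial
#' motifs lacking the core with more than `min_dev_partial_report`
#' deviations (default 15) carry the descriptive `canonical_partial` flag.
#' ABSENT is reserved for sequences without any hexamer hit and is emitted by
#' [scan_sequence()], not here.
#'
#' @param window_seq Window of length `ref$length`.
#' @param ref A [reference_motif()].
#' @param params A [classifier_params()].
#' @param seq_id,window_start,strand Provenance carried into the call record.
#' @return One-row `data.frame` (a motif call).
#' @export
classify_window <- function(window_seq, ref = reference_motif(),
                            params = classifier_params(),
                            seq_id = NA_character_, window_start = NA_integer_,
                            strand = NA_character_) {
  dev <- count_deviations(window_seq, ref, params)
  core <- has_tga_core(window_seq, ref, params)
  cls <- if (core$core_present && dev <= params$max_dev_full) "FULL" else "PARTIAL"
  data.frame(seq_id = seq_id, window_start = as.integer(window_start),
             strand = strand, window_seq = toupper(window_seq),
             deviations = as.integer(dev),
             core_present = core$core_present, core_strand = core$core_strand,
             motif_class = cls,
             canonical_partial = (cls == "PARTIAL" && !core$core_present &&
                                    dev > params$min_dev_partial_report),
             stringsAsFactors = FALSE)
}

# class rank for best-call selection and species aggregation
.motif_rank <- c(FULL = 3L, PARTIAL = 2L, ABSENT = 1L)

#' Scan a sequence for AAGAAT-type element candidates
#'
#' Exhaustive hexamer-anchored scan: every (degenerate) AAGAAT anchor on
#' either strand seeds a reference-frame window, each window is classified,
#' and one best call is selected (FULL over PARTIAL, then fewer deviations,
#' then leftmost window, then plus strand). A sequence without any anchor
#' yields a single ABSENT call.
#'
#' @param seq Nucleotide string (non-empty).
#' @param ref A [reference_motif()].
#' @param params A [classifier_params()].
#' @param seq_id Identifier carried into the calls.
#' @return An object of class `motif_scan`: list with `calls` (all classified
#'   windows) and `best` (one row).
#' @export
scan_sequence <- function(seq, ref = reference_motif(),
                          params = classifier_params(), seq_id = "seq") {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  hits <- find_hexamer_sites(seq, ref, both_strands = params$core_both_strands)
  calls <- list()
  for (i in seq_len(nrow(hits))) {
    w <- extract_window(seq, hits$position[i], hits$strand[i], ref)
    if (is.null(w)) next
    calls[[length(calls) + 1L]] <-
      classify_window(w$window_seq, ref, params, seq_id = seq_id,
                      window_start = w$window_start, strand = hits$strand[i])
  }
  if (!length(calls)) {
    best <- data.frame(seq_id = seq_id, window_start = NA_integer_,
                       strand = NA_character_, window_seq = NA_character_,
                       deviations = NA_integer_, core_present = NA,
                       core_strand = NA_character_, motif_class = "ABSENT",
                       canonical_partial = FALSE, stringsAsFactors = FALSE)
    calls_df <- best[0, , drop = FALSE]
  } else {
    calls_df <- do.call(rbind, calls)
    calls_df <- unique(calls_df)  # +/- anchors can seed the same frame twice
    o <- order(-.motif_rank[calls_df$motif_class], calls_df$deviations,
               calls_df$window_start, calls_df$strand != "+")
    best <- calls_df[o[1L], , drop = FALSE]
    calls_df <- calls_df[order(calls_df$window_start, calls_df$strand != "+"), ,
                         drop = FALSE]
    rownames(calls_df) <- NULL
    rownames(best) <- NULL
  }
  structure(list(seq_id = seq_id, calls = calls_df, best = best),
            class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat("Motif scan of '", x$seq_id, "': ", nrow(x$calls),
      " candidate window(s)\n", sep = "")
  cat("Best call: ", x$best$motif_class, sep = "")
  if (x$best$motif_class != "ABSENT") {
    cat(sprintf(" at %d (%s), %d deviation(s), core %s",
                x$best$window_start, x$best$strand, x$best$deviations,
                if (x$best$core_present) x$best$core_strand else "absent"))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.motif_scan <- function(x, ...) {
  df <- x$calls
  if (nrow(df)) {
    df$best_flag <- seq_len(nrow(df)) %in%
      which(df$window_start == x$best$window_start &
              df$strand == x$best$strand)
  } else {
    df <- x$best
    df$best_flag <- TRUE
  }
  df
}

#' Scan a multi-FASTA of genomic sequences
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @param ref A [reference_motif()].
#' @param params A [classifier_params()].
#' @param all_hits Keep every classified window (`TRUE`) or only the best
#'   call per sequence (`FALSE`, default).
#' @return `data.frame` of motif calls with a `best_flag` column.
#' @export
scan_fasta <- function(fasta, ref = reference_motif(),
                       params = classifier_params(), all_hits = FALSE) {
  seqs <- .as_named_sequences(fasta, Biostrings::readDNAStringSet)
  rows <- lapply(names(seqs), function(id) {
    df <- as.data.frame(scan_sequence(seqs[[id]], ref, params, seq_id = id))
    if (!all_hits) df <- df[df$best_flag, , drop = FALSE]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# accept path / character vector / XStringSet uniformly
.as_named_sequences <- function(x, reader) {
  if (inherits(x, "XStringSet")) {
    s <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- as.character(reader(x))
  } else if (is.character(x)) {
    s <- x
  } else {
    stop("expected a file path, a named character vector or an XStringSet")
  }
  if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  names(s) <- sub("\\s.*$", "", names(s))
  as.list(s)
}

#' Read motif scanner configuration from YAML
#'
#' The file may hold a `reference` block (`sequence`, `hexamer_offset`,
#' `core`, `degenerate_positions` as index -> string of allowed letters) and
#' a `params` block with [classifier_params()] fields.
#'
#' @param path YAML file.
#' @return `list(ref, params)`.
#' @export
read_motif_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rb <- cfg$reference
  dg <- NULL
  if (!is.null(rb$degenerate_positions)) {
    dg <- lapply(rb$degenerate_positions, function(s)
      strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1L]])
    names(dg) <- names(rb$degenerate_positions)
  }
  ref <- reference_motif(
    sequence = rb$sequence,
    hexamer_offset = if (is.null(rb$hexamer_offset)) 0L else rb$hexamer_offset,
    core = if (is.null(rb$core)) "TGACG" else rb$core,
    degenerate_positions = dg)
  pb <- if (is.null(cfg$params)) list() else cfg$params
  params <- do.call(classifier_params, pb)
  list(ref = ref, params = params)
}
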