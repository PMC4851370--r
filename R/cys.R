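#' Protein multiple alignment container
#'
#' A thin container over an existing multiple alignment (the alignment is
#' consumed as produced upstream and never recomputed here): equal-length
#' gapped sequences plus the identity of the reference sequence whose
#' residue numbering anchors all position mapping.
#'
#' @param seqs Named character vector of aligned sequences (gap `-`), or a
#'   `Biostrings::AAStringSet` / `AAMultipleAlignment`, or a file path (see
#'   [read_alignment()]).
#' @param reference_id Name of the reference sequence.
#' @return Object of class `protein_alignment`.
#' @export
protein_alignment <- function(seqs, reference_id) {
  if (inherits(seqs, "AAMultipleAlignment")) {
    seqs <- as.character(Biostrings::unmasked(seqs))
  } else if (inherits(seqs, "XStringSet")) {
    seqs <- as.character(seqs)
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- toupper(seqs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must all have equal length")
  }
  if (!reference_id %in% names(seqs)) {
    stop(sprintf("reference id '%s' not found in alignment", reference_id))
  }
  structure(list(seqs = seqs, reference_id = reference_id,
                 width = nchar(seqs[[1L]])),
            class = "protein_alignment")
}

#' Read a protein multiple alignment from file
#'
#' @param path Aligned FASTA or Clustal file.
#' @param reference_id Reference sequence id.
#' @param format `"fasta"` or `"clustal"`.
#' @return A [protein_alignment()].
#' @export
read_alignment <- function(path, reference_id, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  protein_alignment(aln, reference_id)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Protein alignment: ", length(x$seqs), " sequences x ", x$width,
      " columns (reference: ", x$reference_id, ")\n", sep = "")
  invisible(x)
}

.ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Map an ungapped reference position to an alignment column
#'
#' Returns the 0-based alignment column whose reference character is the
#' `ref_pos`-th non-gap character of the reference sequence. Strictly
#' increasing in `ref_pos`.
#'
#' @param aln A [protein_alignment()].
#' @param ref_pos 1-based ungapped residue index (or vector) in the
#'   reference sequence.
#' @return 0-based column index (or vector).
#' @export
map_position <- function(aln, ref_pos) {
  ref <- strsplit(aln$seqs[[aln$reference_id]], "", fixed = TRUE)[[1L]]
  nongap <- which(ref != "-")
  ref_pos <- as.integer(ref_pos)
  if (any(ref_pos < 1L) || any(ref_pos > length(nongap))) {
    stop(sprintf("reference position out of range 1..%d", length(nongap)))
  }
  nongap[ref_pos] - 1L
}

#' Call cysteines equivalent to reference cysteine positions
#'
#' For every homolog in the alignment, reports the residue found at the
#' alignment column of each reference cysteine position; an equivalent
#' cysteine is a `C` at exactly that column (gaps and `X` never qualify;
#' comparison is case-insensitive). `window` extends the match to +/- k
#' columns (default 0, the column-exact rule).
#'
#' @param aln A [protein_alignment()].
#' @param positions 1-based ungapped reference residue indices (default the
#'   six reference cysteines 27, 68, 87, 114, 154, 340).
#' @param window Column tolerance for calling an equivalent (default 0).
#' @return Object of class `cys_equivalence`: list with `table` (one row per
#'   homolog x position: `id`, `position`, `column`, `residue`,
#'   `is_cysteine`) and `counts` (named equivalent-cysteine count per id).
#' @export
call_equivalents <- function(aln, positions = c(27L, 68L, 87L, 114L, 154L, 340L),
                             window = 0L) {
  cols <- map_position(aln, positions)  # 0-based
  rows <- list()
  for (id in names(aln$seqs)) {
    ch <- strsplit(aln$seqs[[id]], "", fixed = TRUE)[[1L]]
    for (k in seq_along(positions)) {
      span <- max(1L, cols[k] + 1L - window):min(length(ch), cols[k] + 1L + window)
      res <- ch[cols[k] + 1L]
      is_c <- any(ch[span] == "C")
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, position = positions[k], column = cols[k],
        residue = res, is_cysteine = is_c, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  counts <- vapply(names(aln$seqs), function(id)
    sum(tab$is_cysteine[tab$id == id]), integer(1))
  structure(list(table = tab, counts = counts, positions = positions,
                 reference_id = aln$reference_id),
            class = "cys_equivalence")
}

#' @export
print.cys_equivalence <- function(x, ...) {
  cat("Equivalent-cysteine calls at reference positions ",
      paste(x$positions, collapse = ", "), "\n", sep = "")
  for (id in names(x$counts)) {
    pres <- x$table[x$table$id == id, ]
    cat(sprintf("  %-20s %d/%d  [%s]\n", id, x$counts[[id]],
                length(x$positions),
                paste(ifelse(pres$is_cysteine, "C", "X"), collapse = "")))
  }
  invisible(x)
}

#' @export
as.data.frame.cys_equivalence <- function(x, ...) x$table

#' Detect the basic-region (bZIP) start of a protein
#'
#' The bZIP domain of TGA factors lies close to the N-terminus and is rich
#' in basic residues. The first window of width `w` whose lysine/arginine
#' fraction reaches `min_basic_frac` marks the basic region; the position of
#' the first K/R at or after that window's start is returned as the domain
#' start. A supplied override always wins.
#'
#' @param protein_seq Plain (ungapped) protein sequence.
#' @param w Window width in residues (default 16).
#' @param min_basic_frac Minimum K+R fraction in the window (default 0.4).
#' @param override Optional 1-based start; returned as-is when not `NULL`.
#' @return 1-based residue index, or `NA_integer_` when no window qualifies.
#' @export
detect_bzip_start <- function(protein_seq, w = 16L, min_basic_frac = 0.4,
                              override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  ch <- strsplit(toupper(.ungap(protein_seq)), "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < w) return(NA_integer_)
  basic <- as.integer(ch %in% c("K", "R"))
  cs <- cumsum(basic)
  frac <- (cs[w:n] - c(0L, cs)[seq_len(n - w + 1L)]) / w
  start <- which(frac >= min_basic_frac)
  if (!length(start)) return(NA_integer_)
  s <- start[1L]
  first_basic <- s - 1L + which(basic[s:n] == 1L)[1L]
  as.integer(first_basic)
}

#' Annotate the N-terminal extension of a homolog
#'
#' Computes the length of the region N-terminal of the bZIP/basic-region
#' start on the ungapped homolog, its percent identity to the reference
#' N-terminus over alignment columns where neither sequence is gapped, and a
#' homology class: `ABSENT` when the extension is shorter than
#' `min_extension`, `SIGNIFICANT` when identity reaches `min_identity`,
#' otherwise `LOW`. Homologs flagged `truncated` (e.g. no defined start
#' codon) get `extension_length = NA` and class `NA`.
#'
#' @param aln A [protein_alignment()].
#' @param id Homolog id in the alignment.
#' @param bzip_start_map Optional named list/vector of 1-based bZIP starts
#'   per id (overrides detection).
#' @param min_identity Identity threshold for `SIGNIFICANT` (default 30
#'   percent).
#' @param min_extension Minimum extension length in residues (default 20).
#' @param truncated Character vector of ids known to be N-terminally
#'   truncated.
#' @param ... Passed to [detect_bzip_start()].
#' @return One-row `data.frame(id, bzip_start, extension_length,
#'   pct_identity, homology_class, flags)`.
#' @export
annotate_n_terminus <- function(aln, id, bzip_start_map = NULL,
                                min_identity = 30, min_extension = 20L,
                                truncated = character(0), ...) {
  if (!id %in% names(aln$seqs)) {
    stop(sprintf("id '%s' not found in alignment", id))
  }
  if (id %in% truncated) {
    return(data.frame(id = id, bzip_start = NA_integer_,
                      extension_length = NA_integer_, pct_identity = NA_real_,
                      homology_class = NA_character_,
                      flags = "start-codon-undefined", stringsAsFactors = FALSE))
  }
  get_start <- function(sid) {
    ov <- if (!is.null(bzip_start_map)) bzip_start_map[[sid]] else NULL
    detect_bzip_start(aln$seqs[[sid]], override = ov, ...)
  }
  bz <- get_start(id)
  bz_ref <- get_start(aln$reference_id)
  if (is.na(bz) || is.na(bz_ref)) {
    stop("could not locate a basic region; supply bzip_start_map")
  }
  ext_len <- bz - 1L
  # columns strictly N-terminal of the reference's bZIP start
  ref_bz_col <- map_position(aln, bz_ref)  # 0-based
  h <- strsplit(aln$seqs[[id]], "", fixed = TRUE)[[1L]]
  r <- strsplit(aln$seqs[[aln$reference_id]], "", fixed = TRUE)[[1L]]
  idx <- seq_len(ref_bz_col)  # 1-based columns 1..ref_bz_col (strictly before)
  both <- idx[h[idx] != "-" & r[idx] != "-"]
  pct <- if (length(both)) 100 * mean(h[both] == r[both]) else 0
  cls <- if (ext_len < min_extension) "ABSENT"
         else if (pct >= min_identity) "SIGNIFICANT" else "LOW"
  data.frame(id = id, bzip_start = bz, extension_length = ext_len,
             pct_identity = pct, homology_class = cls, flags = "",
             stringsAsFactors = FALSE)
}

#' Annotate N-termini of all homologs in an alignment
#'
#' @inheritParams annotate_n_terminus
#' @return `data.frame`, one row per homolog.
#' @export
annotate_n_termini <- function(aln, bzip_start_map = NULL, min_identity = 30,
                               min_extension = 20L, truncated = character(0),
                               ...) {
  out <- do.call(rbind, lapply(names(aln$seqs), function(id)
    annotate_n_terminus(aln, id, bzip_start_map, min_identity, min_extension,
                        truncated, ...)))
  rownames(out) <- NULL
  out
}
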