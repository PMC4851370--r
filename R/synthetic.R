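# Seeded synthetic inputs with exact ground truth for every pipeline stage:
# intron-like sequences with planted motif candidates, designed protein
# families with known equivalent-cysteine patterns, and observed-mass lists
# with planted modification deltas.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
.NT4 <- c("A", "C", "G", "T")

.sample_background <- function(n, gc) {
  sample(.NT4, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# window indices (1-based) that planted deviations must avoid: the hexamer
# anchor and the core occurrence (forward or reverse orientation)
.protected_positions <- function(ref) {
  hex <- ref$hexamer_offset + seq_len(6L)
  core_at <- regexpr(ref$core, ref$sequence, fixed = TRUE)
  if (core_at < 0L) core_at <- regexpr(revcomp(ref$core), ref$sequence, fixed = TRUE)
  if (core_at < 0L) stop("reference window carries no core in either orientation")
  list(hexamer = hex,
       core = as.integer(core_at):(as.integer(core_at) + nchar(ref$core) - 1L))
}

# realize one planted window with exactly `deviations` substitutions; when
# the core is to be broken, two of them are a two-nucleotide core exchange
.plant_window <- function(ref, deviations, core_intact,
                          params = classifier_params()) {
  prot <- .protected_positions(ref)
  eligible <- setdiff(seq_len(ref$length), c(prot$hexamer, prot$core))
  need_bg <- deviations - if (core_intact) 0L else 2L
  if (need_bg < 0L) stop("deviation_count < 2 is impossible with a broken core")
  if (need_bg > length(eligible)) {
    stop(sprintf("deviation_count %d exceeds the %d editable positions",
                 deviations, length(eligible) + if (core_intact) 0L else 2L))
  }
  repeat {
    w <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
    if (!core_intact) {
      at <- sample(prot$core, 2L)
      for (i in at) w[i] <- sample(setdiff(.NT4, w[i]), 1L)
    }
    if (need_bg > 0L) {
      at <- if (length(eligible) == 1L) eligible else sample(eligible, need_bg)
      for (i in at) w[i] <- sample(setdiff(.NT4, w[i]), 1L)
    }
    win <- paste(w, collapse = "")
    ok_dev <- count_deviations(win, ref, params) == deviations
    ok_core <- has_tga_core(win, ref, params)$core_present == core_intact
    # a substitution may incidentally recreate or spawn a core; resample
    if (ok_dev && ok_core) return(win)
  }
}

#' Generate an intron-like sequence with planted motif candidates
#'
#' An i.i.d. nucleotide background at the requested GC content, with copies
#' of the reference element planted at given positions carrying exactly the
#' requested number of nucleotide deviations. Deviations avoid the hexamer
#' anchor and the core; when `core_intact` is `FALSE` the core itself is
#' destroyed by a two-nucleotide exchange (counted among the deviations),
#' mirroring the binding-abolishing core mutant.
#'
#' @param ref A [reference_motif()].
#' @param length Sequence length in nt (default 1500).
#' @param gc Background GC fraction (default 0.35, intron-like).
#' @param planted `data.frame` with columns `position` (0-based window
#'   start), `deviations`, `core_intact`; may have zero rows.
#' @param seq_id Name of the FASTA record.
#' @param seed Integer seed; the output is byte-identical per seed.
#' @return List: `sequence` (named character), `truth` (`data.frame` with
#'   `position`, `deviations`, `core_intact`, `expected_class`).
#' @export
gen_intron <- function(ref = reference_motif(), length = 1500L, gc = 0.35,
                       planted = data.frame(position = integer(0),
                                            deviations = integer(0),
                                            core_intact = logical(0)),
                       seq_id = "synthetic_intron", seed = 1L) {
  set.seed(seed)
  L <- ref$length
  if (nrow(planted)) {
    if (any(planted$position < 0L | planted$position + L > length)) {
      stop("planted window overruns the sequence")
    }
    o <- order(planted$position)
    p <- planted[o, , drop = FALSE]
    if (nrow(p) > 1L && any(diff(p$position) < L)) {
      stop("planted windows overlap")
    }
  }
  bg <- .sample_background(length, gc)
  for (i in seq_len(nrow(planted))) {
    win <- .plant_window(ref, planted$deviations[i], planted$core_intact[i])
    bg[planted$position[i] + seq_len(L)] <- strsplit(win, "", fixed = TRUE)[[1L]]
  }
  truth <- planted
  if (nrow(truth)) {
    truth$expected_class <- ifelse(
      truth$core_intact & truth$deviations <= classifier_params()$max_dev_full,
      "FULL", "PARTIAL")
  } else {
    truth$expected_class <- character(0)
  }
  seqs <- stats::setNames(paste(bg, collapse = ""), seq_id)
  list(sequence = seqs, truth = truth)
}

#' Generate a designed protein family alignment
#'
#' Builds a reference protein carrying cysteines at the queried positions
#' (five in an N-terminal extension, one C-terminal), a basic-region block
#' marking the bZIP start, and homologs realized from a per-homolog design:
#' extension length, cysteine pattern over the reference positions (`C`
#' present, `X` substituted by serine), and a target N-terminal identity.
#' The alignment is constructed by design: gaps occur only where a homolog's
#' extension is shorter than the reference extension (left-padded), so the
#' expected equivalent-cysteine count and homology class in the truth table
#' are exact.
#'
#' @param design `data.frame` with columns `id`, `extension_length`,
#'   `cys_pattern` (string over `positions`, e.g. `"XCCCCC"`),
#'   `nterm_identity` (target fraction in the overlapping columns).
#' @param positions Reference cysteine positions (default
#'   `c(27, 68, 87, 114, 154, 340)`).
#' @param ref_extension Length of the reference N-terminal extension
#'   (default 166).
#' @param ref_length Total reference length (default 400).
#' @param seed Integer seed.
#' @return List: `alignment` (a [protein_alignment()], reference id
#'   `"REF"`), `truth` (`data.frame` with `id`, `extension_length`,
#'   `expected_equivalent_count`, `expected_class`, `target_identity`).
#' @export
gen_protein_family <- function(design,
                               positions = c(27L, 68L, 87L, 114L, 154L, 340L),
                               ref_extension = 166L, ref_length = 400L,
                               seed = 1L) {
  set.seed(seed)
  stopifnot(all(c("id", "extension_length", "cys_pattern") %in% names(design)))
  if (is.null(design$nterm_identity)) design$nterm_identity <- 0.8
  if (any(nchar(design$cys_pattern) != length(positions))) {
    stop("cys_pattern length must equal the number of reference positions")
  }
  if (any(design$extension_length > ref_extension)) {
    stop("homolog extensions longer than the reference extension are not modelled")
  }
  # reference: extension without K/R (so basic-region detection is unambiguous)
  # and without C except the designed positions; basic block; C-free tail
  quiet <- setdiff(.AA20, c("C", "K", "R"))
  ref <- sample(quiet, ref_length, replace = TRUE)
  bzip_block <- strsplit("KRKRLKRKNSKRRSRA", "")[[1L]]
  ref[ref_extension + seq_along(bzip_block)] <- bzip_block
  ref[positions] <- "C"
  npos <- positions[positions <= ref_extension]
  if (any(positions > ref_extension + length(bzip_block)) == FALSE) {
    stop("at least one position must lie C-terminal of the basic block")
  }
  rows <- list()
  seqs <- c(REF = paste(ref, collapse = ""))
  pat_split <- strsplit(toupper(design$cys_pattern), "", fixed = TRUE)
  for (i in seq_len(nrow(design))) {
    e <- as.integer(design$extension_length[i])
    pat <- pat_split[[i]]
    h <- ref
    gap_n <- ref_extension - e
    covered <- positions > gap_n | positions > ref_extension
    if (any(pat == "C" & !covered)) {
      stop(sprintf("homolog '%s': cys_pattern requires a cysteine inside its gap",
                   design$id[i]))
    }
    # realize the target identity over the e overlapping extension columns
    overlap <- setdiff((gap_n + 1L):ref_extension, integer(0))
    if (e == 0L) overlap <- integer(0)
    forced <- intersect(overlap, positions)
    free <- setdiff(overlap, forced)
    n_match_target <- round(design$nterm_identity[i] * length(overlap))
    forced_match <- sum(pat[match(forced, positions)] == "C")
    n_free_match <- min(max(n_match_target - forced_match, 0L), length(free))
    mism <- free[sample.int(length(free), length(free) - n_free_match)]
    for (j in mism) h[j] <- sample(setdiff(quiet, ref[j]), 1L)
    for (k in seq_along(positions)) {
      p <- positions[k]
      if (covered[k]) h[p] <- if (pat[k] == "C") "C" else "S"
    }
    if (gap_n > 0L) h[seq_len(gap_n)] <- "-"
    seqs[[design$id[i]]] <- paste(h, collapse = "")
    achieved <- if (length(overlap)) {
      100 * mean(h[overlap] == ref[overlap])
    } else 0
    cls <- if (e < 20L) "ABSENT" else if (achieved >= 30) "SIGNIFICANT" else "LOW"
    rows[[i]] <- data.frame(
      id = design$id[i], extension_length = e,
      expected_equivalent_count = sum(pat == "C" & covered),
      expected_class = cls, target_identity = design$nterm_identity[i],
      achieved_identity = achieved, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(alignment = protein_alignment(seqs, "REF"), truth = truth)
}

#' Generate an observed-mass list with planted modifications
#'
#' Digests the protein, applies the planted modification hypotheses to the
#' chosen peptides, adds Gaussian measurement noise, and returns the
#' observed neutral-mass list together with the generating truth.
#'
#' @param protein Amino-acid string.
#' @param planted `data.frame` with columns `peptide_index` (row in the
#'   [digest()] table), `kind`; optional `partner_index` for
#'   `INTER_DISULFIDE` and `multiplicity` for `GLUTATHIONYLATION`.
#' @param noise_sd Measurement noise standard deviation in Da (default
#'   0.01).
#' @param seed Integer seed.
#' @param cleave_before,max_missed Digestion settings (see [digest()]).
#' @param scale Mass scale.
#' @return List: `observed` (`data.frame(id, mass)`), `truth` (planted table
#'   with `peptide`, `predicted_mass`), `peptides` (the digest table).
#' @export
gen_mass_list <- function(protein, planted, noise_sd = 0.01, seed = 1L,
                          cleave_before = "D", max_missed = 0L,
                          scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  set.seed(seed)
  peps <- digest(protein, cleave_before, max_missed)
  if (is.null(planted$multiplicity)) planted$multiplicity <- 1L
  if (is.null(planted$partner_index)) planted$partner_index <- NA_integer_
  if (any(planted$peptide_index < 1L | planted$peptide_index > nrow(peps))) {
    stop("peptide_index out of range of the digest table")
  }
  pred <- numeric(nrow(planted))
  pepseq <- character(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    kind <- toupper(planted$kind[i])
    p1 <- peps$sequence[planted$peptide_index[i]]
    if (kind == "INTER_DISULFIDE") {
      if (is.na(planted$partner_index[i])) stop("INTER_DISULFIDE needs partner_index")
      p2 <- peps$sequence[planted$partner_index[i]]
      pred[i] <- apply_hypothesis(c(p1, p2), kind, scale = scale)
      pepseq[i] <- paste(p1, p2, sep = "+")
    } else {
      pred[i] <- apply_hypothesis(p1, kind, planted$multiplicity[i], scale)
      pepseq[i] <- p1
    }
  }
  observed <- data.frame(id = sprintf("obs%03d", seq_len(nrow(planted))),
                         mass = pred + stats::rnorm(nrow(planted), 0, noise_sd),
                         stringsAsFactors = FALSE)
  truth <- cbind(planted,
                 data.frame(peptide = pepseq, predicted_mass = pred,
                            stringsAsFactors = FALSE))
  list(observed = observed, truth = truth, peptides = peps)
}
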