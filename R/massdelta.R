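# Residue masses (Da) for the 20 standard amino acids.
# Monoisotopic values from the standard elemental compositions; average
# values from IUPAC 2021 atomic weights.
.residue_mono <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918478, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496301, E = 129.04259309, M = 131.04048491, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295)

.residue_avg <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

.water_mono <- 18.01056468
.water_avg  <- 18.01528
.proton     <- 1.00727646688
.h_atom     <- 1.00782503

# modification deltas (Da): glutathione adduct = glutathione (C10H17N3O6S,
# 307.08381 mono) minus the two hydrogens lost on mixed-disulfide formation;
# any disulfide bond loses two hydrogen atoms
.mods <- list(
  NONE             = c(mono = 0,          avg = 0),
  GLUTATHIONYLATION = c(mono = 305.06816, avg = 305.307),
  INTRA_DISULFIDE  = c(mono = -2.015650,  avg = -2.0159),
  INTER_DISULFIDE  = c(mono = -2.015650,  avg = -2.0159),
  CARBAMIDOMETHYL  = c(mono = 57.02146,   avg = 57.0513))

.mod_kinds <- names(.mods)

#' In-silico protease digestion
#'
#' Cleaves a protein with an AspN-style rule: the peptide bond immediately
#' N-terminal to every aspartate is cut (optionally also before glutamate).
#' Peptides with 0..`max_missed` missed cleavages are returned; the
#' 0-missed-cleavage peptides concatenate back to the input.
#'
#' @param protein Amino-acid string (standard 20-letter alphabet; `X`
#'   allowed, but its mass is undefined).
#' @param cleave_before Residues cleaved before (default `"D"`; use
#'   `c("D","E")` for the broader AspN specificity).
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @return `data.frame` with columns `sequence`, `start`, `end` (1-based
#'   inclusive parent coordinates), `missed_cleavages`, `n_cys`, and a list
#'   column `cys_positions` (parent coordinates of cysteines).
#' @examples
#' digest("MADAD")            # MA | DA | D
#' digest("MADAD", max_missed = 1)
#' @export
digest <- function(protein, cleave_before = "D", max_missed = 0L) {
  protein <- toupper(as.character(protein))
  if (!nzchar(protein)) stop("empty protein")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", protein)) {
    stop("protein contains characters outside the standard alphabet")
  }
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cut <- which(ch %in% cleave_before)
  cut <- cut[cut > 1L]          # no cut before the first residue
  bounds <- c(1L, cut, n + 1L)  # fragment i spans bounds[i] .. bounds[i+1]-1
  nf <- length(bounds) - 1L
  rows <- list()
  for (m in 0:min(max_missed, nf - 1L)) {
    for (i in seq_len(nf - m)) {
      s <- bounds[i]; e <- bounds[i + m + 1L] - 1L
      pep <- substr(protein, s, e)
      cys <- s - 1L + which(ch[s:e] == "C")
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, start = s, end = e, missed_cleavages = m,
        n_cys = length(cys), stringsAsFactors = FALSE)
      rows[[length(rows)]]$cys_positions <- list(cys)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peptide mass
#'
#' Sum of residue masses plus the mass of water, on the monoisotopic or
#' average scale.
#'
#' @param sequence Amino-acid string(s); vectorized.
#' @param scale `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Da (numeric vector).
#' @examples
#' peptide_mass("G")   # 75.03203
#' peptide_mass("GG")  # 132.05349
#' @export
peptide_mass <- function(sequence, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  tab <- if (scale == "monoisotopic") .residue_mono else .residue_avg
  water <- if (scale == "monoisotopic") .water_mono else .water_avg
  vapply(toupper(as.character(sequence)), function(s) {
    if (!nzchar(s)) stop("empty peptide sequence")
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    unknown <- setdiff(unique(ch), names(tab))
    if (length(unknown)) {
      stop(sprintf("residue(s) without defined mass: %s",
                   paste(unknown, collapse = ", ")))
    }
    sum(tab[ch]) + water
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mass delta of a cysteine-modification kind
#'
#' @param kind One of `"NONE"`, `"GLUTATHIONYLATION"`, `"INTRA_DISULFIDE"`,
#'   `"INTER_DISULFIDE"`, `"CARBAMIDOMETHYL"`.
#' @param scale `"monoisotopic"` or `"average"`.
#' @return Delta in Da.
#' @export
modification_delta <- function(kind, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  kind <- match.arg(toupper(kind), .mod_kinds)
  unname(.mods[[kind]][if (scale == "monoisotopic") "mono" else "avg"])
}

# cysteines consumed by one application of a modification kind
.cys_required <- c(NONE = 0L, GLUTATHIONYLATION = 1L, INTRA_DISULFIDE = 2L,
                   INTER_DISULFIDE = 1L, CARBAMIDOMETHYL = 1L)

#' Predicted mass under a modification hypothesis
#'
#' Applies one or more modification kinds to a peptide (or, for an
#' intermolecular disulfide, a cross-linked peptide pair) and returns the
#' predicted neutral mass. Each applied kind consumes cysteines from the
#' peptide's budget; stacking beyond the available cysteines is an error.
#'
#' @param peptide Peptide sequence, or a character vector of two sequences
#'   for `INTER_DISULFIDE` (their masses are summed and two hydrogens lost).
#' @param kinds Character vector of modification kinds applied jointly, e.g.
#'   `"GLUTATHIONYLATION"` or `c("GLUTATHIONYLATION", "INTRA_DISULFIDE")`.
#' @param multiplicity Number of glutathione adducts per
#'   `GLUTATHIONYLATION` entry (default 1).
#' @param scale `"monoisotopic"` or `"average"`.
#' @return Predicted neutral mass in Da.
#' @export
apply_hypothesis <- function(peptide, kinds = "NONE", multiplicity = 1L,
                             scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  kinds <- vapply(toupper(kinds), function(k) match.arg(k, .mod_kinds),
                  character(1), USE.NAMES = FALSE)
  inter <- "INTER_DISULFIDE" %in% kinds
  if (inter && length(peptide) != 2L) {
    stop("INTER_DISULFIDE requires exactly two peptide sequences")
  }
  if (!inter && length(peptide) != 1L) stop("expected a single peptide sequence")
  ncys <- sum(vapply(toupper(peptide), function(s)
    lengths(regmatches(s, gregexpr("C", s, fixed = TRUE))), integer(1)))
  need <- sum(ifelse(kinds == "GLUTATHIONYLATION",
                     .cys_required[kinds] * multiplicity,
                     ifelse(kinds == "INTER_DISULFIDE", 2L, .cys_required[kinds])))
  if (need > ncys) {
    stop(sprintf("hypothesis requires %d cysteine(s) but peptide has %d",
                 need, ncys))
  }
  base <- sum(peptide_mass(peptide, scale))
  delta <- sum(vapply(kinds, function(k) {
    d <- modification_delta(k, scale)
    if (k == "GLUTATHIONYLATION") d * multiplicity else d
  }, numeric(1)))
  base + delta
}

#' Enumerate (peptide, hypothesis) candidates for mass matching
#'
#' Builds the search space for delta-mass assignment: every peptide with the
#' unmodified hypothesis, cysteine-containing peptides with each applicable
#' cysteine hypothesis, and (when enabled) all cross-pairs of
#' cysteine-containing peptides for intermolecular disulfides.
#'
#' @param peptides `data.frame` from [digest()].
#' @param hypotheses Kinds to enumerate (default `NONE`,
#'   `GLUTATHIONYLATION`, `INTRA_DISULFIDE`).
#' @param max_multiplicity Cap on glutathione adducts per peptide (default
#'   1; bounded by each peptide's cysteine count).
#' @param max_pairs Cap on intermolecular pairings (default `Inf`).
#' @param scale Mass scale.
#' @param carbamidomethyl Apply the iodoacetamide-derived +57.02146 Da fixed
#'   modification to every remaining free cysteine (default `FALSE`).
#' @return `data.frame(peptide, partner, kind, multiplicity, start, end,
#'   predicted_mass)` sorted by predicted mass.
#' @export
enumerate_candidates <- function(peptides,
                                 hypotheses = c("NONE", "GLUTATHIONYLATION",
                                                "INTRA_DISULFIDE"),
                                 max_multiplicity = 1L, max_pairs = Inf,
                                 scale = c("monoisotopic", "average"),
                                 carbamidomethyl = FALSE) {
  scale <- match.arg(scale)
  hypotheses <- toupper(hypotheses)
  rows <- list()
  add <- function(pep, partner, kind, mult, start, end, mass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide = pep, partner = partner, kind = kind,
      multiplicity = as.integer(mult), start = as.integer(start),
      end = as.integer(end), predicted_mass = mass, stringsAsFactors = FALSE)
  }
  cam_delta <- function(free_cys) {
    if (carbamidomethyl) free_cys * modification_delta("CARBAMIDOMETHYL", scale) else 0
  }
  for (i in seq_len(nrow(peptides))) {
    p <- peptides[i, ]
    if ("NONE" %in% hypotheses) {
      add(p$sequence, NA_character_, "NONE", 0L, p$start, p$end,
          peptide_mass(p$sequence, scale) + cam_delta(p$n_cys))
    }
    if ("GLUTATHIONYLATION" %in% hypotheses && p$n_cys >= 1L) {
      for (m in seq_len(min(max_multiplicity, p$n_cys))) {
        add(p$sequence, NA_character_, "GLUTATHIONYLATION", m, p$start, p$end,
            apply_hypothesis(p$sequence, "GLUTATHIONYLATION", m, scale) +
              cam_delta(p$n_cys - m))
      }
    }
    if ("INTRA_DISULFIDE" %in% hypotheses && p$n_cys >= 2L) {
      add(p$sequence, NA_character_, "INTRA_DISULFIDE", 1L, p$start, p$end,
          apply_hypothesis(p$sequence, "INTRA_DISULFIDE", scale = scale) +
            cam_delta(p$n_cys - 2L))
    }
  }
  if ("INTER_DISULFIDE" %in% hypotheses) {
    cys_idx <- which(peptides$n_cys >= 1L)
    n_pair <- 0L
    if (length(cys_idx) >= 2L) {
      for (a in seq_len(length(cys_idx) - 1L)) {
        for (b in (a + 1L):length(cys_idx)) {
          if (n_pair >= max_pairs) break
          pa <- peptides[cys_idx[a], ]; pb <- peptides[cys_idx[b], ]
          add(pa$sequence, pb$sequence, "INTER_DISULFIDE", 1L, pa$start, pa$end,
              apply_hypothesis(c(pa$sequence, pb$sequence), "INTER_DISULFIDE",
                               scale = scale) +
                cam_delta(pa$n_cys + pb$n_cys - 2L))
          n_pair <- n_pair + 1L
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$predicted_mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign observed neutral masses to modification candidates
#'
#' Each observed mass is assigned to the candidate with the smallest
#' absolute mass error among those within tolerance; masses with two or more
#' candidates within tolerance are flagged ambiguous, and masses with none
#' are reported unmatched.
#'
#' @param observed Numeric vector of neutral masses (Da), or a `data.frame`
#'   with columns `mass` (or `mz` plus `charge`) and optionally `id`.
#' @param candidates `data.frame` from [enumerate_candidates()].
#' @param tol Tolerance (> 0), in Da or ppm.
#' @param tol_unit `"Da"` (default) or `"ppm"`.
#' @return Object of class `mass_match`: `data.frame` with the observed
#'   mass, best candidate, `predicted`, `delta` (observed - predicted),
#'   `within_tolerance`, `ambiguous` and `n_candidates`.
#' @export
match_masses <- function(observed, candidates, tol = 0.5,
                         tol_unit = c("Da", "ppm")) {
  tol_unit <- match.arg(tol_unit)
  stopifnot(tol > 0)
  if (is.data.frame(observed)) {
    ids <- if ("id" %in% names(observed)) as.character(observed$id)
           else as.character(seq_len(nrow(observed)))
    masses <- if ("mass" %in% names(observed)) observed$mass
              else neutral_from_mz(observed$mz, observed$charge)
  } else {
    masses <- as.numeric(observed)
    ids <- as.character(seq_along(masses))
  }
  rows <- lapply(seq_along(masses), function(i) {
    m <- masses[i]
    tol_da <- if (tol_unit == "Da") tol else m * tol * 1e-6
    d <- m - candidates$predicted_mass
    inside <- which(abs(d) <= tol_da)
    if (!length(inside)) {
      return(data.frame(id = ids[i], observed_mass = m, peptide = NA_character_,
                        partner = NA_character_, kind = NA_character_,
                        multiplicity = NA_integer_, start = NA_integer_,
                        end = NA_integer_, predicted = NA_real_,
                        delta = NA_real_, within_tolerance = FALSE,
                        ambiguous = FALSE, n_candidates = 0L,
                        stringsAsFactors = FALSE))
    }
    j <- inside[which.min(abs(d[inside]))]
    data.frame(id = ids[i], observed_mass = m, peptide = candidates$peptide[j],
               partner = candidates$partner[j], kind = candidates$kind[j],
               multiplicity = candidates$multiplicity[j],
               start = candidates$start[j], end = candidates$end[j],
               predicted = candidates$predicted_mass[j], delta = d[j],
               within_tolerance = TRUE, ambiguous = length(inside) >= 2L,
               n_candidates = length(inside), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mass_match", class(out))
  out
}

#' @export
print.mass_match <- function(x, ...) {
  cat("Mass matching: ", nrow(x), " observed mass(es), ",
      sum(x$within_tolerance), " matched (",
      sum(x$ambiguous), " ambiguous)\n", sep = "")
  print.data.frame(x, digits = 7)
  invisible(x)
}

#' Neutral mass from m/z and charge
#'
#' `M = z * mz - z * m_proton`, with the proton mass 1.0072765 Da.
#'
#' @param mz Mass-to-charge ratio(s) (Th), > 0.
#' @param z Charge state(s), integer >= 1.
#' @return Neutral mass in Da.
#' @export
neutral_from_mz <- function(mz, z = 1L) {
  if (any(z < 1L)) stop("charge must be >= 1")
  if (any(mz <= 0)) stop("m/z must be positive")
  z * mz - z * .proton
}

#' m/z from neutral mass and charge
#' @param mass Neutral mass(es) in Da.
#' @param z Charge state(s), integer >= 1.
#' @return m/z in Th.
#' @export
mz_from_neutral <- function(mass, z = 1L) {
  if (any(z < 1L)) stop("charge must be >= 1")
  (mass + z * .proton) / z
}

#' Per-cysteine summary of supported modifications
#'
#' Collapses a [match_masses()] result to the parent-protein cysteine level:
#' for every cysteine covered by a matched, modified peptide, the
#' modification kinds its matches support.
#'
#' @param matches A `mass_match` data.frame.
#' @param peptides The [digest()] table the candidates were built from.
#' @return `data.frame(cys_position, kinds, n_matches)`.
#' @export
summarize_cys_modifications <- function(matches, peptides) {
  hits <- matches[matches$within_tolerance & !is.na(matches$kind) &
                    matches$kind != "NONE", , drop = FALSE]
  acc <- list()
  for (i in seq_len(nrow(hits))) {
    for (pep in stats::na.omit(c(hits$peptide[i], hits$partner[i]))) {
      j <- match(pep, peptides$sequence)
      if (is.na(j)) next
      for (cp in peptides$cys_positions[[j]]) {
        key <- as.character(cp)
        acc[[key]] <- c(acc[[key]], hits$kind[i])
      }
    }
  }
  if (!length(acc)) {
    return(data.frame(cys_position = integer(0), kinds = character(0),
                      n_matches = integer(0), stringsAsFactors = FALSE))
  }
  pos <- sort(as.integer(names(acc)))
  data.frame(
    cys_position = pos,
    kinds = vapply(as.character(pos), function(k)
      paste(sort(unique(acc[[k]])), collapse = ";"), character(1),
      USE.NAMES = FALSE),
    n_matches = vapply(as.character(pos), function(k) length(acc[[k]]),
                       integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Cysteine inventory of a protein
#'
#' Counts and locates cysteines and reports the average-scale mass of the
#' protein and of its all-cysteine-to-serine substitution variant (the
#' redox-inert control used to attribute oligomerization and modification to
#' cysteines).
#'
#' @param protein Amino-acid string.
#' @param nterm_end Last residue of the N-terminal region of interest
#'   (default 166, the N-terminal extension boundary used for the deletion
#'   variant).
#' @return List: `total_cys`, `nterm_cys`, `cys_positions`,
#'   `last_cys_position`, `protein_mass_avg`, `cys_to_ser_mass_avg` (Da).
#' @export
cys_inventory <- function(protein, nterm_end = 166L) {
  protein <- toupper(as.character(protein))
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  cys <- which(ch == "C")
  list(
    total_cys = length(cys),
    nterm_cys = sum(cys <= nterm_end),
    cys_positions = cys,
    last_cys_position = if (length(cys)) max(cys) else NA_integer_,
    protein_mass_avg = peptide_mass(protein, "average"),
    cys_to_ser_mass_avg = peptide_mass(chartr("C", "S", protein), "average"))
}
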