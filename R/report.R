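# Join motif calls, equivalent-cysteine counts and N-terminus annotations
# into per-species presence/absence profiles and render them on a supplied
# species tree (no tree inference here; the cladogram is an input).

.nterm_rank <- c(SIGNIFICANT = 3L, LOW = 2L, ABSENT = 1L)

.best_level <- function(x, rank) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  names(which.max(rank[x]))
}

#' Build per-species profiles from the pipeline outputs
#'
#' One row per species; species with several homologs keep every homolog as
#' a sub-row and the species row carries the maximum equivalent-cysteine
#' count and the best motif / N-terminus class across homologs. Sequence
#' ids without a species mapping produce a warning and an `NA`-species row;
#' species present in the mapping but absent from every input get an all-NA
#' row.
#'
#' @param motif Best-call motif table (e.g. [scan_fasta()] output filtered
#'   to `best_flag`), with columns `seq_id`, `motif_class`; or `NULL`.
#' @param cys A [call_equivalents()] result, or a `data.frame` with `id`,
#'   `equivalent_count`; or `NULL`.
#' @param nterm [annotate_n_termini()] output (`id`, `homology_class`,
#'   `flags`); or `NULL`.
#' @param species_map `data.frame(id, species)` joining sequence ids to
#'   species names.
#' @return Object of class `species_profiles`: list with `species`
#'   (aggregated `data.frame`) and `homologs` (per-homolog sub-rows).
#' @export
build_profiles <- function(motif = NULL, cys = NULL, nterm = NULL, species_map) {
  stopifnot(all(c("id", "species") %in% names(species_map)))
  if (inherits(cys, "cys_equivalence")) {
    cys <- data.frame(id = names(cys$counts),
                      equivalent_count = as.integer(cys$counts),
                      stringsAsFactors = FALSE)
  }
  ids <- unique(c(if (!is.null(motif)) motif$seq_id,
                  if (!is.null(cys)) cys$id,
                  if (!is.null(nterm)) nterm$id))
  unmapped <- setdiff(ids, species_map$id)
  if (length(unmapped)) {
    warning("no species mapping for id(s): ", paste(unmapped, collapse = ", "))
  }
  hom <- data.frame(id = ids,
                    species = species_map$species[match(ids, species_map$id)],
                    stringsAsFactors = FALSE)
  hom$motif_class <- if (!is.null(motif)) {
    motif$motif_class[match(hom$id, motif$seq_id)]
  } else NA_character_
  hom$equivalent_cys_count <- if (!is.null(cys)) {
    cys$equivalent_count[match(hom$id, cys$id)]
  } else NA_integer_
  hom$nterm_class <- if (!is.null(nterm)) {
    nterm$homology_class[match(hom$id, nterm$id)]
  } else NA_character_
  hom$flags <- if (!is.null(nterm) && "flags" %in% names(nterm)) {
    f <- nterm$flags[match(hom$id, nterm$id)]
    ifelse(is.na(f), "", f)
  } else ""
  all_species <- unique(c(species_map$species, hom$species))
  all_species <- all_species[!is.na(all_species)]
  sp_rows <- lapply(all_species, function(sp) {
    sub <- hom[!is.na(hom$species) & hom$species == sp, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(species = sp, n_homologs = 0L,
                        motif_class = NA_character_,
                        nterm_class = NA_character_,
                        equivalent_cys_count = NA_integer_, flags = "",
                        stringsAsFactors = FALSE))
    }
    data.frame(
      species = sp, n_homologs = nrow(sub),
      motif_class = .best_level(sub$motif_class, .motif_rank),
      nterm_class = .best_level(sub$nterm_class, .nterm_rank),
      equivalent_cys_count = if (all(is.na(sub$equivalent_cys_count)))
        NA_integer_ else max(sub$equivalent_cys_count, na.rm = TRUE),
      flags = paste(unique(sub$flags[nzchar(sub$flags)]), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  species <- do.call(rbind, sp_rows)
  rownames(species) <- NULL
  structure(list(species = species, homologs = hom),
            class = "species_profiles")
}

#' @export
print.species_profiles <- function(x, ...) {
  cat("Species profiles: ", nrow(x$species), " species, ",
      nrow(x$homologs), " homolog(s)\n", sep = "")
  print.data.frame(x$species)
  invisible(x)
}

#' Write / read a species-profile matrix as TSV
#'
#' The TSV is lossless: reading it back reproduces the profile table
#' exactly.
#'
#' @param profiles A `species_profiles` object or its `species` data.frame.
#' @param path Output file.
#' @return `write_profile_tsv`: the path, invisibly. `read_profile_tsv`: the
#'   profile `data.frame`.
#' @export
write_profile_tsv <- function(profiles, path) {
  df <- if (inherits(profiles, "species_profiles")) profiles$species else profiles
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(species = "character",
                                         n_homologs = "integer",
                                         motif_class = "character",
                                         nterm_class = "character",
                                         equivalent_cys_count = "integer",
                                         flags = "character"),
                          na.strings = "NA")
  df$flags[is.na(df$flags)] <- ""
  df
}

.normalize_label <- function(x) tolower(gsub("[ _]+", "_", trimws(x)))

# recursive ASCII cladogram; polytomies welcome, leaf order = tree order
.ascii_tree <- function(phy, leaf_text) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  lines <- character(0)
  rec <- function(node, prefix, connector) {
    is_tip <- node <= ntip
    label <- if (is_tip) leaf_text[node] else ""
    lines <<- c(lines, paste0(prefix, connector, label))
    if (!is_tip) {
      kids <- children[[as.character(node)]]
      child_prefix <- paste0(prefix,
                             if (connector == "") ""
                             else if (grepl("^\\+-", connector)) "|  " else "   ")
      for (i in seq_along(kids)) {
        last <- i == length(kids)
        rec(kids[i], child_prefix, if (last) "`- " else "+- ")
      }
    }
  }
  rec(root, "", "")
  lines[nzchar(lines)]
}

#' Render species profiles on a supplied species tree
#'
#' Annotates each leaf of a user-supplied cladogram with its profile glyphs
#' (motif class, equivalent-cysteine count, N-terminus class) and returns an
#' ASCII rendering plus a machine-readable matrix in tree (traversal) leaf
#' order. The topology is never altered; leaves without a profile are
#' rendered `NA` and profiles without a leaf are listed separately.
#'
#' @param profiles A `species_profiles` object.
#' @param tree An `ape::phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param normalize Match leaf labels to species names case-insensitively
#'   with spaces and underscores equivalent (default `TRUE`).
#' @return Object of class `profile_tree`: list with `text` (character
#'   vector of cladogram lines), `matrix` (profiles in leaf order),
#'   `unplaced` (profiles without a matching leaf), `tree` (the `phylo`).
#' @export
render_on_tree <- function(profiles, tree, normalize = TRUE) {
  stopifnot(inherits(profiles, "species_profiles"))
  if (!inherits(tree, "phylo")) {
    tree <- suppressWarnings(
      if (is.character(tree) && length(tree) == 1L && file.exists(tree)) {
        ape::read.tree(tree)
      } else {
        ape::read.tree(text = tree)
      })
    if (is.null(tree)) stop("could not parse Newick tree")
  }
  sp <- profiles$species
  key_tree <- if (normalize) .normalize_label(tree$tip.label) else tree$tip.label
  key_prof <- if (normalize) .normalize_label(sp$species) else sp$species
  idx <- match(key_tree, key_prof)
  glyph <- function(i) {
    if (is.na(i)) return("[NA]")
    sprintf("[motif:%s cys:%s nterm:%s]",
            ifelse(is.na(sp$motif_class[i]), "NA", sp$motif_class[i]),
            ifelse(is.na(sp$equivalent_cys_count[i]), "NA",
                   sp$equivalent_cys_count[i]),
            ifelse(is.na(sp$nterm_class[i]), "NA", sp$nterm_class[i]))
  }
  leaf_text <- sprintf("%s %s", tree$tip.label,
                       vapply(idx, glyph, character(1)))
  mat <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  mat$motif_class <- ifelse(is.na(idx), NA_character_, sp$motif_class[idx])
  mat$nterm_class <- ifelse(is.na(idx), NA_character_, sp$nterm_class[idx])
  mat$equivalent_cys_count <- ifelse(is.na(idx), NA_integer_,
                                     sp$equivalent_cys_count[idx])
  unplaced <- sp[!(key_prof %in% key_tree), , drop = FALSE]
  structure(list(text = .ascii_tree(tree, leaf_text), matrix = mat,
                 unplaced = unplaced, tree = tree),
            class = "profile_tree")
}

#' @export
print.profile_tree <- function(x, ...) {
  cat(x$text, sep = "\n")
  if (nrow(x$unplaced)) {
    cat("\nProfiles without a leaf:\n")
    print.data.frame(x$unplaced)
  }
  invisible(x)
}
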