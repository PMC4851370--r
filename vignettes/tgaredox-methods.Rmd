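---
title: "Methods: element scanning, equivalent-cysteine calling and delta-mass assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: element scanning, equivalent-cysteine calling and delta-mass assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgaredox)
```

## The biological setting

TGA-class bZIP transcription factors bind cis-regulatory elements built
around the TGACG core recognition sequence, the minimal requirement for
binding. One such element is a 33-bp region of the *AGAMOUS* second intron
whose 5' end starts with an AAGAAT hexamer and whose TGACG core sits in
reverse-complement orientation on the annotated strand. The Arabidopsis TGA
factor that binds this element carries an unusual N-terminal extension with
five cysteines (residues 27, 68, 87, 114 and 154 in the reference protein)
plus a sixth cysteine at position 340 in a putative transactivation domain;
its DNA binding is redox-sensitive, and mass spectrometry of the
recombinant protein identified an intramolecular disulfide bridge
(Cys68–Cys87) and S-glutathionylation (Cys340). This package implements the
three computational procedures needed to study that system comparatively:

1. scanning genomic sequences for AAGAAT-type element candidates and
   classifying them as full or partial motifs,
2. mapping reference cysteine positions through a protein multiple
   alignment to call equivalent cysteines in homologs and annotate their
   N-terminal extensions, and
3. in-silico AspN digestion with delta-mass assignment of observed neutral
   masses to cysteine-modification hypotheses,

joined by a per-species profile on a user-supplied cladogram, plus seeded
synthetic-data generators so every stage is testable with exact ground
truth and no downloads.

## Motif scanning and classification

A candidate is anchored by the hexamer AAGAAT, whose first position is
degenerate: A may be replaced by C or T. Anchors are searched on both
strands (`[ACT]AGAAT` and its reverse complement), each anchor seeds the
33-nt window that aligns the hexamer with its offset in the reference
element, and the window is compared to the reference by an ungapped
per-position (Hamming) count over the full fixed frame. The comparison is
ungapped by design: the procedure compares fixed-length element stretches,
not alignments with indels. A degenerate position counts as a match when
the window letter is in its allowed set; `N` never matches anything
(conservative).

Classification uses two thresholds. A **full motif** requires the TGACG
core anywhere in the window — on either strand, since the natural element
carries it in reverse-complement orientation — and at most
`max_dev_full = 7` deviations. A candidate retaining the hexamer anchor but
failing either condition is a **partial motif**; partial motifs lacking the
core with more than `min_dev_partial_report = 15` deviations additionally
carry a `canonical_partial` flag. The two published conditions for a
partial motif (no core, more than 15 deviations) are stated jointly and
leave the 8–15-deviation band undefined; we treat the >15 condition as
descriptive rather than as a gate, so every anchored candidate that is not
FULL is reported PARTIAL with its deviation count, and the flag marks the
canonical case. A sequence without any anchor is **ABSENT**. When several
candidates occur, one best call per sequence is selected: FULL over
PARTIAL, then fewer deviations, then the leftmost window, then the plus
strand — matching the one-status-per-species usage downstream.

Two further choices were genuinely open. The core is accepted anywhere in
the window rather than only at the reference's core offset, because the
published rule names core presence, not position; a positional restriction
would only tighten calls and can be imposed by editing the window before
scanning. Deviation counting runs over all 33 positions including the
hexamer and core themselves, which is the natural reading of deviations "in
the 33 bp sequence".

The 33-bp reference element itself is **not bundled**: published figures of
it are not machine-readable here and hallucinating sequence content would
be worse than requiring input. The shipped default is a synthetic 33-nt
element with the same architecture (hexamer at the 5' end, reverse-strand
core centrally placed, no secondary anchor or core on either strand), used
by the simulators and tests; for real analyses supply the element of your
reference species via `reference_motif()` or a YAML config
(`inst/extdata/example_config.yaml`).

## Equivalent cysteines and N-terminal extensions

Homolog comparison is alignment-based and the alignment is an input — it is
consumed as produced upstream (ClustalW-style, possibly manually adjusted)
and never recomputed, because a manual curation step cannot be reproduced
algorithmically. `map_position()` converts a 1-based ungapped reference
residue index to its alignment column by walking the reference's gaps; an
**equivalent cysteine** is a `C` at exactly that column (a ±k column window
is available as config but defaults to 0, the strict reading of
column-based presence/absence). Gaps and `X` never qualify; comparison is
case-insensitive. Reports use 1-based residue numbering, matching the
Cys27…Cys340 naming convention; columns are 0-based internally.

The N-terminal extension of a homolog is everything N-terminal of its
bZIP/basic-region start. When no start is supplied, `detect_bzip_start()`
finds the first window of width 16 whose K/R fraction reaches 0.4 and
returns the first K or R residue at or after that window's start — the
refinement matters because a qualifying window can begin several residues
before the basic block it overlaps, and the biologically meaningful
boundary is where the basic residues begin. Percent identity to the
reference N-terminus is computed over alignment columns strictly N-terminal
of the reference's bZIP start, counting only columns where neither sequence
is gapped. The published distinction between "significant" and "low"
N-terminal homology is not quantified anywhere; the defaults here —
SIGNIFICANT at ≥ 30 % identity (a conventional twilight-zone cut), ABSENT
below 20 extension residues, LOW otherwise — are explicit, configurable
stand-ins, not reconstructions. Homologs without a defined start codon are
annotated with a `start-codon-undefined` flag and no extension length
rather than being forced into a class.

## Digestion and delta-mass assignment

`digest()` applies the AspN rule — cleavage immediately N-terminal to every
aspartate — with 0..`max_missed` missed cleavages; cleavage before
glutamate as well is available (`cleave_before = c("D","E")`) because
vendor specificity statements vary. Peptide masses are residue-mass sums
plus water on the monoisotopic (default) or average scale.

Modification hypotheses shift the predicted mass by fixed deltas:

* **S-glutathionylation**: +305.06816 Da monoisotopic per site — the
  glutathione tripeptide (C10H17N3O6S, 307.08381 Da) minus the two
  hydrogens lost on forming the mixed disulfide. Reports of a "306 Da"
  glutathione mass difference are nominal/rounded; the chemically derived
  delta is what is implemented and matched.
* **Disulfide bridge** (intra- or intermolecular): −2.01565 Da, the loss of
  two hydrogen atoms; an intermolecular bridge sums both partner peptides
  first.
* **Carbamidomethylation** (+57.02146 Da) is available as an optional fixed
  modification for iodoacetamide-alkylated free cysteines, off by default
  so that comparison against predicted unmodified peptides remains the
  baseline.

Each applied hypothesis consumes cysteines from the peptide's budget
(glutathionylation one per adduct, a bridge two), so stacking beyond the
available cysteines is rejected; within the budget, deltas are additive and
commute. `match_masses()` assigns each observed neutral mass to the
candidate with the smallest absolute error within tolerance (default
0.5 Da, ion-trap-appropriate; ppm available), flags masses with two or more
in-tolerance candidates as ambiguous, and reports unmatched masses.
Observed lists may arrive as m/z with charge; `neutral_from_mz()` uses
M = z·(m/z) − z·1.0072765. Fragmentation-level evidence (ETD disulfide
cleavage) is out of scope; only neutral-mass matching is implemented.

## Per-species profiles on a tree

`build_profiles()` joins the three stages by a sequence-id → species map.
Species with several homologs (ancient duplications are common in this
family) keep every homolog as a sub-row; the species row carries the
maximum equivalent-cysteine count and the best motif and N-terminus class,
so per-homolog detail is never lost while the species-level summary remains
one row. The species tree is always supplied, never inferred, mirroring the
practice of adopting a published cladogram; `render_on_tree()` annotates
its leaves (matching names case-insensitively with spaces and underscores
equivalent), never alters the topology, renders leaves without profiles as
`NA`, and lists profiles without leaves separately. The TSV form of a
profile table is lossless under read-back.

## What the synthetic data emulate — and what they do not

`gen_intron()` plants reference-element copies with an exact deviation
count into an i.i.d. background of configurable GC (default 0.35,
intron-like, 1500 nt). Deviations avoid the hexamer anchor and the core so
the planted count is exactly realized; a broken core is produced by a
two-nucleotide core exchange (as in the binding-abolishing element mutant),
which is why a core-broken plant implies at least two deviations, and the
editable-position ceiling caps core-intact plants at 22 deviations of the
33. The background is order-0 by design: the classifier is window-local, so
higher-order background structure is immaterial to its contract —
consequently these simulations say nothing about motif *discovery* against
realistic intron composition, only about classification given an anchor.
`gen_protein_family()` builds alignments whose gaps occur only in
N-terminal extensions, with cysteine patterns and identity targets realized
by construction; real alignments have internal indels and alignment error,
so passing tests demonstrate correct position mapping, not robustness to
misalignment. `gen_mass_list()` adds Gaussian noise (default sd 0.01 Da) to
predicted masses; real spectra add adducts, deamidation and peak-picking
error that are out of scope. All generators are byte-deterministic per
seed, and every truth table is sufficient to score the downstream stage
without re-reading generator internals.

## Numerical choices and problem sizes

Residue masses are standard monoisotopic/average tables (8-decimal
monoisotopic precision, verified in the test suite against an independent
per-residue elemental-composition computation to 1e-6 Da over 1000 random
peptides); water is 18.01056468 Da, the proton 1.0072765 Da. Digest
conservation (0-missed peptides concatenate to the protein; masses sum up
to (n−1) waters) is asserted to the same precision. The scan is verified
against an exhaustive all-windows scorer on sequences up to 200 nt, and
planted-motif recovery is measured over 1000 seeded 500-nt backgrounds at
up to 7 deviations; these sizes make the whole suite run in seconds while
leaving the properties fully exercised. Tie-breaks are deterministic
everywhere (leftmost, then plus strand); degenerate inputs (empty
sequences, windows overrunning sequence ends, peptides without cysteines,
unmapped species ids) raise typed errors or explicit NA rows rather than
silent drops.

## Known limitations

* The element classifier is anchor-gated: a candidate whose hexamer is
  destroyed (beyond the allowed first-position degeneracy) is invisible,
  even if the rest of the window is well conserved.
* N-terminal homology classes rest on unpublished thresholds (see above)
  and should be read as configurable conventions.
* Mass matching is neutral-mass-level only; it cannot localize a
  modification within a multi-cysteine peptide (the per-cysteine summary
  reports all cysteines of a matched peptide as supported candidates).
* The equivalent-cysteine caller trusts the input alignment; column-exact
  equivalence is only as good as the alignment around the queried columns.
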