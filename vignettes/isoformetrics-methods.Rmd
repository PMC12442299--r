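---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoformetrics)
```

This vignette documents the models implemented in `isoformetrics`, the
parameters that matter, the synthetic-data generators used for testing,
and the design decisions taken where the procedure was genuinely open.
It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The analysis problem

The package compares pairs of protein isoforms produced by alternative
splicing: a *reference* isoform (the canonical sequence of a gene, with a
publicly available predicted structure) and an *alternate* isoform. Each
pair is described at three levels — transcript (exon chains), sequence
(global alignment), and structure (predicted atomic model with per-residue
confidence, pLDDT, stored in the B-factor column) — and the stages of the
pipeline quantify how splicing changes structure, PTM-site accessibility,
expression, and predicted function.

## Splicing event classification

`compare_exon_chains()` takes two exon chains on the same chromosome and
strand, normalises both to transcription orientation (so "first exon"
always means 5′-most and an exon's 3′ boundary is its donor), anchors on
exactly shared exons via a longest-common-subsequence match, and
classifies each unanchored gap:

* an internal reference exon absent from the isoform, flanking junctions
  shared → **ES** (host = isoform; the symmetric case has host =
  reference);
* one internal exon per transcript, mutually non-overlapping → **MXE**;
* a shared exon with one shifted boundary → **ADS** (3′/donor shift) or
  **AAS** (5′/acceptor shift);
* one exon exactly spanning an exon–intron–exon triplet of the partner →
  **IR**;
* terminal gaps: disjoint terminal exons joined to the same adjacent
  junction → **MXE-AFE** / **MXE-ALE**; any other terminal difference →
  **AFE** / **ALE**, except that a terminal exon pair sharing its outer
  boundary with a shifted inner boundary is a donor/acceptor shift
  (ADS/AAS). Inner exons of a terminal gap that overlap nothing on the
  other side are decomposed into plain skipping events, so a gap
  containing both a first-exon boundary shift and a skipped exon yields
  ADS + ES rather than one opaque terminal event.

The event-name vocabulary is fixed, but the published literature does not
pin down a construction rule for every configuration (notably AFE versus
MXE-AFE); the disjoint-exons/shared-junction rule above is this package's
documented choice. Every planted event type from `make_transcript_pair()`
classifies back to exactly itself on both strands (18/18), which the
acceptance suite verifies.

Event lengths are signed (isoform − reference, nt). For regression
features they are converted to residues by dividing by 3; reading frame
and UTRs are *not* modelled, so pairs whose event lengths are not
multiples of 3 are excluded from regressions with a warning. This is a
known limitation: real event boundaries need CDS-aware handling to count
residues exactly.

## Sequence comparison

`global_align()` is Needleman–Wunsch over BLOSUM62 with affine gaps,
delegated to `Biostrings::pairwiseAlignment` in global mode (end gaps
penalized). Defaults: gap opening 10, extension 0.5 — the conventional
values for this substitution matrix, configurable. Identity is identical
columns over total alignment length, so end gaps depress identity.

Region labels are derived from the alignment: isoform-gap runs are
`missing` unless adjacent to a reference-gap run, in which case both runs
are `replaced` (the reference side substituted by new isoform sequence);
reference-gap runs alone are `isoform_replaced`; aligned columns are
`shared` and project to `reference_other` / `isoform_other` per side.
Database annotations of variable splicing regions, where available, may
differ from this adjacency rule near ragged indel boundaries; the
alignment-derived labels are what the synthetic truth validates.

Effective MSA depth down-weights redundant rows:
`Neff = Σᵢ 1/(1 + Σ_{j≠i} 1(I_{ij} ≥ 0.8))`. Pairwise identity is
computed over mutually non-gap columns and normalised by the shorter
ungapped length — the redundancy literature does not fix the denominator,
so it is a documented, configurable choice.

## Structural metrics

**SASA.** Shrake–Rupley with probe radius 1.4 Å (water), 960 quadrature
points per atom, van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å.
The quadrature sphere is a Fibonacci point set expressed in a canonical
frame anchored on the structure's leading atoms; because that frame
co-rotates with the coordinates, SASA is invariant under rigid motions to
machine precision and is exactly monotone non-increasing as atoms are
added. The analytic single-sphere and two-sphere-overlap areas are
reproduced within 1% at 960 points.

**RSA and surface.** RSA divides per-residue SASA by the residue type's
theoretical maximum (Tien et al. 2013 values). Residues with RSA > 0.25
are *surface*; 0.25 is the field's usual exposure convention, and the
same threshold is reused for PTM exposure so that "surface" and "exposed"
mean one thing throughout. Reported per site are both absolute SASA (Å²)
and RSA; classification always uses the relative form.

**Surface charge.** Integer formal charges at pH 7 (Asp/Glu −1, Lys/Arg
+1, His 0, termini uncharged) summed over surface residues. This replaces
force-field per-atom charge assignment with a transparent model; a custom
per-residue charge table can be supplied.

**Radius of gyration.** Mass-weighted RMS distance from the mass-weighted
centroid (the standard square-root form).

**Secondary structure.** A simplified Kabsch–Sander assignment: amide H
placed 1 Å from N along the preceding C=O direction, hydrogen bond if the
electrostatic energy `0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` is
below −0.5 kcal/mol, helices from consecutive 3-/4-/5-turns, sheets from
parallel/antiparallel bridge patterns, eight states collapsed to three
(G/H/I → H, B/E → E, else L). Different assigners disagree at helix/sheet
termini; tests therefore check interior residues and fractions, not exact
per-residue strings.

**TM-score.** Sequence-guided: the residue correspondence is fixed by the
pair alignment and only the rigid superposition is optimised, by
fragment-seeded iterative Kabsch refinement (seed fragments of full,
half, and quarter alignment length; the aligned subset within a distance
cutoff is re-superposed to convergence). `d0 = 1.24(L−15)^{1/3} − 1.8`,
floored at 0.5 Å for short chains. The final score averages the
normalizations by reference and by isoform length, which makes the
protocol symmetric in the pair. The implementation agrees with an
independent oracle — direct numerical maximisation of the TM objective
over rigid motions from many restarts — to better than 1e−3 on ≤60-residue
fixtures (observed ~4e−8).

**pLDDT, disorder, isolated helices.** Per-residue pLDDT is the CA
B-factor. Quality classes use strict upper bounds: >90 high, (70,90]
confident, (50,70] low, ≤50 very low; boundary values fall in the lower
class because the band definitions are strict inequalities. IDRs are
maximal runs (≥20 residues) where the 25-residue centered window mean
pLDDT is below 70; these three parameters are configurable defaults in
the spirit of published pLDDT-window disorder criteria. Isolated helices
are runs of >20 residues that are simultaneously helical and exposed
(RSA > 0.25) — an artifact signature of predicted models used as a
filtering criterion, not a biological annotation.

**Outliers.** Tukey fences: Q1 − 1.5·IQR and Q3 + 1.5·IQR with
interpolated quartiles (R's default quantile type 7).

## PTM fate classification

Sites recorded on the reference map across the alignment; a gap column
means `spliced_out`. Isoform-only sites that cannot be mapped back are
`spliced_in`. Mapped sites compare exposure (RSA > 0.25) between the
structures: `unchanged`, `buried_to_exposed`, or `exposed_to_buried`.
Records whose stated residue letter disagrees with the sequence are
flagged and excluded from summaries; sites mapped onto a *substituted*
residue are classified normally but flagged `residue_changed`, since no
established convention exists for them. The five categories are
exhaustive and mutually exclusive by construction.

## Per-residue effect regression

For each outcome metric (TM-score, Δhelix%, Δsheet%, Δloop%, Δcharge,
ΔRg, ΔIDR fraction) the design has one row per pair: per-type splicing
lengths in residues plus the pLDDT difference, and the outcome
standardized to mean 0, sd 1. Signed mode splits ES and IR by host
transcript (they can occur in either); the TM-score outcome is
non-directional, so it forces absolute lengths with ES/IR unsplit.
Fitting is ordinary least squares with an intercept (the default of R's
`lm`, which is also what a practitioner would reach for) and classical
two-sided coefficient t-tests; no robust errors and no multiple-testing
correction across the effect grid — each cell is read at 0.05. Collinear
designs are rejected with the offending columns named rather than
silently dropped. Calibration is verified by simulation: exact recovery
without noise, ≥95% ±3·SE coverage at n = 500 over 100 seeds, and a
permutation null whose p < 0.05 rate is 0.05 ± 0.02.

## Isoform switching

Counts are TPM-normalised per cell (count/length rescaled to 1e6) and
log2(TPM+1)-transformed. Cell types with fewer than 30 cells are excluded
*before* testing. Each isoform of a gene is tested for expression
differences across the remaining cell types — Welch's t-test for two
groups (the equal-variance assumption is not defensible for single-cell
data), one-way ANOVA otherwise — on absolute log expression (isoform
proportions are an alternative reading of the procedure; absolute
expression is the implemented choice). Bonferroni correction uses the
family of all isoform tests in the run. An isoform's preferred cell type
is the argmax of mean log expression; fold change is the preferred-type
TPM mean over the other-types mean; both contrasts are documented
artifact choices since "sorted by fold change" does not define one. A
gene is a *switch* when at least two significant isoforms prefer distinct
cell types — isoforms upregulated in the same type never count as a
switch. The cross-tissue variant runs the identical machinery with tissue
as the grouping factor inside one cell type.

## GO scoring

Channel scores are weighted annotation fractions: sequence
(identity·bitscore weights), structure (identity·TM·bitscore), PPI
(STRING scores), and a logistic domain channel with externally supplied
weights (training is out of scope). The consensus combiner is a weighted
mean over available channels with a pluggable function hook — a
transparent stand-in for trained gradient-boosted consensus models, whose
weights are not portable. Confident terms need probability strictly
above 0.6. Gain/loss are plain set differences; no GO-hierarchy
propagation is performed (term sets are compared as given). Enrichment of
a term change within a splicing type is the upper-tail hypergeometric
probability (the point pmf is also returned, since a printed formula
alone does not disambiguate the two); it matches exhaustive enumeration
for small populations.

## Synthetic data: what it emulates and what it does not

Generators are deterministic given a seed, and every fixture carries its
ground truth.

* **Structures** are built from ideal internal geometry (N–CA 1.458,
  CA–C 1.525, C–N 1.329 Å, τ ≈ 111°; helix φ/ψ = −57/−47, strand
  −119/113, coil seeded random dihedrals) with backbone + CB atoms.
  They exercise SASA, secondary structure, Rg and TM-score correctly, but
  they have no side-chain rotamers: bulky residue types are
  under-exposed relative to their full-side-chain maximum ASA, so
  exposure-sensitive fixtures use small residues (poly-Ala). Passing
  tests demonstrate algorithmic correctness, not predictive realism.
* **Structure pairs** rebuild the isoform from the edited per-residue
  plan; surviving residues keep their torsions, so an empty edit
  reproduces the reference exactly while real edits change the global
  fold — mimicking how splicing changes a predicted model.
* **Transcript pairs** plant exactly one event of each type with 99-nt
  exons and introns (length changes are multiples of 3 by default).
  Minus-strand fixtures are mirror images, making strand invariance
  testable.
* **Expression** is negative binomial (dispersion 0.1 — full-length
  single-cell counts are overdispersed; the exact distribution is a
  generator parameter, not a claim) with a log2 effect of 5 between
  preferred and other cell types, noise sd 0.5, 100 cells per type as
  the planted-switch study condition.
* **MSAs** mutate the query at rate 1 − identity per row, which controls
  redundancy but has no phylogenetic correlation structure.

## Problem sizes and determinism

The test suite and acceptance script run on deliberately small problems:
25–60-residue structures, 100 rigid motions for invariance, 100 seeds for
regression coverage, 200 null genes for switch calibration, an
8-pair end-to-end cohort. These sizes give the property checks sharp
expected values while keeping the whole suite in minutes on one core.
Every stochastic step is seeded; `run_pipeline()` records the seed and a
configuration hash in its run log, and reruns are byte-identical.

## Known limitations

* Backbone-level synthetic structures (above): exposure calibrated for
  full-atom models should be re-checked before applying thresholds to
  other coarse models.
* nt→residue conversion ignores reading frame; frame-ambiguous pairs are
  excluded from regressions rather than guessed.
* Single-chain models only; multi-chain input keeps the first chain with
  a warning. Insertion codes and multi-model files are out of scope.
* The AFE/MXE-AFE discrimination and the "replaced" region adjacency rule
  are documented package choices where the literature is silent.
* The GO consensus combiner is intentionally simple; plug in a trained
  model via the `combiner` argument for production scoring.
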