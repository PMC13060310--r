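---
title: "Burial-based fold encodings: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burial-based fold encodings: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(burialcode)
```

## The encodings

`burialcode` treats a protein structure as a source of categorical label
channels and asks how well — and how cheaply, in bits — each channel pins
down the fold.

**Core identity.** Residue burial is measured by relative solvent
accessibility: the residue's solvent accessible surface area (SASA) divided
by its SASA in a fully exposed reference state. The binary core label is
`b_i = 1` iff `rSASA_i < 0.1` (strictly), `0` otherwise. The cutoff 0.1 is
the strictest burial definition that still ranks models well; `cutoff_scan()`
exposes the sensitivity analysis over a benchmark.

**Contact map.** `c_ij = 1` iff the Cα atoms of residues i and j are
strictly closer than 8 Å. The default puts no sequence-separation filter on
the N(N−1)/2 pairs — bonded neighbours count as (trivial) contacts. A named
`"esm2"` preset (Cβ atoms, glycine falling back to Cα, `|i−j| > 6`) matches
the convention used by sequence-based contact predictors, and is the right
configuration when ingesting such predictions.

**Secondary structure and H-bond satisfaction.** Backbone hydrogen bonds are
assigned with the Kabsch–Sander electrostatic criterion
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond iff
`E < −0.5`. Amide hydrogens are reconstructed on the bisector opposite the
C(i−1)–N and Cα–N directions at 1.01 Å; prolines and the N-terminus have no
donor; donor–acceptor pairs with `|i−j| < 2` are excluded. The 3-state
secondary structure (H/E/C) is a deliberately simplified reduction of that
bond pattern — runs of two consecutive O(i)⋯H–N(i+4) bonds mark helix,
parallel/antiparallel bridge patterns mark strand. It is **not** a DSSP
replacement and 8-state parity is out of scope; both channels are secondary
results in the analyses here.

**External alphabets.** `ingest_labels()` accepts any per-residue string
over a declared alphabet (e.g. a 20-letter 3Di string or a 0/1 predicted
burial string), validated character by character, so external encoders plug
into the same scoring and information machinery.

## Scoring agreement and model accuracy

Native-vs-model agreement of any labeling is the Matthews correlation
coefficient: the determinant form for two classes and the k-class
generalization `(cs − Σ p_k t_k)/√((s²−Σp_k²)(s²−Σt_k²))` otherwise. When a
margin of the confusion matrix is empty (a model predicting no core at all)
φ is undefined; we report 0 with a `degenerate` flag, which keeps downstream
rank correlations well defined and matches the "no correlation" reading.

Model accuracy is Cα LDDT: reference pairs are target Cα pairs with i ≠ j
and distance strictly below the 15 Å inclusion radius; a pair is preserved
at tolerance t ∈ {0.5, 1, 2, 4} Å iff the model reproduces its distance
within t (strict); per-residue scores average over tolerances and the global
score averages residues that have at least one reference pair. LDDT is not
symmetric — the first argument fixes the reference — and every piece
(radius, thresholds, separation) is configurable because published variants
differ in these details.

Because decoy sets are dominated by low-accuracy models, all reported
correlations are *flattened* bootstrap Spearman estimates: LDDT is cut into
20 equal-width bins over [0, 1], the same number of observations (the
smallest non-empty bin count) is drawn with replacement from every non-empty
bin, Spearman's ρ (average ranks on ties) is computed per replicate, and the
median over 1000 replicates is reported. Without flattening the correlation
mostly reflects the worst models.

## Information accounting

Each label outcome x carries `ι(x) = −log₂ p(x)` bits, with p(x) the pooled
outcome frequency over the native structures of the corpus. Frequencies are
exact when every outcome is observed; only when an outcome has zero count is
a Jeffreys pseudo-count of 0.5 added to **every** outcome (keeping ι finite
and probabilities normalized). This two-regime rule reconciles exactness on
well-populated corpora with robustness on tiny ones.

`subsample_restraints()` passes a random fraction of native labels per
target (rounded half-up, at least one), scores every decoy's φ over exactly
those positions, and books `I = Σ ι(native label)/N` per target, averaged
over targets (N is always the residue count, also for pair channels — that
is what makes full contact maps cost tens of bits per residue while burial
costs less than one). `rho_vs_I_curve()` repeats draws until the running
mean of I moves less than 1% (after at least 25 draws) or the repeat budget
is exhausted, whichever comes first; each fraction draws from an independent
stream derived from the master seed, so fractions can be computed in any
order or subset with identical results. `i_star()` linearly interpolates the
smallest I at which ρ crosses the threshold (0.9 by default) and reports
`NA` when the curve never gets there — some channels simply do not contain
enough information, and that absence is a result, not an error.

φ during subsampling is computed per decoy (each decoy is one observation
against its LDDT), since LDDT is a per-decoy quantity; the flattened
Spearman then runs jointly over all decoys of all targets. The per-target
normalize-then-average convention for I was chosen over pooled ΣN
normalization; with targets of similar length the two differ negligibly.

## Robustness and hydrophobicity

`flip_labels()` flips each native core label independently with probability
p (decoy labels are never touched), and `robustness_curve()` reports the
mean and standard deviation of ρ across repeated perturbations — the
practical question being how many labeling errors a sequence-based core
predictor may commit before φ stops ranking models.
`external_predictor_point()` places any such predictor on the same axes
(pooled mismatch fraction vs ρ). Per-residue-type base rates come from
`type_rates()`: probability of being core p_c, Shannon entropy
`H = −p_c log₂ p_c − p_s log₂ p_s` (with 0·log 0 = 0), and the accuracy rate
R of a prediction, each joined with the residue's hydrophobicity.

Core hydrophobicity is `ℋ = (1/N) Σ h_i b_i` and `Δℋ = ℋ_native − ℋ_model`;
Δℋ < 0 flags a model that buried a *more* hydrophobic core than the native
fold. The shipped `"consensus"` scale is the Eisenberg consensus
hydrophobicity scale (Eisenberg, Weiss, Terwilliger & Wilcox, normalized
consensus values); Kyte–Doolittle ships as `"kd"` and any named numeric
vector over the 20 types works. Unit tests deliberately use synthetic scales
so no literature values participate in correctness checks.

## The synthetic benchmark: what it emulates and what it does not

Real evaluations of this kind use community-experiment targets with tens of
thousands of predicted models. The package instead generates its own study
conditions:

* **Targets** are mixed-topology backbones of 50–70 residues (helices of
  8–14, strands of 5–8, coil linkers of 2–5), built from ideal bond geometry
  with (φ, ψ) = (−57°, −47°) for helix and the extended (−135°, +135°) for
  strand; coils sample the three allowed Ramachandran basins. Side chains
  are single typed pseudo-spheres at the Cβ position, sized from side-chain
  volumes. Candidate folds are clash-rejected (non-adjacent backbone atoms
  < 2.5 Å), the most compact of 25 candidates is kept, and a greedy
  Monte-Carlo hydrophobic collapse over the coil dihedrals (250 clash-free
  moves minimizing the hydrophobicity-weighted spread of side-chain centers)
  packs a preferentially hydrophobic core. Residue types are assigned so
  that deeper positions receive more hydrophobic types, with noise.
  Topologies are resampled until at least 8% of residues are buried at the
  0.1 cutoff, mirroring the fact that benchmark targets are globular single
  domains.
* **Decoys** add iid Gaussian noise (σ ∈ {0.1 … 3.5} Å by default) to every
  atom, giving LDDT values spanning roughly [0.25, 1] and occupying well
  over half of the 20 flattening bins; a geometry-preserving
  `segment_rotate` mode (σ interpreted as rotation-angle standard deviation
  in degrees) is available where covalent integrity matters.

What passing tests on this generator shows: the *machinery* — SASA, rSASA,
φ, LDDT, information accounting, flattening, flipping — behaves correctly,
and the qualitative structure holds (burial and contact φ both track LDDT
with flattened ρ > 0.5; more information never hurts; label noise degrades ρ
monotonically). What it does **not** show: quantitative agreement with
real-data headline numbers (per-label bit costs, I\* values, exact ρ),
which depend on real fold geometry, side-chain packing and the accuracy
distribution of real predictors. Gaussian decoys also break covalent
geometry, which is acceptable only because no channel in scope depends on
it.

Default problem sizes in the test suite (2–3 targets, 16–40 decoys each,
25 or fewer subsampling repeats, a few hundred bootstrap replicates) were
chosen as the smallest sizes at which the qualitative properties are stable
across seeds; every generator default above is fixed once here and not
tuned per run.

## Numerical choices

* **SASA** uses Shrake–Rupley test points from a deterministic golden-section
  spiral (no RNG), 960 points per atom by default; results are
  bit-reproducible and converge to well under 1% against 3840 points. Only
  heavy atoms contribute; the probe is 1.4 Å. Per-atom area never exceeds
  the isolated expanded sphere, and total area is rigid-motion invariant to
  point-scheme tolerance.
* **Reference state**: the rSASA denominator is the residue's SASA as the
  central residue of an extended Gly-X-Gly host *recomputed with the active
  radii, probe, point count and side-chain representation* (and cached per
  settings). Self-consistency makes rSASA robust to radii-table swaps and to
  the coarse pseudo-side-chain representation; a literature table can be
  supplied instead. Backbone atoms are included in both numerator and
  denominator. rSASA is clamped at 1.5 — conformations may expose slightly
  more area than the extended host; such values are legal and never core.
* **Radii**: the shipped table is standard van der Waals values (C 1.70,
  N 1.55, O 1.52, S 1.80 Å) plus the per-type pseudo-sphere radii, matched
  first on (residue, atom name), then by element. It is a documented
  stand-in for any validated production set and fully swappable via
  `read_radii()`.
* **Strict inequalities** everywhere a cutoff appears (contacts, burial,
  LDDT preservation), with boundary behaviour covered by tests.
* **Indexing** is 1-based and contiguous after parsing, the R convention;
  original PDB numbering and insertion codes are retained as metadata, and
  duplicated residue numbers with insertion codes stay distinct positions in
  file order.
* **Alignment** of target/model pairs is global Needleman–Wunsch (BLOSUM62,
  gap open −10, extend −0.5, first gap position charged open+extend);
  terminal overhangs are trimmed on both sides until lengths match exactly,
  and any interior gap in the optimal alignment rejects the pair — model
  sets are expected to differ from targets only at the ends, and silently
  realigning around internal indels would corrupt position-wise label
  comparisons.
* **Degeneracies**: φ with an empty margin is 0 (flagged); residues with no
  LDDT reference pairs are excluded from the global mean; an all-tied φ
  vector makes the flattened Spearman 0 (flagged) rather than NA.

## Limitations

* The coarse representation cannot reproduce real packing densities, so
  absolute bit costs and I\* values from the synthetic benchmark are not
  comparable to real-data numbers.
* The secondary-structure detector is 3-state and simplified; isolated
  strands (no partner) are labeled coil.
* Only single protein chains are handled (monomeric use case); mmCIF,
  NMR multi-model files and assemblies are out of scope.
* The hydrophobic-collapse refinement is a sampling heuristic, not a
  physical folding simulation; it exists to give the burial channel
  realistic variation, nothing more.
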