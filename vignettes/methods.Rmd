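---
title: "Surface-voxel paratope prediction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-voxel paratope prediction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paratopeVox)
```

## The problem and the model

Antibodies bind antigens through a small set of surface residues — the
paratope — concentrated in, but not confined to, the CDR loops of the
variable domain. `paratopeVox` predicts these residues from the antibody
structure alone. The ground truth is geometric: a residue binds iff any of
its heavy atoms lies within 4.5 Å of any antigen heavy atom. We use `<=`
uniformly (for residue labels, surface-point labels and the pair sanity
check); the distinction between `<` and `<=` is measure-zero on real
coordinates but matters for fixtures constructed exactly at the cutoff, so
one convention is applied everywhere.

Prediction is formulated on the *surface*, not on residues directly. A
dot-sampled solvent-accessible surface assigns each surface point a local
41×41×41 voxel grid (1 Å voxels) oriented by the point's outward normal,
each voxel carrying 22 per-atom channels. A deep network scores each grid
in [0, 1], and a residue's score is the maximum over its surface points.
The max is deliberate: a residue binds if *any* patch of its surface does,
and the max is permutation-invariant and monotone — raising a point score
can never lower a residue score.

## Surface generation

The reference pipeline uses the external DMS program. To keep this package
free of binary dependencies we implement an equivalent rolling-probe dot
surface natively and also parse DMS files. Each heavy atom gets
`round(density · 4πr²)` dots on its expanded sphere of radius
`r = r_vdW + probe` (probe 1.4 Å, the standard water probe, which the
source text does not specify); dots strictly inside any other atom's
expanded sphere are removed; normals point radially outward from the parent
atom. Density defaults to 0.5 dots/Å², the value recommended for large
molecules. Dots are placed on a deterministic Fibonacci lattice oriented by
the molecule's principal axes (with a third-moment sign convention and a
cross-product third axis), so surface generation needs no seed, is
bit-reproducible, *and* is rigid-equivariant: rotating the structure
rotates dots and normals with it, which a lattice fixed in the global frame
would violate through orientation-dependent occlusion. The cost is that our
dot positions are not bit-identical to DMS output. All downstream contracts are
therefore stated as invariants (unit normals, exact dot radius, no interior
dots, rigid equivariance to 1e-6) rather than file diffs. Whether DMS's
probe conventions differ from ours cannot be resolved from the text we
worked from; the DMS reader uses that file's normals verbatim.

## Feature channels

Each heavy atom contributes 22 channels: a 9-way element-class one-hot
(B, C, N, O, P, S, Se, halogen, metal — unclassifiable elements get an
all-zero class vector and a warning), hybridization (coded 2 for sp2, 3 for
sp3), heavy valence, heterovalence, partial charge, five pattern flags
(hydrophobic, aromatic, H-bond acceptor, H-bond donor, ring), and four
force-field channels (AMBER and CHARMM charge and radius). No
cheminformatics toolkit exists for R in this stack, so the pattern
semantics are encoded as explicit per-(residue, atom-name) tables for the
20 standard amino acids — e.g. aromatic = the named ring atoms of
Phe/Tyr/Trp/His; donor = backbone N (except proline) plus the familiar
side-chain N/O/S donors; acceptor = carbonyl and carboxylate oxygens,
hydroxyls and His ND1 — together with two connectivity-derived rules:
valences come from distance-based bond perception
(`d <= r_cov,i + r_cov,j + 0.45 Å`) and "hydrophobic" means a carbon bonded
only to carbon (or a halogen). These tables are the package's reference
definitions of the patterns.

Force-field channels are read from PQR files when supplied (one per force
field; the last two numeric columns are charge and radius). Without PQR we
fall back on packaged residue-template tables: Amber-94-like backbone and
charged-group charges with element-typed generics, mbondi-style radii, and
a CHARMM-like alternative set. These templates are approximate by
construction — they exist so the pipeline runs without external software —
and nothing in the package's validated behaviour depends on their precise
values; tests assert *source isolation* (channels 1–18 never change when a
PQR is supplied; only 19–22 do) and plumbing (PQR misses are zeroed and
logged). Structures whose PQR generation failed upstream are excluded from
training sets by the CLI's exclusion manifest, mirroring how incompatible
structures are dropped in practice.

## Grids

The normal fixes only one grid axis; the in-plane orientation is arbitrary.
We take the third frame row to be the normal and the first to be the global
x-axis (y when nearly parallel) projected into the tangent plane. The
90°-rotation augmentation applied during training is the pipeline's own
mitigation of exactly this arbitrariness, so the choice is benign. Voxel
intervals are half-open with the centre voxel spanning [−0.5, 0.5) Å per
axis; an atom maps to the voxel containing its frame-transformed offset
(no density smearing), and atoms sharing a voxel are summed channel-wise —
summation preserves the per-channel totals that the rotation tests rely
on. A 41-voxel grid at 1 Å therefore covers every atom within 20 Å of the
centre. Voxelization commutes bit-exactly with joint rigid translation of
structure and centre, and with joint rotation up to atoms within half a
voxel of a bin boundary.

Balanced sampling draws up to 800 binding-eligible surface points
(`<=` 4.5 Å from an antigen heavy atom) and exactly as many negatives,
uniformly without replacement, shrinking the positive count (and with it
the negatives) when fewer are available; a pair with zero eligible points
is unusable and is flagged. Negatives are drawn uniformly over all
non-positive points — whether the original used a minimum-distance buffer
is unstated, so the simplest rule is implemented. Augmentation applies one
quarter-turn per grid per epoch; whether several turns compose per sample
is likewise unstated.

## The network

The published description fixes: an initial 3D convolution; four residual
stages of dilated bottleneck blocks ending at 2048 channels; a 1×1×1
compression 2048 → 256 with batch norm and ReLU; a transformer block with
self-attention over the spatial positions; global average pooling; dropout
0.1; a fully connected sigmoid head. Unpublished details — per-stage block
counts, strides, dilation rates, token scheme, head count — are
reconstructed canonically: stages of 3/4/6/3 bottlenecks (a 3D
ResNet-50-style layout), strides 1/2/2/2, dilations 1/1/2/4, a 7³ stride-2
stem with 3³ stride-2 max-pool, 8 attention heads over the flattened
post-compression spatial tokens with learned positional embeddings and a
pre-norm transformer block. Every choice is a `modelConfig()` field.

No deep-learning framework exists for R in this environment, so all layers
are implemented in-package: 3D convolution as chunked im2col plus BLAS
gemm (Rcpp/Armadillo), batch norm, max pooling, multi-head attention,
layer norm, dropout, Adam, and binary cross-entropy on the logits (the
numerically stable softplus form). Every backward pass was verified against
central finite differences during development. Training follows the stated
recipe: Adam at 1e-4 divided by 5 every 5 epochs (`lr(e) = lr0 / 5^⌊e/5⌋`,
epochs 0-based), batch size 64, best-validation-loss checkpointing (the
returned model carries the best epoch's weights), optional early-stopping
patience, and full determinism given the seed. Single-class datasets are
rejected: with the balanced sampling design, BCE on one class is
degenerate.

A width-reduced configuration (`reducedModelConfig()`: 9-voxel grids, one
bottleneck stage, trunk 64, compression 16, 2 heads, ~20k parameters) is
first-class so that training-mechanism tests run on one CPU. Its learning
rate is 3e-3 rather than the full model's 1e-4: at 1600 training grids and
5 epochs the optimiser takes only 125 steps, and a step size sized for a
48M-parameter GPU model under-trains a 20k-parameter one in that budget.
With 3e-3 the reduced model clears the planted-rule recovery bar (held-out
AUROC at least 0.95 within 5 epochs, computed by the test suite). The
full-size defaults are untouched.

## Synthetic data: what it does and does not establish

`makeToyComplex()` builds receptors of rigid 4-atom glycine-like units on a
line (6 Å spacing) above an antigen lattice; each interface residue's
lowest atom sits *exactly* `minDist` (default 3.5 Å) above an antigen atom
and every other residue at `decoySep` (default 12 Å), so the true label set
is known by construction and the construction is deterministic
(byte-identical PDB across runs). Toy complexes exercise every geometric
code path — labelling, surfaces, sampling (both the abundant and the capped
branch, via interface sizing), voxelization, inference — but are chemically
minimal: pattern-flag channels are exercised separately on small
real-residue fixtures embedded in the test suite. A green toy test
establishes geometric and contractual correctness, not predictive accuracy
on real antibodies.

`makePlantedGrids()` is the desk-scale stand-in for GPU-scale training:
white-noise grids in which positive grids carry a constant shift spread
over the central 3×3×3 block of one channel. The per-voxel shift is
`effect · noise / √27`, so the central-region sum separates classes by
`effect` null standard deviations and the one-feature oracle has AUROC
`pnorm(effect/√2)` in closed form (0.9998 at effect 5). Classes are
exactly balanced and the dataset is a pure function of its seed. The grid
edge defaults to 9 voxels: 2000 grids at the full 41³×22 geometry would
occupy ~24 GB, which is precisely the regime the reduced configuration
exists to avoid; the channel count stays 22. Recovery of the planted rule
by the reduced network (held-out AUROC ≥ 0.95 within 5 epochs) demonstrates
that the training mechanism — grids in, BCE/Adam/schedule, scores out —
works; it says nothing about paratope accuracy, which requires the
benchmark datasets and GPU-scale training that are out of scope here.

## Evaluation

IMGT positions are an *input* (a mapping table per chain, validated for
range and monotonicity): how structures are renumbered is outside the
package, and no sequence-based numberer is bundled. Regions follow the
fixed ranges FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104,
CDR3 105–117, FR4 118–128, constant beyond. CDR±2 extends each loop by two
residues *along the ordered chain*, robust to insertion-code gaps, and
truncates at chain ends. Scopes nest: CDR ⊆ CDR±2 ⊆ Fv (1–128) ⊆ Fab.

AUROC is the Mann–Whitney statistic with ties counted one half — identical
to pairwise concordance, which the tests verify against an O(n²) oracle.
AUC-PR uses step interpolation (average precision), with tied scores
grouped so the curve is evaluated only at distinct thresholds; the
enumeration oracle in the tests pins this convention down so comparisons
are reproducible. CAUROC is the median of per-complex AUROCs;
complexes whose scoped residues are single-class have no AUROC and are
excluded from the median (with a warning) while still counting in the
pooled threshold metrics. Pooled metrics are micro-averaged over residues
by default — whether published pooled numbers are micro- or macro-averaged
is not stated, and macro-averaging can be had by evaluating per complex
and averaging the reports. Classification uses strict exceedance
(score > threshold), at 0.5 by default and 0.734 for comparison with
sequence-based work (that threshold's provenance is external to the source
we reimplement).

The positional baseline scores each (chain type, IMGT position) by its
binding frequency in a training cohort, with unseen positions scoring 0 —
the standard reference point for how much structure adds over position
statistics.

## Numerical choices and degenerate inputs

- Altloc records keep the highest-occupancy conformer (ties: first
  encountered); the source text is silent, and this is the common choice.
- Monoatomic HETATM residues on a fixed ion name list are removed at
  cleaning; MSE and similar modified residues are retained as protein.
  Cleaning is idempotent and an all-hetero structure is an error.
- Distance queries use a cell-list spatial index (cell edge = cutoff) that
  is exact, and is tested for equality with brute force.
- Residues with no surface dots score 0 with a `noSurface` flag.
- B-factor annotation is fixed-width with 2 decimals (PDB format limit).
- Batch-norm in evaluation mode uses running statistics, so scoring is
  deterministic and batched scores match single-sample scores to 1e-6.
- The surface-point scored unit vs the "atom" wording: surface points are
  scored and residues aggregated via the max, as the pipeline's overview
  figure depicts.

## Known limitations

- The network reconstruction pins unpublished hyperparameters; published
  benchmark numbers are not reproducible here (datasets and GPU training
  out of scope), and none are claimed.
- The packaged force-field templates are approximations; supply PQR files
  for faithful electrostatics.
- Pattern tables cover the 20 standard amino acids; exotic ligands fall
  back to connectivity rules.
- The dot surface is solvent-accessible only; reentrant (Connolly) patches
  and analytic areas are non-goals.
- R's pipeline is desk-scale: full 41³ grid sets for whole antibodies
  should be streamed to disk (`writeGridDataset()`), not held in memory.
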