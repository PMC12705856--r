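---
title: "Gyre geometry and ensemble dynamics of nucleosome-like particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gyre geometry and ensemble dynamics of nucleosome-like particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyredyn)
```

## The measurement problem

In a nucleosome, ~147 bp of DNA wrap the histone core in about 1.65
left-handed superhelical turns, so the duplex passes the core twice: two
*gyres*. Octasomes — particles built from two (histone/H4)~2~ tetramers
without H2A/H2B — wrap DNA the same way but hold the two gyres together
much more loosely, and the degree of gyre separation ("gapping") is the
quantity that distinguishes a compact nucleosome from a breathing,
clamshell-like octasome. This package provides the measurements that make
that comparison quantitative, for single structures (cryo-EM/crystal
models) and for conformational ensembles (MD trajectories or any
multi-model source).

All positions along the wrapped DNA are addressed *dyad-relative*: the
pseudo-two-fold base pair is index 0, indices increase 5'→3' along strand 1.
Deposited models differ in author numbering (the dyad is author residue 0
in octasome-style models but 73 in older nucleosome entries), which is why
`build_duplex()` accepts either an automatic middle-pair dyad or an
explicit author residue address, and why distance measurements accept both
dyad-relative indices and `list(chain =, resnum =)` author addresses
without guessing which convention a label uses.

## The observables

**Clamshell angle and gyre distance.** The operational definition is
atom-level: with `P(i)` the purine N1 position of the pair at index `i`,

* `gyre_angle`: the interior angle at `P(0)` of the triangle
  `P(-39), P(0), P(+39)` (degrees);
* `gyre_distance`: `|P(+39) - P(-39)|` (Å).

The offset 39 bp places the arm points half-way between dyad and DNA ends
of a 147-bp wrap; it is configurable for shorter constructs. A
`bp-center` mode (midpoint of the two C1' atoms) is provided as the
alternative vertex definition; the N1 form is the default because it is
fully determined by single atoms. The angle is evaluated with the
`atan2(|u×w|, u·w)` form, which stays well-conditioned near 0° and 180°.

**Rigid-body superposition.** `superpose()` is a standard Kabsch
least-squares fit (SVD of the cross-covariance, determinant-corrected so
reflections are never returned — mandatory for chiral biomolecules). It
returns the rotation, translation and RMSD; (near-)collinear selections
are rejected because their rotation is undetermined.

**Four-helix-bundle rotation.** `bundle_rotation()` superposes structure A
onto B via anchor selections, fits both probe helix axes
(principal direction of the centred trace atoms, oriented N→C) and
reports the acute line-line angle in [0°, 90°]. The line-angle convention
is deliberate: an overlay divergence read from a figure has no sign, and
a 120° construction is genuinely indistinguishable from 60° at the axis
level. A `signed = TRUE` variant resolves the sense of rotation about the
anchor axis for users who need it.

**Hydrogen-bond audit.** `hbond_distances()` reports donor–acceptor
heavy-atom distances only — no angular or energetic scoring — matching how
interface quality is described for the Arg/Asp/His (RDH) triads of
homotypic four-helix bundles. `rdh_contacts()` carries the three preset
interfaces (CENP-A 118/125/115, H3 116/123/113, H4 78/85/75). The choice
of which Arg/His nitrogen faces which Asp oxygen is a documented package
convention; the planted-distance fixture (`make_rdh_fixture()`) tests the
plumbing, not hydrogen-bond chemistry.

## Ensemble analyses

`align_ensemble()` performs the usual iterative fit-to-running-mean until
the mean structure moves < 1e-6 Å (RMS over the fit selection, cap 100
iterations; non-convergence warns and flags the result rather than
failing silently).

`rmsf_profile()` computes per-residue RMSF about the time-mean position
after alignment, aggregated by `atom_policy` (`CA`, `P` or `heavy-mean`),
and converts to B-factors with the isotropic crystallographic relation
`B = (8π²/3)·RMSF²`. The relation is adopted explicitly because "thermal
B-factors predicted by MD" is otherwise ambiguous. Which atoms per-residue
RMSF plots use is likewise often unstated in the literature; the policy
switch covers the plausible readings.

`pca_modes()` is unweighted Cartesian PCA on a reduced atom set (default
protein Cα plus DNA P), computed by SVD of the centred frame matrix so
that eigenvalues are exact sample-covariance eigenvalues and their sum
equals the total positional variance to machine precision. Unweighted is
the default because mass weighting is an assumption, not a given; a
`weights` argument provides it when wanted.

**Hinge detection.** The dominant mode of a breathing particle is an
oscillation of the DNA arms about two hinge base pairs. `hinge_positions()`
reduces mode 1 to a per-bp amplitude `a(i)` (mean 3-vector norm over the
pair's selected atoms), thresholds at `k = 2` times the median amplitude
of the core (`|i| ≤ 20`), and on each arm finds the contiguous
above-threshold run reaching the arm's end; the hinge is the pivot pair
just inside that run. Requiring the run to reach the arm end makes the
detector immune to isolated noise spikes that a plain first-crossing scan
would mistake for a hinge; if an arm never sustains the threshold the
result is an explicit no-hinge (`NA`), never a fabricated index. `k` and
the core half-width are parameters and are reported in the output.
`detect_dna_hinges()` wires the pipeline end-to-end, aligning on the rigid
DNA core (P atoms, `|i| ≤ 20`) — aligning on all atoms would let the
moving arms drag the fit and smear coherent counter-motion into the core.

`metric_series()` re-evaluates any geometric metric per frame (the duplex
is resolved once on the topology; frames only swap coordinates), and
`metric_density()` turns a series into a normalized histogram with mean ±
SD, the summary used for opening-angle distributions.

## The synthetic generator

Real octasome trajectories are hundreds of nanoseconds of ~10^5^-atom
systems; nothing desk-sized can re-create them. What *can* be tested
offline is every inferential step between coordinates and reported
numbers, provided the inputs have known ground truth. The generator
builds:

* `make_superhelix_duplex()` — a duplex of pseudo-atoms (C1' ×2, purine
  N1, pyrimidine N3, P ×2 per bp) on idealized local frames along a
  parametric superhelix. Defaults (147 bp, radius 41.9 Å, pitch 25.9 Å,
  1.65 left-handed turns, 36°/10.5 bp local twist) are canonical
  nucleosome-scale geometry and give a closed-particle θ of ≈ 25.7°,
  i.e. the right order for particles whose openings are discussed in the
  18–28° range. The Watson–Crick criteria hold by construction and the
  ground-truth pairing is returned, so detector and generator must agree
  exactly (a closure test, not a tautology: the detector never sees the
  bookkeeping).
* `open_clamshell()` — rigid gyre translation along the superhelix axis
  and/or rigid arm rotation about a hinge pair, with ground truth updated.
* `gaussian_ensemble()`, `clamshell_ensemble()`, `hinge_mode_ensemble()` —
  seeded, bit-reproducible ensembles carrying isotropic noise, oscillating
  or Gaussian-distributed gyre translation, and sinusoidal arm bending
  about chosen hinges (defaults −46/+60, amplitude 15°, jitter 0.2 Å).
* `make_bundle_pair()` — two pseudo-bundles whose probe helices differ by
  an imposed rotation about the anchor axis. The helical phase of
  `make_ideal_helix()` is centred on the trace midpoint, which confines
  the inherent principal-axis tilt of a finite helix to the rotation
  plane; the imposed angle is then recovered exactly in the noiseless
  case rather than to ~0.02°.

What the generator deliberately does *not* emulate: sequence-dependent
DNA mechanics, histone atoms and their packing, solvent, correlated
thermal motion beyond the single imposed mode, or experimental map noise.
Green tests therefore certify the measurement chain — pairing, indexing,
geometry, alignment, PCA, detection — not the biology of any particular
trajectory.

## Numerical and design choices

* **Antiparallel criterion.** Pair assignment is greedy on purine-N1 to
  pyrimidine-N3 distance (≤ 3.5 Å) with a C1'–C1' gate (10.4 ± 1.5 Å);
  local antiparallelity is then enforced through partner ordering
  (partner residue numbers strictly decrease along strand 1). A naive
  per-residue C1' step-vector dot product fails on genuinely antiparallel
  duplexes because the helical twist dominates the step vector; the
  ordering form is the twist-insensitive statement of the same
  constraint.
* **Ambiguity and ties.** Multi-candidate pairing resolves by minimal
  N1–N3 distance, ties by lower residue number. Altloc resolution keeps
  the highest-occupancy conformer, ties by altloc identifier order.
  Everything is deterministic.
* **Degenerate inputs.** Zero-length angle arms, collinear superposition
  selections, < 4 axis atoms, single-frame RMSF/PCA, empty selections and
  unresolvable addresses all raise classed errors (`gyredyn_*`), never
  silent results. Missing pairs at ±offset are hard errors; nothing is
  substituted silently.
* **Formats.** PDB (fixed-width v3.3, 1e-3 Å) and mmCIF (`atom_site`,
  1e-6 Å) for single structures; multi-model PDB is the single ensemble
  interchange format. Binary trajectory formats are out of scope: every
  consumer here also wants the topology, and a text format keeps the
  package free of compiled I/O.
* **Sampling checks.** The flat-spectrum PCA property is asserted against
  the Marchenko–Pastur edges `(1 ± sqrt(q))²` for aspect ratio
  `q = 3n/frames`, computed in closed form, rather than against an ad hoc
  max/min ratio.
* **Problem sizes.** The shipped tests and drivers use 147-bp duplexes
  with ensembles of 120–2000 frames and 100-replicate oracle sweeps —
  sizes chosen so the full study re-runs in well under a minute while
  keeping sampling tolerances (e.g. 3% on RMSF at 2000 frames ≈ 3.3
  standard errors) meaningful.

## Known limitations

* Watson–Crick detection assumes author residue numbers increase 5'→3'
  within each strand; exotic renumbering defeats the partner-ordering
  criterion.
* Only canonical DA/DG/DC/DT (and one-letter) residues pair; modified
  nucleotides at paired positions are a hard error by design.
* `hinge_positions()` reports one hinge per arm — the dominant-mode
  description — and cannot represent multiple hinges on the same arm.
* The RDH preset audits distances for one fixed atom-pairing convention;
  rotamer-dependent alternatives (e.g. OD1/OD2 swaps) are the caller's
  responsibility.
* mmCIF writing emits the minimal `atom_site` category only (no entities,
  no assemblies).
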