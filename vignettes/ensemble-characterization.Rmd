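---
title: "Characterizing disordered-protein ensembles: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing disordered-protein ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter (with units and
defaults), the numerical decisions taken where the methodology is genuinely
open, what the synthetic generator does and does not emulate, and the known
limitations. The companion README shows a worked run; nothing stated here
goes beyond what the package's tests and acceptance script themselves
compute.

## The problem

An intrinsically disordered protein (IDP) in its unbound state is an
ensemble: many interconverting conformations, from extended random-coil-like
chains to collapsed globules, with transient local structure (usually short
helices) and transient tertiary contacts. Characterizing such an ensemble
means answering, quantitatively: how heterogeneous is it; which collective
motions dominate; which conformational substates exist and how populated are
they; how much secondary structure and how much exposed surface does each
substate carry; and which residue–residue interactions stabilize the compact
states. `idpens` implements one coherent chain of answers, applicable to any
coordinate ensemble (multi-model PDB or the built-in generator), plus the
orthogonal experimental view given by native electrospray mass spectrometry.

## Units and containers

All coordinates are stored in nanometres; PDB Ångström values are converted
at the read/write boundary and round-trip to 1e-4 nm (the fixed-width PDB
precision). A `conformational_ensemble` is an atom/residue topology plus an
`A x 3 x F` coordinate array; residue numbering is taken verbatim from the
input and never rewritten.

## Superposition and RMSD

Rigid-body motion is removed by least-squares (Kabsch) superposition over a
selection (`"ca"` for the Cα trace, `"mainchain"` for N/CA/C/O). The
iterative-mean variant fits every frame to the current ensemble mean,
recomputes the mean, and repeats to a 1e-12 nm tolerance. Starting from the
ensemble mean (rather than an arbitrary frame) makes the operation
idempotent — an already-superposed ensemble is its own fixed point — which is
also the property the test suite asserts; with a degenerate mean (e.g.
synthetic frames related by pure rotations) the first frame seeds the
iteration instead.

Pairwise RMSD matrices re-fit each pair by default (`fit = "pairwise"`).
Whether published pairwise RMSDs use per-pair fits or one global
superposition is usually unstated; both modes are exposed, and per-pair
fitting is the default because it makes the matrix independent of any
global reference choice.

## Essential dynamics

PCA diagonalizes the covariance of positional fluctuations about the mean,
optionally mass-weighted (standard atomic masses by element; pseudo-atoms
count as carbon). For Cα selections of ~70 residues the 3A x 3A symmetric
eigenproblem is trivial; above 3000 coordinates the F x F dual problem is
solved instead, which carries the identical non-zero spectrum.

RMSIP between two decompositions is the root-mean-square of the d x d inner
products, `sqrt((1/d) * sum (eta_i^A . eta_j^B)^2)`, with d = 10 by default.
The squared-and-rooted form is the one that satisfies RMSIP(A, A) = 1 and is
invariant under rotations of the basis *within* each subspace — both asserted
in the tests; a plain sum of inner products satisfies neither. For two
independent random d-dimensional subspaces of an n-dimensional space the
expected squared inner-product sum is d²/n, so the null expectation is
`sqrt(d/n)` (≈ 0.218 for d = 10, n = 210); the test suite reproduces this by
Monte Carlo over Haar-random frames. Values above 0.5 for the first ten
eigenvectors are the usual benchmark for converged replicate trajectories.

## Free-energy landscapes and basins

Over two reaction coordinates the surface is `G = -kT ln P`, with P a joint
histogram (default 32 x 32 bins over the 2%-padded data range; kT in kJ/mol
with k = 0.0083145 kJ/mol/K). Two numerical choices:

* **Empty bins are masked, not infinite.** Unpopulated bins carry `NA`, so
  no infinities propagate into basin search; re-exponentiating the populated
  bins recovers the histogram to 1e-10 relative error.
* **Bin counts should match the sample size.** A rule of thumb of ~sqrt(F)
  bins per axis keeps basins contiguous; the end-to-end tests use 8 x 8 for
  80-frame ensembles and 32 x 32 for 10⁴-sample surfaces.

Published landscape figures are usually annotated by eye; the package
instead decomposes the surface algorithmically, so the procedure had to be
fixed by design: every populated bin descends to its local minimum over
8-neighbourhoods (ties toward the lowest linear index, so the decomposition
is deterministic); a basin whose depth — lowest connecting saddle minus its
minimum — is below `min_depth` (default 1 kT) is merged across that saddle,
shallowest first. Isolated islands of populated bins have no connecting
saddle; they can only escape over the highest observed energy, so their
depth is taken against that ceiling and they merge toward the nearest basin.
This yields the limiting behaviours the tests pin down: a single-Gaussian
surface gives one basin, two well-separated Gaussians give two basins of
half the population each, and a merge threshold above the full G range gives
exactly one basin. Basins are labelled A, B, C… by increasing minimum G;
basins below `min_population` (default 2%) are reported as minor and, by
default, excluded from the per-basin analyses. No free-energy barrier
heights are reported as physical quantities: histogram landscapes over two
coordinates are not accurate enough for that.

## Gromos clustering and the order parameter

Gromos clustering is the greedy neighbour-count algorithm on the pairwise
RMSD matrix: the frame with most neighbours within the cutoff becomes a
cluster centre, it and its neighbours are removed, repeat. Ties are broken
toward the lowest frame index so the partition is deterministic; the tests
hold the implementation equal to an independently coded brute-force oracle
over hundreds of random instances. Each cluster's medoid is the member with
the lowest mean RMSD to the other members.

The ensemble order parameter is

O = Σᵢ wᵢ log₂[1 + Σⱼ wⱼ exp(−D²(sᵢ,sⱼ) / (2⟨D²⟩))]

over cluster representatives with weights wᵢ = cluster size / F. Three
notes:

* **⟨D²⟩ = 0.27 is taken on the nm² scale.** The literature value is often
  printed as "0.27 nm", dimensionally a distance, but the symbol enters the
  formula as a squared distance; the package uses 0.27 nm² and exposes
  `msd_scale` so either convention can be supplied explicitly.
* **D² uses per-pair optimal superposition** of the Cα coordinates by
  default (a no-refit flag exists), since the convention is rarely stated.
* **Closed forms anchor the implementation:** O = 1 exactly for a single
  conformation (and for duplicated representatives with split weights);
  O = log₂(1 + 1/n) for n equally weighted, mutually well-separated
  conformations; O → 0 as n → ∞. `order_parameter_uniform()` evaluates the
  exchangeable-geometry closed form without constructing an n x n matrix,
  which is how the acceptance script traces the limit to n = 10⁶.

`disorder_profile()` chains clustering → medoids → weights → O across a
cutoff list (clustering cutoffs are always explicit nm inputs). On genuinely
disordered synthetic ensembles nearly every frame is its own cluster and O
lands near log₂(1 + 1/n_clusters) — a direct, quantitative statement of
ensemble heterogeneity.

## Secondary structure

The Kabsch–Sander criterion is re-implemented rather than shelled out to a
DSSP binary: the analysis must run self-contained, and an in-package
implementation is testable atom by atom. The hydrogen-bond energy is
E = 0.084·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)·332 kcal/mol with a −0.5
kcal/mol call threshold; two consecutive n-turns (n = 3, 4, 5) open a helix
of class G/H/I with the DSSP priority H > G > I; turn-but-not-helix residues
are T and everything else C. β-structure is deliberately only bookkeeping —
helix content is what matters for this analysis. Amide hydrogens are always
reconstructed at 0.1 nm from N along the C(i−1)−O(i−1) direction. This is
the DSSP convention itself, chosen (over, e.g., an N-centred bisector
construction) so that the assignment agrees with every DSSP-family
implementation placement-for-placement; the test suite holds per-residue
agreement with an external reference implementation (mdtraj's DSSP, via the
pre-installed Python) at ≥ 95% on ideal α, 3₁₀ and extended constructs.

Helical-content summaries report per-class counts averaged and maximized
over frames, with the total helical percentage computed over the chain
length. The "maximum" columns are per-frame maxima over the subset, the
natural reading for an ensemble table.

## Solvent-accessible surface

Shrake–Rupley quadrature with a deterministic golden-spiral point set
(default 960 points, probe 0.14 nm; van der Waals radii C 0.17, N 0.155,
O 0.152, S 0.18, H 0.12 nm, pseudo-atoms carbon-like). Because a fixed
lab-frame point set makes the result weakly orientation-dependent, the
quadrature is evaluated in a canonical molecule-fixed frame (principal axes
with moment-fixed signs), which renders the surface invariant under rigid
motion to numerical precision — a property the tests assert directly, along
with 0.5% agreement with the isolated-sphere closed form and 1% agreement
with the exact two-sphere union area. The quadrature error decreases
monotonically from 240 to 3840 points. For per-basin tables the surface is
evaluated on an evenly-spaced frame subsample (default cap 30 frames per
basin); the SAS of a basin is a mean over frames, and subsampling changes it
well below the compact-versus-extended contrast of interest.

## Interaction networks

Contacts are detected per frame by class-specific criteria: salt bridges as
minimum distance between side-chain charged nitrogens (Lys NZ; Arg NE/NH1/
NH2) and carboxylate oxygens (Asp OD1/OD2; Glu OE1/OE2) within 0.5 nm, His
excluded by default but available; aromatics as ring-centroid distances
within 0.6 nm; amino-aromatic as charged-N-to-centroid within 0.6 nm (the
aromatic cutoff, since no separate value is established); hydrophobics as
minimum side-chain carbon distances within 0.5 nm between aliphatic/Phe
residues at sequence separation ≥ 2. No sequence-separation filter is
applied to salt bridges. Minimal topologies carrying one side-chain
reference atom per residue map that atom to the class groups by residue
type. Persistence is the exact rational count/F; the graph view thresholds
at 20% persistence, with hubs at degree ≥ 3 (the stricter "more than 3"
convention is one parameter away), components ordered by size, and simple
paths enumerated exhaustively in lexicographic node-sequence order with a
truncation flag. Hubs, components and paths run on `igraph`; the tests
validate all three against independent brute-force oracles (degree counts,
transitive closure, permutation enumeration) on every random graph of up to
8 nodes they draw.

## Charge-state distributions

Native ESI-MS of a conformationally heterogeneous protein yields a
multimodal charge-state distribution: compact conformers take up fewer
charges than extended ones, because ionization tracks the solvent-accessible
surface at transfer into the gas phase. The package fits
intensity-versus-charge profiles (after the m/z → z transformation) with
k = 1…4 Gaussians and selects the minimal number leading to a stable fit.
"Stable" is qualitative in the methodology, so it is operationalized with
three explicit, configurable requirements: adjacent component means must be
resolved by at least twice the wider sigma (distinct conformer modes — the
same separation regime the parameter-recovery tests use); every component
must carry at least 5% of the area; and residual-bootstrap refits from
neutral starting values must keep all means within 0.5 charge units in 80%
of replicates. An extra component must additionally improve the AIC by more
than a margin of 2. Unresolved or unstable mixtures never count as
improvements, which is what stops noise-level peak-splitting on 14-point
spectra. Flat profiles collapse to a single flagged component. The
charge-to-surface transform `SAS = a·z^b` requires explicit calibration
constants from published regressions; none are silently defaulted, because
the calibration is instrument- and study-specific.

## The synthetic generator

The generator exists so that every stage has planted ground truth. It
builds full-backbone chains (N, H, CA, C, O plus one side-chain reference
pseudo-atom per residue at a residue-type-specific distance along the ideal
CA→CB direction) from ideal internal coordinates; helical segments receive
ideal α-torsions (φ = −57°, ψ = −47°, 2° jitter) in a per-frame Bernoulli
fraction of frames; coil residues draw from a broad β/polyproline-II/α
mixture. Each frame is assigned to a state by weight and driven to that
state's target radius of gyration — `compactness x 0.22 N^0.38 nm`, the
globular scaling baseline — by greedy pivot moves on coil torsions, which
preserve all bond geometry exactly and move helices as rigid bodies (a
statistical stand-in for collapse, not a force field). Contact schedules
move side-chain reference atoms to 0.30 nm in scheduled frames and keep them
beyond 0.7 nm otherwise; only residue pairs that could register in the same
interaction class are background-separated, so one residue can hold several
planted partners (hub geometry). Coordinate noise is 0.002 nm by default —
small enough that planted helices stay assignable (≥ 90% of occupied frames)
and planted persistences are recovered exactly.

What the generator does **not** emulate: solvent, force-field energetics,
realistic kinetics or inter-frame correlation (frames are independent
draws), side-chain rotamers, or the sequence of any particular protein (the
default 70-residue sequence is a deterministic charge-rich IDP-like
pattern). Passing tests therefore demonstrate correctness of the analysis
chain on ensembles with the right statistical structure — state mixtures,
occupancy schedules, contact persistence — not agreement with any specific
experimental system. Headline numbers from MD studies of real proteins
(order parameters near 0.15 on hundreds of nanoseconds of trajectory,
per-basin SAS tables) depend on trajectories that are not distributable and
are deliberately not asserted anywhere in the package.

## Problem sizes

The shipped tests run ensembles of 10–500 frames and 20–70 residues,
10⁴-sample landscape surfaces, 200 random clustering instances, 500 random
graphs, 50 seeded spectra and a 10-seed end-to-end sweep — sizes chosen so
the full suite completes in a few minutes while every assertion retains the
statistical power it needs. The same functions run unchanged on
hundreds-of-thousands-of-frame trajectories; the pairwise RMSD matrix
(O(F²) Kabsch fits) is then the dominant cost, and per-basin SAS subsampling
becomes essential.

## Known limitations

* Basin boundaries on a histogram landscape are grid-resolution-dependent;
  labels are deterministic given the surface but not comparable across bin
  counts.
* The Kabsch–Sander re-implementation covers helix/turn/coil; strand and
  bridge classes are folded into coil.
* Gromos clustering is O(F²) in memory through the RMSD matrix.
* The CSD fitter assumes an integer charge axis and well-formed relative
  intensities; it does not pick peaks from raw m/z spectra.
* `plant_contacts()` resolves conflicting schedules iteratively; heavily
  over-constrained schedules (many pairs sharing residues in crowded compact
  frames) may realize persistences a few counts below target, though the
  0.5 nm detection cutoff absorbs this in practice.
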