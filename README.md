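# idpens

Characterization of intrinsically disordered protein (IDP) conformational
ensembles in R.

Unbound IDPs are not random coils: they transiently populate helical
elements and collapsed, globular conformations stabilized by networks of
intramolecular interactions. `idpens` implements the standard analysis chain
used to dissect such heterogeneous ensembles — whether they come from
molecular-dynamics trajectories (multi-model PDB input) or from the package's
own ground-truth synthetic generator — and the complementary mass-spectrometry
view of the same conformational equilibrium. It is aimed at computational
structural biologists who need a tested, scriptable version of this pipeline
rather than a chain of one-off tools.

## What it computes

* **Essential dynamics.** PCA of the (optionally mass-weighted) covariance
  matrix *C* of atomic positional fluctuations after least-squares
  superposition; projections of frames on the leading eigenvectors; cumulative
  explained variance; and the subspace overlap
  RMSIP = √[(1/D) Σᵢ Σⱼ (ηᵢᴬ·ηⱼᴮ)²] between replicate trajectories
  (1 = identical essential subspaces, 0 = orthogonal).
* **Free-energy landscapes.** G(q) = −kT ln P(q) over two reaction
  coordinates (e.g. PC1/PC2, or a PC against the solvent-accessible surface),
  with algorithmic basin decomposition: steepest-descent assignment of
  populated histogram bins, merging of shallow minima, deterministic labels
  A, B, C… by increasing minimum G, and per-frame basin membership.
* **Ensemble heterogeneity.** Gromos clustering (greedy neighbour-count on
  the pairwise RMSD matrix at a fixed cutoff) and the Fisher–Stultz order
  parameter
  O = Σᵢ wᵢ log₂[1 + Σⱼ wⱼ exp(−D²(sᵢ,sⱼ)/(2⟨D²⟩))],
  where D² is the pairwise Cα mean-square distance between cluster
  representatives, wᵢ the relative cluster sizes and ⟨D²⟩ = 0.27 nm² the
  fluctuation scale of a typical folded protein. O = 1 for a single
  conformation; O → 0 for an infinitely heterogeneous ensemble.
* **Structure metrics.** Kabsch–Sander (DSSP) hydrogen-bond secondary
  structure re-implemented in-package (helix classes α/3₁₀/π), per-residue
  persistence profiles, and Shrake–Rupley solvent-accessible surface with a
  deterministic, rigid-motion-invariant quadrature.
* **Interaction networks.** Per-frame detection of salt-bridge, aromatic,
  amino-aromatic and hydrophobic contacts; persistence matrices (exact
  fractions of frames); persistence-weighted residue graphs with hubs
  (degree ≥ 3), connected components and exhaustive simple-path enumeration.
* **Native ESI-MS charge-state distributions.** Gaussian deconvolution of
  intensity-versus-charge profiles into the minimal stable number of
  conformer components, their relative abundances, and a calibrated
  charge-to-surface transform.
* **Synthetic ensembles with known ground truth.** Chains built from ideal
  internal coordinates with plantable helical segments, compact/extended
  state mixtures (pivot-move compaction to target radii of gyration) and
  contact schedules with exact target persistence — so every downstream
  stage is testable without reference trajectories.

## Worked example

Generate a two-state (compact/extended) 70-residue ensemble, plant three
salt bridges around one hub residue in the compact frames, and run the full
pipeline:

```r
library(idpens)

syn <- generate_ensemble(ensemble_spec(n_frames = 80, seed = 1))
top  <- syn$ensemble$topology
rids <- unique(top$residue_ids)
rn   <- top$residue_names[match(rids, top$residue_ids)]
basic  <- rids[rn %in% c("LYS", "ARG")]
acidic <- rids[rn %in% c("ASP", "GLU")]

sched <- contact_schedule(data.frame(i = basic[c(1, 1, 1)], j = acidic[1:3]),
                          mode = "mask",
                          masks = rep(list(syn$state == "compact"), 3))
ens <- plant_contacts(syn$ensemble, sched)$ensemble

report <- run_full_analysis(ens, analysis_config(fel_bins = c(8, 8),
                                                 cluster_cutoffs = c(0.4, 0.5),
                                                 sas_n_points = 240,
                                                 sas_max_frames_per_basin = 12))
report
```

```
Ensemble analysis report
  frames: 80   basins: 3 (3 analyzed)
  disorder profile:
 cutoff n_clusters          O
    0.4         80 0.06313059
    0.5         80 0.06313059
  per-basin structure:
 basin n_frames total_helical_pct sas_mean
     A       39          20.40293 46.86142
     B       34          14.87395 72.97747
     C        7          15.71429 75.72990
  hub residues per basin: A:1  B:0  C:0
```

Basin A collects the 39 compact frames: it has the lowest mean
solvent-accessible surface (46.9 nm² vs ≈ 73 nm² for the extended basins),
the highest helical content, and it alone contains a salt-bridge hub — the
planted residue holding three simultaneous partners. The order parameter
O ≈ 0.06 at both clustering cutoffs says that every frame is its own cluster:
a maximally heterogeneous, disordered ensemble.

Deconvolving a bimodal native ESI-MS charge-state distribution (planted
30/70 mixture of a low-charge compact and a high-charge extended conformer):

```r
g   <- generate_csd(csd_spec(data.frame(mean = c(7, 10), sigma = c(0.8, 1.0),
                                        area = c(0.3, 0.7)),
                             z_range = c(3, 16), noise_sigma = 0.02, seed = 11))
fit_csd(g$csd)
```

```
CSD deconvolution: 2 component(s)
  mean z = 6.99, sigma = 0.77, fraction = 0.292
  mean z = 9.98, sigma = 1.00, fraction = 0.708
```

The fit selects two components and recovers the planted means and
abundances; the low-charge component (z̄ ≈ 7, ~29%) is the compact
conformer.

## Package layout

* `R/ensemble.R`, `R/ensemble-io.R` — ensemble containers, multi-model PDB
  I/O, concatenation, superposition, pairwise RMSD.
* `R/synthetic-ensemble.R` — the ground-truth ensemble/contact generator
  (the charge-state-distribution generator lives beside its fitter in
  `R/csd-ms.R`).
* `R/essential-dynamics.R`, `R/landscape.R`, `R/heterogeneity.R`,
  `R/structure-metrics.R`, `R/networks.R`, `R/csd-ms.R` — the analysis
  stages.
* `R/pipeline.R` — `run_full_analysis()` orchestration with provenance
  logging and delimited-text export.
* `vignettes/ensemble-characterization.Rmd` — the methods notes: model
  assumptions, parameter choices, numerical decisions and limitations.
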