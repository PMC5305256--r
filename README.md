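# cryodyn

Comparative conformational dynamics of cold- and warm-adapted enzyme
homologs, in R.

Cold-adapted (psychrophilic) enzymes keep working at temperatures where
their warm-adapted (mesophilic) homologs slow down, and one candidate
mechanism is altered conformational flexibility.  Deciding whether a
given homolog pair — the motivating case is the periplasmic,
Mg²⁺-dependent endonucleases of marine *Vibrionaceae*, ~71 % identical
in sequence and nearly superimposable as crystal structures — actually
differs in dynamics requires comparing conformational *ensembles*, not
static structures.  `cryodyn` implements that workflow for
computational biochemists:

* **Flexibility profiling** — fitted RMSD / radius-of-gyration /
  ion-distance time series; windowed, replicate-averaged per-residue
  Cα RMSF with across-replicate uncertainty bands; per-residue
  difference profiles between homologs (insertions reported as explicit
  gaps); the covariance trace tr(C) of the 3N×3N Cα covariance as a
  scalar overall-flexibility metric.
* **Ensemble-sampling similarity** — PCA of Cα fluctuations and the
  root mean square inner product over the first D = 10 components,
  RMSIP = √((1/D) ΣᵢΣⱼ (vᵢ·wⱼ)²) ∈ [0, 1];
  clustering-based ensemble similarity (CES: affinity propagation on
  the pooled pairwise fitted Cα-RMSD matrix, preference −10, then the
  Jensen–Shannon divergence between per-ensemble cluster populations);
  dimensionality-reduction-based ensemble similarity (DRES: stochastic
  proximity embedding into 6 dimensions, Gaussian KDE, Monte-Carlo JSD).
  JSD uses natural log: 0 = identical ensembles, ln 2 ≈ 0.69 =
  non-overlapping.  Outlier replicates are flagged by mean off-diagonal
  JSD, never silently dropped.
* **Protein structure networks** — residues as nodes, persistence-
  weighted edges per interaction class: hydrophobic (side-chain
  centre-of-mass < 0.65 nm), hydrogen bond (donor–acceptor ≤ 0.35 nm and
  donor-H-acceptor angle > 120°), salt bridge (charged-group
  centre-of-mass < 0.45 nm); hubs (degree ≥ 5), connected interaction
  clusters, and differential edges between two systems, exported as
  GraphML + TSV.
* **Sequence-level adaptation signal** — amino-acid composition deltas
  between the two targets, and classification of every substitution
  site into *candidate* (both temperature groups conserved on different
  residues) vs *drift* (shared or heterogeneous patterns) using a
  temperature-labeled multiple sequence alignment.
* **Synthetic-data generators** with analytically known ground truth
  (harmonic ensembles, multi-basin mixtures, planted-contact peptides,
  planted alignments), so every stage has a parameter-recovery test
  without access to molecular-dynamics trajectories.

All coordinates are nm, times ns; ensembles are read/written as
multi-model PDB through `bio3d`.

## Worked example

Two ensembles confined to disjoint conformational basins, one 50/50
mixture, and their clustering-based similarity:

```r
library(cryodyn)

base <- make_ca_structure(10)                       # helical C-alpha toy
refs <- make_basin_references(base, n_basins = 2, separation = 5, seed = 3)
spec <- basin_spec(refs, list(c(1, 0), c(0, 1), c(0.5, 0.5)),
                   intra_basin_sigma = 0.05, min_separation = 5,
                   n_frames = 500, seed = 7)
ens_a   <- gen_basin_mixture(spec, 1)   # all frames in basin 1
ens_b   <- gen_basin_mixture(spec, 2)   # all frames in basin 2
ens_mix <- gen_basin_mixture(spec, 3)   # 50/50 mixture

ces(list(ens_a, ens_b, ens_mix))
#> similarity_matrix (ces_jsd), 3 replicates
#>        ens1   ens2   ens3
#> ens1 0.0000 0.6931 0.2191
#> ens2 0.6931 0.0000 0.2125
#> ens3 0.2191 0.2125 0.0000

fit   <- superpose_frames(ens_a, ens_a$xyz[1, ])
basis <- pca_ensemble(fit)
rmsip(basis, basis)                      # a basis against itself
#> [1] 1

prof <- windowed_rmsf(ens_a, window_ns = 100, exclude_initial_ns = 100)
sprintf("mean C-alpha RMSF: %.4f nm over %d windows",
        mean(prof$rmsf_mean), attr(prof, "n_windows"))
#> [1] "mean C-alpha RMSF: 0.0774 nm over 4 windows"
```

Reading the numbers: the disjoint pair sits at the JSD ceiling
ln 2 = 0.6931 (non-overlapping ensembles), the mixture sits near the
closed-form JSD((1,0), (½,½)) = 0.2158 against either pure basin, and an
essential subspace compared with itself gives RMSIP exactly 1.  The RMSF
of a basin-confined ensemble reflects its 0.05 nm/coordinate jitter
(≈ 0.05·√3 after fitting).

## The analysis workflow

`analysis/` contains numbered drivers that run the full comparative
study on a synthetic two-system set (two systems × four replicates, one
replicate per system planted in a different basin, plus a labeled
alignment with three planted candidate columns):

```sh
Rscript analysis/01_simulate_systems.R      # data + pipeline config
Rscript analysis/02_sampling_similarity.R   # RMSIP/CES/DRES + outlier flags
Rscript analysis/03_flexibility.R           # windowed RMSF, differences, traces
Rscript analysis/04_structure_networks.R    # PSNs, hubs, clusters, diffs
Rscript analysis/05_sequence_adaptation.R   # composition + candidate/drift
Rscript analysis/06_full_pipeline.R         # same via run_pipeline() + report
```

Each step prints what it found (e.g. step 2 flags `rep1` in both
systems as a sampling outlier; step 5 recovers exactly the three planted
candidate columns) and writes its tables under `results/`.

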