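---
title: "Comparative conformational dynamics of thermally adapted enzyme pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative conformational dynamics of thermally adapted enzyme pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Enzymes from cold-living (psychrophilic) organisms stay catalytically
active at temperatures where their warm-adapted (mesophilic) homologs
slow down, usually by lowering the activation enthalpy at the cost of a
more negative activation entropy.  A long-standing hypothesis ties this
to increased conformational flexibility, locally near the active site or
globally.  Testing it for a specific homolog pair — here the periplasmic,
non-specific, Mg²⁺-dependent endonucleases of marine *Vibrionaceae*,
whose cold- and warm-adapted variants share about 71 % sequence identity
and nearly identical crystal structures — requires going beyond static
structures: one compares conformational *ensembles* (molecular-dynamics
replicates), their per-residue fluctuations, their noncovalent
interaction networks, and the substitution patterns in temperature-labeled
homolog alignments.

`cryodyn` implements that comparative workflow as a tested, reusable R
package.  Because the trajectories behind such studies are rarely
deposited, the package also ships generators for synthetic ensembles and
alignments with *known* ground truth, so every analysis stage has a
parameter-recovery test that runs at desk scale.  The `analysis/`
scripts in the repository run the complete workflow on such a synthetic
two-system study set.

## Data model and units

Coordinates are stored in nm internally (the interaction cutoffs below
are quoted in nm); PDB files are converted from/to Ångström at the I/O
boundary.  Times are in ns.  A `structure_model` holds an ordered atom
table plus one conformation; an `ensemble` holds a topology and an
ordered frame set with a fixed time step; a `replicate_set` groups
replicates of one system.  Residues are indexed 1-based internally (the
natural R convention) and every user-facing output goes through a
*numbering map* carrying reference residue labels — for real structures
the author/PDB numbering including insertion codes (e.g. "52A"), which is
how positions are reported when comparing homologs against a reference
structure's numbering convention.

Ensembles are read and written as multi-model PDB.  Binary trajectory
formats are deliberately out of scope: a text format keeps fixtures
reviewable and the readers testable; converting a real trajectory to
multi-model PDB is a one-liner in any MD toolchain.  Alternate locations
other than blank/'A' are dropped (with a warning) so the topology is
deterministic.  Whether to keep or remove crystallographic ions (e.g. a
weakly contacting chloride) is left to the user's input preparation, not
hard-coded.

## Flexibility profiling

`rmsd_series()`, `radius_of_gyration_series()` and `distance_monitor()`
are the standard trajectory-stability descriptors (least-squares-fitted
RMSD to a starting structure, mass-weighted Rg, ion-coordination
distances).  The central quantity is the windowed RMSF
(`windowed_rmsf()`): Cα fluctuations are computed over non-overlapping
time windows (default 10 ns) after discarding an initial span (default
10 ns), averaged over windows, then averaged across replicates
(`average_profiles()`).  Windowing measures fluctuations on a fixed
timescale rather than about one global mean, which is what makes
profiles comparable between systems with different slow drift.

Two conventions are underdetermined in this protocol and fixed here
explicitly:

* **Per-window fitting reference.**  Frames of each window are fitted to
  the window-mean structure (one fit-recompute iteration), and RMSF is
  taken about that mean.  Fitting to the window mean rather than the
  global start removes rigid-body drift per window; the choice is
  documented because it slightly affects absolute values.
* **The uncertainty band.**  `windowed_rmsf()` reports the across-window
  standard deviation for a single replicate; `average_profiles()`
  replaces it with the across-replicate standard deviation, which is the
  band shown when comparing systems.

Least-squares fitting absorbs six rigid-body degrees of freedom, so the
RMSF of pure isotropic noise of sd σ per coordinate converges to
σ√3·√(1−6/3N) rather than σ√3 exactly; at the problem sizes used in the
tests (≥ 40 residues) this is a ≤ 2 % effect, well inside the 5 %
tolerance asserted there.  Mass weighting: Rg is mass-weighted; RMSD and
RMSF are unweighted over their selection (conventional defaults, stated
because protocols differ).

`covariance_trace()` sums the variances of the fitted Cα coordinates —
the trace of the 3N×3N covariance matrix, a scalar overall-flexibility
metric.  The trace is basis-invariant, so it equals the sum of the PCA
eigenvalues of the same data; the test suite asserts that identity to
1e-9, which pins the covariance conventions of both modules to each
other.

`rmsf_difference()` aligns two profiles by residue label (optionally via
an explicit cross-system map) and reports per-residue differences;
positions present in only one homolog (insertions) are emitted as gap
rows, never silently dropped — length differences between homologs are
themselves signal.

## Ensemble-sampling similarity

Three measures quantify whether replicates sample the same conformational
space:

**RMSIP.**  With `v` and `w` the first D eigenvectors of the Cα
covariance matrices of two ensembles (default D = 10),

    RMSIP = sqrt( (1/D) Σᵢ Σⱼ (vᵢ·wⱼ)² )

ranges from 0 (orthogonal essential subspaces) to 1 (identical
subspaces).  It is invariant to eigenvector sign flips and symmetric in
its arguments, and a basis against itself gives exactly 1 (the last-bit
rounding of the double sum is absorbed so that the identity is exact).

**CES** (clustering-based ensemble similarity).  All frames are pooled,
the all-vs-all pairwise least-squares-fitted Cα RMSD matrix is clustered
by affinity propagation with similarity = −RMSD, and each ensemble
becomes a probability vector over clusters (the fraction of its frames
per cluster).  The score is the Jensen–Shannon divergence (natural log)
between those vectors: 0 for identical distributions, ln 2 ≈ 0.693 for
non-overlapping ones.  Affinity propagation parameters: preference −10
(in the negative-nm similarity units; the value is configurable because
its original units are tool-internal), damping 0.9, at most 1000
iterations, convergence when the exemplar set is stable for 50 sweeps.
One degeneracy is handled explicitly: if the pooled data contain
duplicated conformations (e.g. an ensemble compared against a copy of
itself), affinity propagation can elect *both* twins of a frame as
exemplars, producing coincident cluster pairs that split duplicates
arbitrarily and inflate the divergence.  Clusters whose exemplars lie
within 1e-6 nm RMSD are therefore merged after clustering.  The reported
value always equals the closed-form discrete JSD of the population
vectors — an identity the tests assert to 1e-12 on every run.

**DRES** (dimensionality-reduction-based ensemble similarity).  The same
pooled RMSD matrix is embedded into 6 dimensions by stochastic proximity
embedding (SPE): random pair updates move embedded points toward their
target dissimilarity, with the learning rate annealed 2.0 → 0.01 and the
neighbourhood radius annealed from the maximum pooled RMSD down to its
1st percentile over 200 cycles of 50·n updates.  Each ensemble's density
in the embedded space is a Gaussian kernel density estimate (per-dimension
Scott's-rule bandwidth), and the JSD between densities is estimated by
Monte-Carlo sampling (10⁴ draws per density per pair), clipped to
[0, ln 2].  The estimator is stochastic; with the seed fixed it is exactly
reproducible.  The SPE schedule is deliberately long enough that
duplicated frames embed at coincident points: the identical-ensemble
endpoint then lands below 0.05 rather than at an estimator-biased
plateau.  KDE (rather than cluster-free resampling) was chosen for the
density estimate because it is the standard, parameter-light choice; the
bandwidth rule is recorded in this vignette so results are reproducible.

For the O(n²) RMSD matrix a frame stride is applied by default so the
pool holds at most 3000 frames.  Replicates whose mean off-diagonal JSD
exceeds a configurable threshold (default 0.4 in the pipeline) are
*flagged* as sampling outliers — the decision to exclude them from
further averaging is reported, never taken silently.

## Protein structure networks

Residues are nodes; noncovalent interactions are edges; the edge weight
is the interaction's *persistence*, the fraction of frames in which its
geometric criterion holds.  Classes are analysed separately:

| class | criterion | convention |
|---|---|---|
| hydrophobic | side-chain heavy-atom centre-of-mass distance < 0.65 nm | residue set ALA/VAL/LEU/ILE/MET/PHE/TRP/PRO, configurable; side-chain (not whole-residue) centre by default |
| hydrogen bond | donor–acceptor distance ≤ 0.35 nm AND donor-H-acceptor angle > 120° | standard backbone N–H/C=O plus side-chain N/O donors and acceptors; subtype recorded (mainchain–mainchain/–sidechain/sidechain–sidechain) |
| salt bridge | charged-group centre-of-mass distance < 0.45 nm | ASP/GLU carboxylate vs LYS ammonium/ARG guanidinium; HIS excluded by default (protonation unknown) |

"Below"/"lower than" are strict (<); the hydrogen-bond distance is read
as ≤.  Residue pairs adjacent in sequence (|i−j| < 2) are excluded so
trivially persistent covalent-neighbour contacts do not dominate.  When
the topology carries no hydrogens, hydrogen-bond detection refuses to run
unless `infer_hydrogens = TRUE`, which places a donor hydrogen 0.1 nm
toward the acceptor — a coarse stand-in suitable for rotatable donors
only, and flagged in the output.  Edges with persistence ≥ the threshold
(default 0.2 — a documented, configurable choice, as published analyses
rarely state theirs) are retained.

Hubs are nodes connected by more than four edges (degree ≥ 5);
interaction clusters are the connected components of the filtered graph.
`diff_networks()` partitions mapped edges of two systems into
only-in-A / only-in-B / shared (with both persistences); edges touching
residues outside the cross-system map land in an explicit `unmapped`
bucket.  For hydrogen-bond networks the mainchain–mainchain subtype can
be excluded before counting, the usual convention when tallying
polar/electrostatic differences between homologs.  Nothing beyond
connected components (no shortest-path or community analysis) is
computed: the comparison is about which interactions exist and how
persistent they are.

## Sequence-level adaptation signal

Comparing just the two target sequences confounds adaptation with
genetic drift.  The classifier therefore uses the full labeled alignment:
at every column where the targets differ, the cold group (psychrophilic +
psychrotolerant, pooled by default — the two classes are ecologically
contiguous; a flag keeps them separate) and the mesophilic group are
summarised by their modal residue and its frequency among non-gaps.
A substitution is a **candidate** when both groups are conserved (modal
frequency ≥ 0.8 by default) on *different* residues and each target
matches its own group; **drift** when the groups share the modal residue
or the mesophilic group is heterogeneous; **indeterminate** otherwise
(including when the only group members are the targets themselves).
Raising the conservation cutoff can only move verdicts away from
candidate, never toward it — a monotonicity the tests assert.  An
optional grouped mode treats physicochemically similar residues
(V/I/L/M, S/T, D/E, K/R, F/Y/W, N/Q) as one conserved pattern, mirroring
how curators accept "a valine or isoleucine here" as conservation;
exact-residue matching is the default because it is the stricter, more
reproducible convention.

`composition_delta()` counts residues over the ungapped targets and
reports signed differences plus grouped summaries over a documented
class table (positives K/R/H, negatives D/E, polar S/T/N/Q/C/Y/W/H,
hydrophobic A/V/L/I/M/F/W/P, aromatic F/Y/W, glycine, proline; classes
overlap where chemistry does).  `pairwise_identity()` divides identical
non-gap positions by all columns carrying at least one residue (gap-gap
columns excluded; indels count as mismatches); a `denominator = "both"`
mode restricts to doubly occupied columns.

## Synthetic data: what it emulates and what it does not

The generators are first-class, tested code, and they define the study
conditions for every acceptance check:

* `gen_harmonic_ensemble()` draws Gaussian fluctuations about a reference
  along prescribed orthonormal modes plus isotropic noise.  Expected
  per-residue RMSF and covariance trace are known in closed form
  (E[RMSF] = σ√3 for pure isotropic noise; trace → Σa² + 3Nσ²), giving
  exact convergence targets at 5000 frames / 5 % tolerance.
* `gen_basin_mixture()` draws frames from well-separated reference
  conformations with prescribed mixture weights plus jitter.  Separation
  is enforced in *fitted* RMSD (a translation would be removed by the
  fit), via `make_basin_references()`.  With separation ≫ jitter the
  clusters found by CES coincide with the basins, so cluster populations
  recover the planted weights up to binomial error, and the
  identical/disjoint endpoints (0 and ln 2) are reached exactly.
  The ensemble-similarity acceptance checks use 500–1000 frames per
  ensemble, 10-residue topologies, 5 nm separation and 0.05 nm jitter.
* `gen_contact_peptide()` builds a three-residue toy peptide from
  idealized geometry in which one planted interaction's criterion holds
  in *exactly* round(p·n) frames (the partner group is displaced beyond
  the cutoff in the remaining frames, chosen by a seeded shuffle).
  Persistence recovery is therefore an exact test, not a statistical one.
* `gen_labeled_alignment()` plants candidate columns (each group fixed on
  a different residue), drift columns (targets differ, mesophilic group
  heterogeneous) and identical background columns, so classifier
  precision and recall are exactly 1 by construction.

Every generator is a pure function of its specification and seed (one
seeded stream per call, no global RNG state leaks).

What the synthetic data does **not** emulate: real protein energetics,
anharmonic and multi-timescale dynamics, correlated side-chain packing,
solvent, or the phylogenetic correlation structure of real alignments.
Passing the recovery tests shows the *estimators* are correct and the
criteria implemented as stated; it does not certify that any real enzyme
pair shows a particular flexibility difference.  In particular,
MD-derived quantities reported for real endonuclease pairs (interaction
counts, covariance traces, specific hubs, RMSF peaks of a few
hundredths of a nm) depend on microsecond trajectories that are not
redistributable and are therefore outside what this package can or does
reproduce.

## Numerical choices and degenerate inputs

* Pairwise fitted RMSD uses a closed-form Kabsch kernel (singular values
  of the 3×3 cross-covariance, with the reflection sign handled); it is
  cross-checked in the tests against an independently implemented
  quaternion (Horn) oracle and against bio3d's fitting.
* PCA of a constant trajectory returns all-zero eigenvalues, not an
  error; covariance of a single frame *is* an error (variance undefined).
* Superposition requires ≥ 3 non-collinear selected atoms; the synthetic
  Cα topologies are laid out on an ideal helix (0.15 nm rise, 0.23 nm
  radius, 100°/residue — the canonical ~0.38 nm Cα–Cα spacing) precisely
  so that fits are well posed.
* JSD uses natural log throughout (bound ln 2); probability vectors are
  validated to sum to 1; 0·log 0 = 0.
* KDE bandwidths require non-degenerate spread in every embedded
  dimension; all-identical points raise an error suggesting jitter.
* Windows are converted from ns to whole frame counts by floor; trailing
  partial windows are discarded; "no complete window" is an error that
  states the required length.
* The pipeline config is a versioned YAML schema in which unknown keys
  are errors, not warnings — a typo in a stage parameter must not
  silently run the comparison with defaults.  Every artifact carries the
  config hash and seed.

## Problem sizes

The test suite and the acceptance script run on deliberately small
problems: 10–50-residue Cα topologies, 100–5000 frames, alignments of
≤ 15 sequences × ≤ 120 columns.  These sizes are where the closed forms
and planted constructions above are sharp (binomial bounds, 5 %
convergence tolerances) while the whole suite stays interactive; the
statistics being checked are size-free identities or convergence rates,
so nothing about the implementation is specific to these sizes.

## Known limitations

* Multi-model PDB is the only trajectory format; no XTC/DCD readers.
* Hydrogen inference is geometric and crude; for real hydrogen-bond
  networks, supply a topology with explicit hydrogens.
* DRES inherits the bias of Monte-Carlo JSD between KDEs: values very
  close to 0 are reported as small positive numbers; the identical-copy
  endpoint is asserted only to < 0.05.
* Affinity propagation is O(n²) per sweep in the pooled frame count;
  the default stride caps the pool at 3000 frames.
* The sequence classifier assumes the alignment is given (computed
  externally); it performs no alignment, no database search, and no
  growth-temperature inference — labels are user-supplied curation.
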