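---
title: "Measuring protein stability from MD trajectories with protdyn"
author: "protdyn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein stability from MD trajectories with protdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protdyn)
```

## The problem

When an enzyme is characterized for industrial use — a thermostable,
acid-resistant glucose 1-dehydrogenase intended for NAD(P)H cofactor
regeneration is the motivating case — the biochemical assays are usually
complemented by a molecular dynamics (MD) simulation of the modelled
structure. The simulation answers a question the wet lab cannot: *does the
fold stay put at the working temperature, and where is it flexible?* The
answer is read off a standard panel of descriptors:

* **RMSD** of all atoms and of the backbone against the starting
  structure, as a function of time — global drift and equilibration;
* **radius of gyration** — compactness;
* **intra-protein hydrogen-bond counts** under a geometric criterion —
  cohesion of the fold;
* **solvent-accessible surface area** (SASA) — packing/unfolding;
* **per-residue RMSF**, converted to crystallographic **B-factors** —
  which residues move;
* **Lipari–Szabo order parameters S²** of the backbone amide N–H
  vectors — bond-level restriction of ps–ns motion;
* **essential dynamics** (PCA of the Cα covariance matrix) — whether the
  motion is concentrated in a few collective modes.

protdyn computes this panel from a trajectory stored as a multi-model PDB
file, and fits the Michaelis–Menten constants that anchor the kinetics
side of such a study. Every estimator ships with a synthetic generator
whose ground truth is known in closed form, so the package can prove its
own correctness by parameter recovery rather than by comparison against a
reference trajectory that may not be available.

## Models and estimators

### Superposition

All descriptors that compare frames first remove global rotation and
translation with a Kabsch least-squares fit (`kabschFit()`): the 3×3
cross-covariance of the centered point sets is decomposed by SVD and the
reflection branch is corrected so the rotation is always proper. The fit
can be mass-weighted (the default for RMSD fitting, matching common MD
tool conventions); the RMSD *measurement* is always unweighted. Because
the underlying simulation packages differ on both conventions and the
original analyses rarely state them, both are exposed as arguments rather
than hard-wired.

Fluctuation-type analyses (RMSF, S², essential dynamics) superpose onto
the *iterated mean structure*: frames are fitted to the first window
frame, averaged, refitted to that average, and averaged again (two passes
by default). Fitting to the mean is what "fluctuation about ⟨r⟩" means;
referencing frame 1 instead inflates RMSF by the displacement of frame 1
from the mean. The same superposition pass is shared across the three
analyses inside `runPipeline()`, which makes the algebraic cross-checks
below hold to machine precision rather than approximately.

### RMSF and B-factors

RMSF per residue is `sqrt(mean |r - <r>|^2)` over the window for the Cα
atom. The crystallographic conversion is the isotropic harmonic relation

$$B = \frac{8\pi^2}{3}\,\mathrm{RMSF}^2,$$

applied with RMSF in Å (the package stores nm and converts), giving B in
Å². The mapping is exactly invertible (`rmsfFromBfactor()`), which the
tests exploit as a round-trip identity.

### Hydrogen bonds

A bond is counted when the donor–acceptor distance is ≤ 0.35 nm **and**
the hydrogen–donor–acceptor angle, measured at the donor, is ≤ 30°.
Donors and acceptors are nitrogen and oxygen only; a donor must carry an
attached hydrogen, and the criterion is explicitly hydrogen-dependent —
a polar topology without hydrogens is an error, not a zero. The angle
convention matters: several tools use the donor–H–acceptor angle instead,
and the two are not interchangeable. Heavy-atom pairs closer than 0.17 nm
are treated as covalently bonded and never scored. Detection uses a
cubic cell list at the cutoff length; the test suite proves the cell-list
path identical to a brute-force all-pairs scan on random polar systems.

### SASA

Shrake–Rupley rejection sampling: each atom is covered with a
deterministic Fibonacci lattice of 960 points (no RNG, so results are
exactly reproducible) at radius r_vdW + probe, and the accessible
fraction is the share of points inside no neighbouring expanded sphere.
The probe is 0.14 nm (water); radii are the Bondi set. Neither parameter
is dictated by the descriptors' definitions, so both are explicit,
documented defaults. At 960 points the total for a small helix agrees
with its own 10,000-point refinement to better than 1%, and with an
independent implementation (identical radii) to ~0.2%. Note the residual
lattice anisotropy: rotating a structure moves the burial pattern across
lattice points, so rotation invariance holds only to ~0.5% at the default
resolution, while translation invariance is exact.

### Order parameters

For each amide, unit bond vectors u = (r_H − r_N)/|·| are collected over
the superposed window and scored with the ensemble second-moment
estimator

$$S^2 = \tfrac{3}{2}\left(\langle u_x^2\rangle^2 + \langle u_y^2\rangle^2 +
\langle u_z^2\rangle^2 + 2\langle u_x u_y\rangle^2 +
2\langle u_x u_z\rangle^2 + 2\langle u_y u_z\rangle^2\right) - \tfrac{1}{2},$$

the infinite-sampling plateau of the P₂ orientational autocorrelation
function. S² = 1 means a rigid bond vector; 0 means isotropic disorder.
The autocorrelation-plateau estimator is also provided
(`s2AutocorrelationPlateau()`) but only as a validation mode: on finite
stationary samples the two converge to the same value, and the
second-moment form is the exact closed form of that limit. Prolines and
chain N-termini have no amide hydrogen and are excluded, following NMR
practice. Profiles are reported per chain; `s2Summary()` gives the
across-residue mean and region means.

The diffusion-in-a-cone generator is the ground truth here: vectors drawn
uniformly within a cone of semi-angle θ₀ have exactly
S² = [cos θ₀ (1 + cos θ₀)/2]², which the estimator recovers at five
angles spanning rigid to isotropic.

### Essential dynamics

The covariance of the concatenated Cα coordinates (3N-dimensional) is
computed over the superposed window with 1/F normalization, so that
trace(C) = Σ RMSF² exactly. `eigenDecompose()` returns descending
eigenvalues, orthonormal eigenvectors with a deterministic sign
convention (largest-magnitude component positive — projections are then
reproducible across runs and platforms), per-mode variance fractions and
their cumulative sum. Projections of the trajectory onto mode i have
population variance equal to λᵢ and are mutually uncorrelated — both
identities are asserted at 1e-9 in the tests. The per-residue
cross-correlation map normalizes ⟨Δrᵢ·Δrⱼ⟩ by the residue variances; a
zero-variance residue would make that undefined, so its row and column
are set to 0 (unit diagonal) with a warning. Covariance is unweighted:
all Cα masses are equal, so weighting would only rescale.

The cumulative-variance report (`cumulativeVarianceReport()`) is the
machinery used to judge essential-subspace dimensionality (e.g. the
fractions at 2 and 20 modes). Those percentages are properties of a
specific trajectory; with no deposited trajectory to load, the package
validates the machinery on constructed cases (flat spectrum, rank-1, a
single dominant collective mode) rather than claiming the study's
figures.

### Kinetics

`fitMichaelisMenten()` fits v = Vmax[S]/(Km+[S]) by unweighted
Levenberg–Marquardt least squares (via minpack.lm), with the standard
initial guesses Vmax₀ = max(v) and Km₀ = [S] at the observation nearest
Vmax₀/2, and standard errors from the Jacobian at the optimum.
Weighted or robust variants are deliberately omitted: initial-rate
triplicates are conventionally fitted unweighted. kcat = Vmax/[E] is
computed **per subunit** — for an oligomer, [E] must be the monomer
concentration — and kcat/Km is the catalytic efficiency. A fit needs at
least four distinct substrate concentrations; fewer is an error, not a
warning.

## The synthetic generators, and what they do not emulate

`generateReferenceStructure()` builds a poly-alanine helix (five atoms
N, H, CA, C, O per residue, N–H = 0.10 nm) with its amide hydrogens
aimed at the i−4 carbonyl oxygens, one helix per chain on a 3 nm grid.
It is deliberately idealized: the downstream statistics depend only on
named atoms, masses and geometry, not on side chains or sequence.

`generateHarmonicTrajectory()` adds independent Gaussian displacements of
scale σᵢ (nm, per Cartesian coordinate, per residue) to every atom, then
optionally applies a uniform random rigid tumble (quaternion-uniform
rotation, translation in ±1 nm) to the whole frame. The displacement
stream is drawn before the tumbling stream, so toggling tumbling does not
change the internal motion for a given seed — the package's own test that
superposition removes tumbling exactly depends on this. The expected
per-residue RMSF is √3·σᵢ, which is the parameter-recovery target
(recovered within 2% at 5000 frames; the residual bias is the ~6/(3N)
variance absorbed by the six fitted rigid-body degrees of freedom).

What these trajectories do **not** have: bonded structure in the noise
(atoms of a residue displace independently, which no force field would
allow), solvent, correlated collective modes (unless constructed), or
relaxation dynamics — the frames are i.i.d. Passing the recovery tests
therefore demonstrates estimator correctness, not realism of any MD
engine; conversely nothing in the estimators depends on the noise being
i.i.d.

`generateMMDataset()` evaluates the Michaelis–Menten curve at a substrate
grid and adds Gaussian noise of SD = noiseCV·Vmax (constant variance, the
simplest model consistent with triplicate initial-rate assays). Defaults
in the validation runs follow the motivating study's glucose assay:
substrate spanning 1–200 mM (10 log-spaced points), 2% noise, and the
published d-glucose constants Km = 17.126 mM, kcat = 87.844 s⁻¹ as
ground truth.

## Windows, sizes and numerical choices

* **Equilibrium window.** Profile and ED analyses default to the second
  half of the trajectory (`startFraction = 0.5`), mirroring the common
  practice of analysing only the equilibrated portion of a production
  run. The four time-series panels default to the full trajectory,
  because those figures conventionally show the approach to equilibrium;
  every function accepts a start fraction.
* **Problem sizes.** The package's own validation uses a 4-chain,
  60-residue/chain, 2000-frame tetramer for the end-to-end pipeline
  (≈ 2 minutes on one CPU, SASA dominating), 5000 frames for RMSF
  recovery, 20,000 vectors per cone angle, and 50 replicate kinetics
  datasets — sizes chosen so sampling error sits well inside the stated
  tolerances.
* **Tolerances.** Exact identities (round-trips, spectral
  reconstruction, projection variances) are asserted at 1e-9–1e-12;
  Monte-Carlo quantities at 2–3 standard errors; cross-implementation
  SASA at 2%.
* **Degenerate inputs.** Collinear point sets have no unique rotation and
  are an error in `kabschFit()`; single-frame trajectories have undefined
  fluctuations; PDB B-factors overflowing the fixed 6.2 column clamp to
  999.99 with a warning; eigenvalues in [−1e-10, 0) from round-off clip
  to zero.
* **Seeds.** Every stochastic generator takes an explicit seed and is
  bit-reproducible; the deterministic parts (Fibonacci lattice, sign
  conventions, selection order) are chosen to make whole-pipeline reruns
  byte-identical.

## Known limitations

* PDB is the only trajectory format (no XTC/DCD/TRR, no mmCIF); at the
  PDB's 3-decimal Å precision a round-trip is exact to 0.0001 nm.
* Hydrogen-bond analysis is intra-protein only, N/O donors/acceptors, no
  lifetimes; SASA has no per-residue hydrophobicity decomposition; S² has
  no internal-correlation-time fitting; ED stops at projections (no
  free-energy landscapes or subspace overlap between trajectories).
* The kinetics module fits the single-substrate hyperbola only — no
  substrate inhibition, no bi-substrate mechanisms.
* Published headline numbers that depend on a specific production
  trajectory (mean S², variance captured by leading eigenvectors,
  B-factor ranges) can be *computed* by this package given an equivalent
  trajectory, but cannot be *reproduced* without one; the validation
  surface is closed-form ground truth instead.

## A worked pipeline run

```{r pipeline, eval = FALSE}
ref <- generateReferenceStructure(nResidues = 60, nChains = 4, seed = 1)
traj <- generateHarmonicTrajectory(ref, sigma = 0.05, nFrames = 2000,
                                   dt = 10, tumbling = TRUE, seed = 9)
manifest <- runPipeline(list(outdir = "gdh_analysis", seed = 9),
                        trajectory = traj)
manifest$outputs
#> "rmsd.tsv" "rg.tsv" "hbonds.tsv" "sasa.tsv" "rmsf.tsv" "s2.tsv"
#> "ed_eigenvalues.tsv" "ed_projections.tsv" "correlation_map.tsv"
```

Each table is one figure panel of a conventional stability analysis; the
manifest records every parameter the run actually used.
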