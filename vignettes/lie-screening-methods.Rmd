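---
title: "Methods: similarity-search screening and LIE energetics for AChE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-search screening and LIE energetics for AChE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lieScreen)
```

## The workflow

Acetylcholinesterase (AChE) hydrolyses acetylcholine and is a primary drug
target in Alzheimer's disease. `lieScreen` implements a desk-scale version
of a combined computational strategy for finding AChE inhibitors:

1. **Affinity regression.** A machine-learning model is trained to predict
   binding free energy from molecular descriptors, using compounds with
   measured inhibition constants as labels (converted by
   $\Delta G = RT\ln K_i$).
2. **Multi-round similarity-search enrichment.** The model scores an
   initial diverse library; the strongest predicted binders seed a 2-D
   fingerprint similarity search of a much larger library; newly found
   compounds are scored, re-seeded, and searched again. Each round's
   predicted-affinity distribution is summarized separately, and
   successive medians shifting toward more negative values is what
   "enrichment" means.
3. **LIE validation.** For complexes with molecular-dynamics interaction
   energy traces, the binding free energy is estimated by the linear
   interaction energy (LIE) method and compared with experimental values
   derived from IC50 measurements.
4. **Contact analysis.** Receptor-ligand trajectories are analysed for
   geometric hydrogen bonds and heavy-atom side-chain contacts, reported
   as per-residue fractions of simulation time, plus Kabsch-fitted RMSD.

The package does not dock ligands, run MD, parameterize force fields, or
query live chemical databases: structures, trajectories and energy traces
are inputs, and a local fingerprinted library stands in for the public
similarity-search service.

## Models and assumptions

### Thermodynamic conversion

Measured activities are converted with $\Delta G = RT \ln K$ where
$R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $K$ is the
inhibition constant or IC50 in molar units (nM and uM inputs are scaled by
exactly $10^{-9}$ and $10^{-6}$). IC50s are treated as surrogate
equilibrium constants, the usual pragmatic assumption when true $K_i$
values are unavailable.

Temperature is an explicit argument everywhere. The default is **300 K**,
not the conventional 298 K, because the packaged validation table's
experimental free-energy column is only consistent with
$RT \approx 0.596$ kcal/mol, i.e. $T \approx 300$ K ($RT$ at 298 K is
0.592). The 2 K discrepancy moves every converted value by under 0.1
kcal/mol; pass `temperature = 298` to use the standard temperature.

One row of the packaged table is internally inconsistent: for 7D9O (ligand
H0L) the stated 3 nM IC50 implies $-11.70$ kcal/mol at 300 K, not the
stored $-11.77$ (which corresponds to an unrounded IC50 near 2.66 nM).
The fixture therefore keeps the *stored* value so the published numbers
are reproduced bit-exactly, and `buildValidationTable()` always reports
the recomputed column alongside (`dg_exp_recomputed`) so the discrepancy
stays visible.

### Similarity search

Similarity is the Tanimoto coefficient $|A\cap B|/|A\cup B|$ over
fixed-length binary fingerprints. Two all-zero fingerprints get similarity
1 (identical objects). The cutoff defaults to **0.9**, the conventional
threshold of public 2-D similarity services, and is configurable. Hits are
deduplicated by compound id, records whose id appears among the seeds are
excluded (each round scores *newly identified* compounds), and results are
sorted by id so the search is independent of library record order. The
fingerprint source is deliberately pluggable — any backend that produces
fixed-length bitsets can populate the sidecar format — because the search
engine itself makes no chemical assumptions.

### Affinity regression

Three families are provided behind one interface: ordinary least squares,
random forests (ranger) and gradient-boosted trees (xgboost). Gradient
boosting is the default screening model. Splits and stochastic fits are
seeded, and tree learners run single-threaded, so training is exactly
reproducible. The held-out set is always the complement of the training
set (n_test = n − n_train). Metric uncertainties (RMSE, Pearson's R,
Spearman's rho) are standard deviations over seeded paired bootstrap
resamples (default 1000) — a model-agnostic choice made because no
analytic form covers all three metrics at small n.

Top-compound selection reads "lower than a threshold" as a *strict*
inequality, and breaks ties in both modes by lexicographic id, so
selections are deterministic.

### LIE energetics

The LIE estimate is
$$\Delta G_{LIE} = \alpha\left(\langle V^{vdw}\rangle_b -
\langle V^{vdw}\rangle_u\right) + \beta\left(\langle V^{cou}\rangle_b -
\langle V^{cou}\rangle_u\right) + \gamma$$
with $\langle\cdot\rangle_b$ and $\langle\cdot\rangle_u$ the mean
ligand-surrounding van der Waals and Coulomb interaction energies in the
bound (complex) and unbound (free ligand in solvent) states. The default
parameters $\alpha = 0.288$, $\beta = -0.049$, $\gamma = -5.88$ kcal/mol
are empirical values transferred from a protease whose shallow binding
cleft resembles that of AChE; the package treats them as given constants
(`lieParameters()`) and does not refit them.

Numerical conventions:

* **Units.** kcal/mol internally; kJ/mol inputs are divided by 4.184 at
  read time only.
* **Equilibration.** The first 20% of each trace's time span is discarded
  by default (`equilFraction = 0.2`). Production trajectories typically
  need an unspecified equilibration allowance; 20% is a conservative
  round figure, and the fraction is an explicit argument.
* **Replica aggregation.** The default pairs bound replica *i* with
  unbound replica *i*, computes one estimate per replica, and reports
  mean ± SEM, where SEM uses the sample standard deviation (n − 1
  denominator) over replicas. A single shared unbound trace is allowed
  with `sharedUnbound = TRUE` (the free-ligand simulation run once), and
  `pooled = TRUE` instead pools post-equilibration frames across replicas
  (weighting replicas by length; no replica spread, so no SEM). Replica
  counts are a configuration, not a constant, since published protocols
  vary between two and four repeats.

**Coverage of replica SEMs.** With $n$ replicas, the studentized error
$(\bar{\Delta G} - \Delta G_{true})/\mathrm{SEM}$ follows a Student-t
distribution with $n-1$ degrees of freedom, not a normal: with the common
two-replica protocol ($n=2$), $\pm 3\,\mathrm{SEM}$ covers only about
80% of cases, and with $n = 4$ about 94%. Interval statements based on
small-replica SEMs should therefore use t quantiles
(e.g. `qt(0.995, n - 1)`), and the package's calibration tests do.

### Contact analysis

A hydrogen bond requires (i) a donor (N/O/S) with a covalently bound
hydrogen — bonds inferred by distance $< 1.2\times$ the sum of covalent
radii when no topology is available — (ii) a donor-acceptor distance
$\le 3.5$ Å, and (iii) an acceptor-hydrogen-donor angle, measured at the
hydrogen, $\ge 135^\circ$. Acceptors are N/O, with S admitted by flag.
The angle-at-hydrogen convention is taken literally; note that a widely
used trajectory tool's native criterion differs (donor-acceptor cutoff
with a hydrogen-donor-acceptor angle $\le 30^\circ$), so numbers from
that tool are close but not identical by construction.

A side-chain contact is any receptor-residue non-hydrogen atom within
4.5 Å of any ligand non-hydrogen atom. The criterion is applied over
*all* heavy atoms of the residue by default because that is how the
distance rule is usually stated; `sideChainOnly = TRUE` excludes backbone
atoms for the stricter reading. Contact probabilities are fractions of
frames with at least one qualifying contact — the fraction of simulation
time the contact exists.

A consequence worth knowing: any qualifying hydrogen bond places two
heavy atoms within 3.5 Å, which automatically satisfies the 4.5 Å
side-chain criterion. Per-residue hydrogen-bond probability therefore
can never exceed side-chain probability, and the synthetic trajectory
generator enforces `sc_fraction >= hb_fraction` for its planted
fractions.

RMSD uses least-squares rigid-body superposition (Kabsch, via the SVD
with the determinant correction that excludes reflections) over a fit
selection, measured over a possibly different selection. Fitted RMSD is
never larger than unfitted RMSD, and the test suite checks the fitted
minimum against an independent brute-force search over a refined rotation
grid.

## What the synthetic generators emulate — and what they do not

`makeLibrary()` emulates a scaffold-clustered screening library:
descriptor vectors cluster around scaffold centres, labels are linear in
the descriptors plus Gaussian noise, and fingerprints share a scaffold
mask plus at most $k$ private bits, with $k = \lfloor m(1-t)/(2t)\rfloor$
derived so within-scaffold Tanimoto provably stays above the floor $t$
(a pair shares the $m$ mask bits and differs in at most $2k$, giving
similarity $\ge m/(m+2k)$). Defaults put the affinity distribution near a
median of $-7.4$ kcal/mol with an interquartile range of roughly 1.3-1.5
kcal/mol — the shape of the screened library that motivated the default
scaffold spread of 0.9 — with 1 kcal/mol label noise, 2000 compounds and
512-bit fingerprints. The planted potent scaffold shifts its descriptor
centre along the coefficient vector so its members average a requested
free energy (default $-11$ kcal/mol), making rediscovery by a trained
model possible rather than guaranteed by construction.

What it does not emulate: real descriptor distributions (molecular
weight, polar surface area and friends are correlated and bounded; these
are isotropic Gaussians), real fingerprint bit statistics, activity
cliffs, or any nonlinearity between descriptors and affinity. A passing
enrichment benchmark therefore demonstrates that the *pipeline mechanics*
(search, prediction, selection, summarization) enrich when a recoverable
signal exists — not that any particular chemistry would.

`makeEnergyTraces()` produces stationary AR(1) series with specified
means, marginal standard deviation (3 kcal/mol), and autocorrelation time
(5 ps at 2 ps spacing; lag-1 autocorrelation $e^{-dt/\tau}$), 25 000
frames per 50 ns-scale trace. AR(1) rather than white noise keeps SEM
calibration honest about autocorrelation, but real interaction energies
also drift, switch conformational basins, and correlate between their
vdW and Coulomb components — none of which is modelled.

`makeBindingTrajectory()` plants contacts by *exact count* (not
Bernoulli draws): a residue in contact in a fraction $f$ of frames is
placed in qualifying geometry in exactly `round(f * nFrames)` frames
chosen by a seeded shuffle, with hydrogen-bond frames a subset of
side-chain frames. Recovery is therefore an equality test. The geometry
is schematic (three-atom residues on radial directions around a
three-atom ligand), nothing like real AChE.

All generators route randomness through one seeded stream per call and
restore the caller's RNG state, so they are pure functions of their
seeds.

## Problem sizes and runtime choices

The shipped tests and the reproduction script run, by choice, at sizes
where every stage completes in seconds on one core: libraries of 120-2000
compounds, 100-25 000-frame traces, 100-frame/10-residue trajectories,
bootstrap sizes of 50-1000, 20-seed campaign replications and 100-seed
SEM calibrations. These are the sizes at which the statistical claims in
the test suite (coverage rates, enrichment success rates, recovery
tolerances) were derived; scaling any of them up changes runtime, not
correctness.

## Known limitations

* The enrichment benchmark's success criterion is assessed with the
  gradient-boosting screening model; a perfectly calibrated (noiseless)
  model can make round 1 find *only* the potent scaffold, in which case
  round 2 — which excludes its seeds — cannot lower the median further.
* Donor/acceptor typing is element-based with distance-inferred bonds;
  unusual protonation states or metal sites need an explicit topology.
* The IC50-to-free-energy conversion ignores assay-dependent offsets
  between IC50 and $K_i$; compare trends, not absolute values, across
  assays.
* Fingerprints are opaque bitsets here; nothing in the package computes
  them from structures. Attach real chemistry fingerprints through the
  sidecar file.
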