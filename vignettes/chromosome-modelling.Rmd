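---
title: "Modelling 3D chromosome organisation with NucleomeSim"
author: "NucleomeSim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 3D chromosome organisation with NucleomeSim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NucleomeSim)
```

## The model

NucleomeSim treats an interphase chromosome as a coarse-grained polymer at
50-kb resolution: one bead per 50-kb locus, carrying a chromatin
subcompartment type (A1, A2, B1, B2, B3, B4, or a neutral centromeric
type). The central physical hypothesis is that the compartmentalisation
seen in Hi-C maps arises from *microphase separation* of chromatin
segments with different biochemical identities: the 3D architecture is
encoded in the 1D sequence of compartment annotations plus the placement
of stable loops, much as a protein fold is encoded in its amino-acid
sequence plus disulfide bonds.

The energy landscape over bead positions $\mathbf{r}_1,\dots,\mathbf{r}_n$
is a sum of five terms, all in reduced units (bead diameter $\sigma = 1$,
thermal energy $k_BT = 1$):

1. **Connectivity** — a FENE bond between consecutive beads,
   $U_b(r) = -\tfrac{1}{2} k r_0^2 \ln\!\left(1 - (r/r_0)^2\right)$, plus
   a purely repulsive truncated-shifted Lennard-Jones (WCA) core. The
   bond diverges at the maximum extension $r_0$, so chain crossing is
   strongly suppressed.
2. **Nuclear confinement** — a half-harmonic spherical wall,
   $U_c = k_c\,(|\mathbf{r}| - R)^2$ for $|\mathbf{r}| > R$ and zero
   inside, mimicking the confining nuclear envelope.
3. **Ideal chromosome** — a translationally invariant term
   $\sum_{d_{\min} \le |i-j| \le d_{\max}} \gamma(|i-j|)\, f(r_{ij})$
   that depends only on genomic separation, never on bead identity. It
   models the distance-dependent compaction produced by motor activity
   along the fibre. We parameterise
   $\gamma(d) = g_1/\ln d + g_2/d + g_3/d^2$.
4. **Type-to-type interactions** —
   $\sum_{|i-j|\ge 2} \alpha(t_i, t_j)\, f(r_{ij})$ plus the WCA core for
   non-bonded pairs. The symmetric coupling matrix $\alpha$ over the six
   subcompartment types (plus the neutral type, which couples to nothing)
   drives microphase separation. Negative couplings are attractive.
5. **Loops** — $\chi\, f(r_{ab})$ for each anchor pair $(a, b)$ in the
   loop list (CTCF/cohesin-stabilised contacts).

All finite-range attractive terms act through the same sigmoidal contact
kernel

$$ f(r) = \tfrac{1}{2}\left[1 + \tanh\big(\mu\,(r_c - r)\big)\right], $$

which is 1 at contact, 1/2 at the midpoint $r_c$ and decays to 0 with
steepness $\mu$. `contactKernel()` exposes it directly.

## Parameters, defaults and why

`michromParameters()` holds every coefficient. The defaults are a
documented reduced-unit profile, *not* a published calibrated set — the
canonical 27-parameter optimisation lives in its own supplementary data
and can be dropped in verbatim by overriding the constructor's arguments:

| parameter | default | rationale |
|---|---|---|
| `feneK`, `feneR0` | 30, 1.5 | standard Kremer–Grest bead-spring values; keep bonds near $\sigma$ and uncrossable |
| `stericEpsilon`, `stericSigma` | 1, 1 | unit excluded volume in reduced units |
| `contactMu`, `contactRc` | 3.22, 1.78 | the field-standard kernel steepness/midpoint at 50-kb resolution |
| `confinementRadius`, `confinementK` | 10, 10 | radius is a per-system choice (set it from bead count and target density); 10 is a safe roomy default |
| `typeMatrix` | homotypic −0.4, within-class −0.2, A–B −0.05, neutral 0 | qualitative microphase-separation ordering: homotypic strongest, cross-class weakest |
| `idealGamma` | (−0.01, −0.1, 0) over `dMin = 3` to `dMax = 500` | a mild attractive decay; nearest and next-nearest neighbours are excluded because connectivity and sterics own them |
| `loopChi` | −1.5 | a loop is a few $k_BT$ — strong enough to hold formed anchors, weak enough not to dominate |

Two sign conventions matter: energies are `coefficient * f(r)`, so
*negative* coefficients attract; and the confinement wall is
$k_c (|\mathbf{r}|-R)^2$ without a 1/2 factor.

## Sampling

`runLangevin()` integrates the landscape with a BAOAB-discretised
Langevin thermostat (unit mass). BAOAB is the standard choice for
configurational sampling accuracy at moderate timesteps. Defaults
`timestep = 0.01`, `friction = 0.1` are ordinary coarse-grained-polymer
practice; the stiff-bond statistical tests below use a smaller timestep
and higher friction, both plain configuration fields.

Equilibration is deliberately **not** detected automatically: you state
`equilibrationSteps`, and the sampler reports an integrated
autocorrelation time of the radius-of-gyration series
(`diagnostics$rg_autocorrelation_time`, in saved frames) so you can judge
whether the burn-in and saving stride were adequate. Reproducibility: one
RNG (a 64-bit Mersenne Twister inside the integrator), seeded from the
configuration; replica $k$ uses `seed + k - 1` (`runReplicas()`).

The tested envelope is desk-scale: chains of roughly 100–2,000 beads
(5–100 Mb). Whole-genome production runs are what `exportMdInputs()` is
for — it writes the five tabulated potentials (`table_b0/b1/b2.xvg`,
`table.xvg`, `tablep.xvg`), the `.gro` initial coordinates and the
`.top` topology that an external MD engine consumes. Because the
type-to-type and ideal-chromosome terms have per-pair coefficients but a
table is a single curve, those two tables store the *basis* (the kernel
at unit coupling) and the coefficients live in `.top`; each file header
states this. The grid is $r \in [0, 3R]$ at $10^{-3}$ spacing.

## The structure-file ecosystem

`.ndb` is a human-readable, PDB-style 12-field text format for
chromosome structural ensembles: element type (`CHROM` bead or `DNAELE`
particle), element index, two-letter epigenetic code, genetic info (e.g.
a CTCF motif with orientation), chain id (`1M`/`1P` for
maternal/paternal homologs), within-chain index, x/y/z, genomic
start/end (1-based inclusive bp), and the spatial spread of the locus in
optical experiments. Loops are `LOOPS` records naming anchor element
indices and a class (`COHESIN`, `POLYCOMB`, `UNKNOWN`). Unknown
two-letter codes are preserved verbatim (the alphabet is extensible).
Because the reference description of the format does not fix column
positions, the dialect shipped here (documented in `?writeNdb`) fixes
them in PDB style and additionally accepts whitespace-delimited records.
On the spread field, the format's prose calls it a "width" while its
figure caption says "variance"; we store the value verbatim and do not
interpret it.

Siblings: `.spw` is the 6-column projection (fields 1, 10, 11, 7, 8, 9);
`.cndb` is the lossless binary container (magic + version + JSON metadata
+ float64 frames, little-endian) — text coordinates are rounded to three
decimals, binary ones are exact; `.pdb` export exists for the
visualisation ecosystem, with an optional per-bead scalar rescaled into
the B-factor column for colouring; `.gro` carries the initial
conformation with compartment annotations in the name columns.

Genomic coordinates: `.bed` input is 0-based half-open (the `.bed`
standard); everything internal and every `.ndb` field is 1-based
inclusive; the conversion happens once at ingest in `binBedSignal()`.

## From ChIP-seq to bead types

`binBedSignal()` integrates interval scores into 50-kb bins with
proportional length weighting — an interval contributes
`score * overlap/resolution` to each bin — chosen because it makes the
integral exact, conserves total signal and is independent of how
intervals split across boundaries. `collectMarks()` assembles the
canonical 11-mark matrix (missing marks allowed and flagged), and
`predictAnnotations()` applies a pluggable predictor. The shipped
`baselinePredictor()` is a transparent active-versus-repressive contrast
(documented in its help page) so the pipeline runs end to end; it is a
baseline, not a trained annotation network, and no claim of matching a
trained model's accuracy is made. Binned signals are passed to the
predictor raw — any normalisation is the predictor component's own
business. Users with real annotations bypass prediction entirely
(`readAnnotations()`).

## In-silico Hi-C and validation observables

`contactMap()` turns an ensemble into a locus-by-locus contact frequency
matrix. The contact criterion in experimental pipelines is not uniquely
defined, so both a hard cutoff (default, at the kernel midpoint `rc`) and
kernel averaging are offered. Downstream: `psCurve()` (mean contact
probability by genomic separation), `compartmentEigenvector()` (the
standard compartment call: observed/expected with per-diagonal expected,
Pearson correlation of columns, leading eigenvector; masked loci carried
as `NA`; the arbitrary global sign fixed by a stated convention),
`compareEigenvectors()` (Pearson after optimal sign alignment, sign
reported), `mapCorrelationByDistance()` (per-diagonal Pearson, with
truncation for the different-chromosome null comparison), and
`distanceDistribution()` (FISH-style pairwise distances).

## What the synthetic fixtures emulate — and what they do not

Every test input is generated, seeded and pure
(`makeBlockCopolymer()`, `makeIdealChainEnsemble()`,
`makeBlockContactMap()`, `makeBedTrack()`, `makeRandomEnsemble()`), each
shipping the closed-form expectation its consumer asserts. The planted
block maps mirror the plaid pattern of real compartmentalised maps
(checkerboard on a $1/(1+s)$ decay with symmetric lognormal noise); the
bed fixtures place breakpoints on `resolution/8` multiples so expected
bin integrals are dyadic-exact; the ideal-chain generator provides the
Gaussian $\langle R^2(s)\rangle = s\,b^2$ oracle.

Passing on these fixtures demonstrates the *mechanisms and the
machinery*: that the energy terms are the stated closed forms, that the
sampler draws from their Boltzmann distribution in analytically solvable
limits, that a two-type chain with homotypic attraction microphase
separates and closes the loop from planted types through sampled
structures to a recovered compartment eigenvector. It does **not**
demonstrate agreement with any particular experimental Hi-C map: the
published headline correlations require external experimental maps and
ensembles of order $10^5$–$10^6$ structures, far beyond desk scale. The
operations that would compute those comparisons are implemented and
tested on synthetic data; the problem sizes actually exercised are
stated below.

## Numerical choices and degenerate inputs

* Energy/force kernels skip pair interactions beyond
  $r_c + 14/\mu$, where the kernel is below $10^{-12}$ — far below every
  tolerance asserted anywhere.
* The sampler aborts with the step number and bond on FENE overstretch
  (the observable symptom of timestep blow-up).
* Duplicate loop entries collapse to one with a warning, anchor order
  canonicalised.
* `compartmentEigenvector()` refuses maps with fewer than three
  non-constant nonzero loci, naming the degeneracy; constant diagonals in
  `mapCorrelationByDistance()` yield `NA`, not an error.
* The observed/expected step conditions on genomic separation, so
  eigenvector equivariance holds under separation-preserving
  relabellings (e.g. chain reversal), which is what the test suite
  checks.
* Initial conformations are rejected early if the bead count cannot fit
  in the requested sphere at a workable density.
* PDB serials and residue numbers wrap modulo their field capacity above
  99,999 / 9,999 (stated in `?toPdb`).

## Problem sizes used by the shipped checks

The statistical tests run at sizes chosen to make their analytic limits
sharp while staying desk-friendly: the FENE dimer draws 1,000
bond-length samples 2,500 steps apart at `timestep = 0.002` (stiff-bond
accuracy); the tethered-bead equipartition check uses 20,000 saved
positions of a single bead in the $R \to 0$ confinement well (which is
exactly the isotropic harmonic well $U = k_c r^2$); the ideal-chain
check uses 10,000 frames of a 25-bead Gaussian chain; the
microphase-separation demonstration uses a 200-bead, four-block copolymer
sampled for $10^5$ steps in a radius-5 sphere. The documented
eigenvector-recovery threshold for that stochastic end-to-end run is 90%
sign agreement; the planted-map (no-sampler) recovery threshold is 95%
at the generator's documented noise level of 0.2.

The loop check is a one-sided comparison over replicas, run on a neutral
homopolymer so type attraction cannot confound the loop effect: a
150-bead chain in a dilute (radius-8) sphere carrying three 200-kb
(4-bead) loops — a typical CTCF-loop span at this resolution — against
three non-looped pairs at the same genomic separation, pooled over four
replicas of $3 \times 10^4$ steps. Averaging three independent loop
instances over replicas is what makes the few-percent equilibrium
contraction of a ~1.5 $k_BT$ anchor bond statistically sharp; a single
long-span loop in a single trajectory is dominated by slow conformational
noise.

## Known limitations

* The default parameter profile is qualitative; quantitative comparison
  to experimental maps requires a calibrated published set.
* The baseline annotation predictor is a two-class contrast that never
  emits B2/B4.
* The Langevin sampler is single-threaded and desk-scale; it makes no
  claim of matching the sampling efficiency of a production MD engine,
  which is what the exported input files are for.
* The `.ndb` dialect's column layout is this package's own (the format's
  reference description fixes fields, not columns); the
  whitespace-delimited fallback keeps the parser liberal.
* Cell-cycle-dependent variants of the ideal-chromosome term are not
  modelled; $\gamma(d)$ is fixed per system.
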