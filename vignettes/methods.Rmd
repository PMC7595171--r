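---
title: "Methods: two-state conformational analysis and free-energy machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state conformational analysis and free-energy machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh2states)
```

## Scope and model

The N-SH2 domain of the tyrosine phosphatase SHP2 populates two main
conformations. In the **α state** the pY loop is closed over the
phosphotyrosine site (Lys35 Cα–Thr42 Cα ≈ 9 Å), the central β-sheet is
spread into a Y shape (Gly39 C–Asn58 N ≈ 12 Å) and the +5 specificity
pocket is closed (Tyr66 Cα–Leu88 Cα ≈ 7 Å). In the **β state** the pY
loop is open (≈ 11 Å), the sheet strands are parallel and closed (≈ 4 Å)
and the +5 site is open (≈ 12 Å). The sheet spread is anticorrelated with
the pY-loop opening, and the pY-loop and +5-site openings are positively
coupled — an allosteric link that spans the domain. `sh2states` implements
the analysis machinery with which such a two-state picture is established
and interrogated:

* superposition, core-fit PCA, loop subvectors, order parameters,
  correlation analysis and α/β classification (`superpose()`, `pca()`,
  `subvector()`, `order_parameters()`, `classify_states()`);
* GROMOS conformational clustering and umbrella-window seeding
  (`rmsd_matrix()`, `gromos_cluster()`, `choose_cutoff()`,
  `seed_windows()`);
* WHAM free-energy profiles with Bayesian bootstrap of complete
  histograms (`wham_solve()`, `bayesian_bootstrap()`);
* Crooks/Bennett nonequilibrium estimation with thermodynamic-cycle ΔΔG
  composition (`bar_solve()`, `crossing_estimate()`, `work_bootstrap()`,
  `cycle_ddg()`);
* simulated tempering with Park–Pande initial weights and Wang–Landau
  adaptation coupled to constant-velocity pulling
  (`park_pande_weights()`, `st_attempt()`, `wl_update()`,
  `run_tempered_pull()`).

Because the microsecond all-atom trajectories behind the published
SHP2 analyses are not reproducible at desk scale, every method here is
exercised on synthetic systems with analytically known ground truth: 1-D
model potentials, Crooks-consistent Gaussian work pairs, and pseudo-domain
structural ensembles with stored state labels. The package validates the
*machinery*, not the force-field results.

## Units and constants

Lengths are nanometres and energies kJ/mol internally, with
kB = 0.0083145 kJ/mol/K; Ångström appears only at I/O boundaries (PDB
files, order parameters, RMSD values) through explicit conversions. This
avoids the silent Å/nm mixing that plagues scripts in this field.

## The synthetic two-state generator

`build_two_state_ensemble()` emits a pseudo-N-SH2 backbone — residues
3–103 in SHP2 numbering, atoms N/CA/C per residue on a smooth helical
curve — in which the six anchor atoms of the three order parameters are
placed explicitly so that each state reproduces its target distances
exactly at zero noise. Frames sit at one of the two reference geometries
(per-frame state drawn Bernoulli(α-fraction)) connected by a single
collective displacement mode, plus isotropic Gaussian coordinate noise.
Along that mode the order parameters co-vary linearly with the allosteric
sign structure (sheet vs pY negative, pY vs +5 positive); a `coupling_mode`
sign map can flip either coupling for negative-control tests.

Default study conditions, used throughout the tests: 2000 frames,
α-fraction 0.7 where a recovery target is needed, coordinate noise
0.3 Å, which keeps the smallest inter-state distance gap (2 Å for the pY
parameter) at ≈ 4.7 σ of the induced distance noise — overlapping enough
to make classification nontrivial, separated enough that accuracy ≥ 98%
is achievable. No quantitative α/β populations are published for any
peptide, so the α-fraction is a free generator parameter, not a literature
value. The generator warns, and records in its log, when the requested
noise makes the reference distances overlap (4√2·noise above the smallest
gap).

What the generator deliberately does **not** emulate: real backbone
geometry (bond lengths/angles), anharmonic loop dynamics, multiple
coupled modes, and state-dependent noise. Passing tests therefore
demonstrate correctness of the analysis pipeline on well-posed inputs,
not robustness to every pathology of real trajectories.

## Superposition and PCA

`superpose()` uses the closed-form Kabsch solution (SVD of the
cross-covariance, with the determinant correction that excludes
reflections); the transform is computed on a fit selection and applied to
all atoms. Degenerate (collinear) fit selections are rejected. The
default fit selection for domain analysis is the rigid core
(Phe7–Pro33, Asp40–Arg47, Ala50–Asn58, Asp61–Leu65, Phe71–Tyr81,
Leu88–Glu90, Val95–Pro101); the PCA covariance is built over the backbone
of Trp6–Pro101. "Backbone" is {N, CA, C, O} when O atoms are present and
{N, CA, C} otherwise.

`pca()` assumes an already-superposed ensemble (superposing internally
when a fit selection is passed) and diagonalises the 3m × 3m coordinate
covariance via SVD of the centred frame matrix. Eigenvector signs are
arbitrary, so the package fixes a convention: vectors are oriented so that
increasing projection η moves the Gly39 C–Asn58 N distance upward, i.e.
+η points toward the α state; this makes quadrant-style state plots
reproducible across runs. Projections are η_t = (frame_t − mean)·v, and
the identity var(η) = eigenvalue is asserted in the tests.

`subvector()` follows the two-step recipe used for loop-specific modes:
reconstruct the rank-1 trajectory mean + η₁v, then run PCA restricted to
the subset atoms (pY loop Ser34–Phe41, +5 site Gln57–Glu97). The result
must equal the restriction of the parent vector re-normalised to unit
length, up to sign; the implementation computes both routes and fails
loudly if |dot| < 0.999, so the closed-form equivalence is checked on
every call rather than trusted.

## Classification

Default thresholds are the midpoints of the two state targets — pY 10 Å,
sheet 8 Å, +5 site 9.5 Å — because the literature reports state centroids,
not boundaries; all thresholds are overridable. A frame is α iff the pY
loop **and** the +5 site are closed, β iff both are open, and `mixed`
otherwise (the two off-diagonal quadrants; the closed-pY/open-+5 corner is
the geometry typical of the isolated domain in a crystal environment).
State fractions carry Wilson 95% intervals. A projection-mode classifier
(`classify_states_projection()`) applies the same quadrant logic to η
values on the two loop subvectors, with thresholds at the midpoint of the
projected reference geometries.

## GROMOS clustering and window seeding

`gromos_cluster()` is the greedy neighbour-count algorithm: take the frame
with the most neighbours within the cutoff, remove the cluster, repeat.
Ties on neighbour count are broken toward the lowest frame index — the
original algorithm is silent on ties and determinism is required for
reproducible runs. Centres are the neighbour-richest frames, not mean
structures. `choose_cutoff()` histograms all off-diagonal pairwise RMSDs
(Freedman–Diaconis bin width), smooths with a 3-bin moving average, and
returns the first local maximum; bins below 5% of the peak count are not
eligible, so one-count noise bumps in the tail cannot masquerade as the
first mode, and a monotone histogram falls back to the median with a
logged warning. Whether the distribution should be of all pairs or of
pairs-to-centres is ambiguous in the original procedure; all off-diagonal
pairs is implemented. `seed_windows()` partitions a pulling trace into
equal reaction-coordinate intervals and seeds each window with the centre
of its largest cluster, at a per-interval cutoff.

## WHAM and the Bayesian bootstrap

`wham_solve()` iterates the standard self-consistent equations on binned
samples (default 200 uniform bins over the sampled range) until
max|ΔF_i| < 1e−4 kJ/mol (max 10⁵ iterations); neither tolerance nor bin
count is prescribed in the literature for this problem, so both are
package defaults. Empty bins are dropped rather than reported as
infinities, and profiles use the min-zero offset convention, recorded in
the output. Adjacent windows that share no occupied bin trigger a
warning; a genuine coverage gap (empty bins between two windows' occupied
ranges) is an error naming the gap, because the profile would decompose
into disconnected pieces with arbitrary relative offsets.

`bayesian_bootstrap()` treats **whole window histograms** as the
independent units: each replicate draws i.i.d. exponential weights over
windows (normalised — the Bayesian-bootstrap Dirichlet weighting),
re-solves WHAM with the weighted histograms, aligns each replicate to the
base profile by the mean over shared bins, and reports per-bin standard
deviations. Weights never attach to individual samples. The replicate
count defaults to 100; the published protocol does not state one.

Profile accuracy is assessed over the span of the window references: the
umbrella design guarantees coverage there, whereas bins beyond the
outermost references hold only tail samples whose statistical noise is
unbounded. At the test conditions (24 windows, k = 1000 kJ/mol/nm²,
10⁴ exact samples per window over a K = 50 kJ/mol/nm² harmonic landscape)
the recovered profile agrees with ½Kx² to better than 0.5 kJ/mol across
that span.

## Crooks/Bennett estimation

`gaussian_work_pairs()` draws forward work from N(ΔG + βσ²/2, σ²) and
reverse work from N(−ΔG + βσ²/2, σ²) — the unique Gaussian pair
satisfying the Crooks relation P_F(W)/P_R(−W) = e^{β(W−ΔG)} exactly, which
the tests verify analytically. The default sample size of 200 per
direction mirrors the standard protocol of spawning 200 fast
nonequilibrium transitions from each equilibrium end state.

`bar_solve()` implements the Bennett acceptance-ratio estimator — the
maximum-likelihood ΔG under the Crooks relation — as a bracketed root
solve of the logistic self-consistency equation, with
M = kBT ln(n_F/n_R), bracket [min(−W_R), max(W_F)] ± 10 kBT and tolerance
1e−6 kJ/mol. The literature phrase "computed using the Crooks fluctuation
theorem" does not disambiguate between this estimator and the
crossing-point reading; both are provided, with BAR primary and
`crossing_estimate()` (Gaussian KDE, Silverman bandwidth, intersection of
P_F(W) and P_R(−W) inside their overlap) as the diagnostic cross-check.
Work sets whose forward and negated-reverse values are separated by more
than 50 kBT are rejected with advice to sample more. `work_bootstrap()`
resamples the two directions independently with replacement.

`cycle_ddg()` composes two legs, ΔΔG = ΔG_bound − ΔG_unbound with
quadrature errors, and renders the sign convention explicitly: in the
α-vs-β-preference context a positive ΔΔG means an augmented preference
for the α state. Work-table files always embed the work sign convention
(forward = work done on the system for λ 0→1) in their headers, since
silent sign flips are the classic failure mode of these calculations.

## Simulated tempering and pulling

Two ladder presets reproduce the tempering protocols used for the two
pulling problems: 300–400 K in 5 K steps (whole-phosphatase opening) and
300–380 K in 10 K steps (β-sheet opening). `park_pande_weights()` sets the
initial weights by trapezoidal thermodynamic integration of per-rung mean
energies; `st_attempt()` is the Metropolis rung exchange
min{1, exp[−(β_j−β_i)U + (f_j−f_i)]} with nearest-neighbour proposals and
uniformly chosen direction (the proposal scheme is unstated in the
sources; nearest-neighbour is the common choice).

`wl_update()` implements Wang–Landau adaptation: the visited rung's weight
drops by δ, and when the visit histogram is flat (min/mean > 0.8) δ is
halved and the histogram reset (δ₀ = 1, scale 0.5; the scheme's citation
carries no parameter values). Two refinements guard against well-known
pathologies of the plain scheme on a single-walker ladder: (i) a stage
only completes once every rung has ≥ 20 visits, because a single sweep of
a nearest-neighbour rung walk already produces a deceptively flat
residence histogram; (ii) the driver applies the 1/t refinement, never
letting δ fall below n_rungs/t, which removes the error-saturation
pathology in which δ decays exponentially while a finite weight error
freezes in place. With these, 2×10⁵ attempts on the 21-rung harmonic
test system converge the weights to the exact βF ladder within 0.2
(additive constant removed) across seeds, which is what the acceptance
suite asserts.

Occupancy flatness under exact weights is a Markov-chain property: the
rung sequence is a nearest-neighbour walk whose relaxation time on 21
rungs is ≈ 2·21²/π² ≈ 90 attempts, so raw per-attempt counts fluctuate
far above multinomial noise. Uniformity is therefore tested on attempts
thinned by 500 (≈ 5 relaxation times) with a χ² test at the 3σ
significance level — the statistically calibrated version of "occupancy
uniform within 3σ".

`run_tempered_pull()` integrates overdamped Langevin dynamics
(Euler–Maruyama; the integrator refuses dt·K_max/γ ≥ 2, the contraction
bound of the deterministic part, and aborts on divergence) under a moving
harmonic bias, with tempering attempts at a fixed interval and work
accumulated per reference increment by the midpoint rule
dW = k(ref_mid − ξ)dref — second-order accurate, and verified against
the reversible limit: at pull speed 0.02 nm/ps on the stiff-trap harmonic
system the mean work over 16 pulls is within 5% of the closed-form
ΔF = ½·k_eff·Δref² with k_eff = kK/(k+K). Runs are at constant volume
(trivially so for these model systems) and record that in their metadata.
Frames visiting the base rung are flagged, since downstream window
seeding draws only from the base-temperature sub-ensemble.
`pull_work_set()` repeats fast forward/reverse pulls from exactly sampled
equilibrium end states and stores the quadrature truth for the restrained
end-state ΔG on the resulting work set.

## Numerical choices, in brief

* Exact inverse-CDF sampling on a 2¹⁵-point grid for all umbrella inputs;
  no Markov-chain equilibration confounds WHAM tests.
* WHAM: 200 bins, tolerance 1e−4 kJ/mol, max 10⁵ iterations; min-zero
  offsets; profile accuracy judged over the window-reference span.
* BAR: tolerance 1e−6 kJ/mol; bracket expansion 10 kBT; overlap guard at
  50 kBT.
* Langevin: stability bound dt·K_max/γ < 2 enforced; the Euler–Maruyama
  stationary variance carries an O(dt·K/γ) inflation, so equilibrium
  marginal checks use dt·K/γ ≤ 0.05.
* Problem sizes in the shipped tests — 10⁴–10⁵ sampler draws, 2000-frame
  ensembles, 50 work-set replicates, 10⁵–2×10⁵ tempering attempts, 16+400
  pulls — were chosen so each stochastic assertion sits several standard
  errors inside its tolerance.
* Ties in clustering break toward the lowest frame index; eigenvector
  signs follow the sheet-opening convention; all RNG flows through
  explicit per-call seeds (no global state is consumed or disturbed).

## Known limitations

* The crystal-structure distance check requires a PDB file (entry 2SHP)
  that is not redistributable inside the package; the packaged
  `nsh2_beta_synthetic.pdb` is a generator-built β-state reference —
  synthetic, as its name states — useful for exercising the measurement
  code path, not a substitute for the crystallographic measurement.
* Single-temperature WHAM only; umbrella windows must share a
  temperature.
* The pseudo-domain generator supports every selection the analysis uses
  but is not stereochemically realistic; PCA variance fractions on it are
  not comparable to those of real trajectories.
* No replica exchange, no multidimensional reaction coordinates, and no
  force-field simulation of any kind.
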