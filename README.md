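# sh2states

Conformational-state and free-energy analysis toolkit for two-state
allosteric protein domains, built around the α/β equilibrium of the
SHP2 N-SH2 domain.

## The problem

The N-SH2 domain of the tyrosine phosphatase SHP2 both autoinhibits the
catalytic domain and recognises phosphotyrosine (pY) ligands. It
populates two conformations: an **α state** (closed pY loop, spread
Y-shaped central β-sheet, closed +5 specificity pocket) that promotes
phosphatase activation, and a **β state** (open pY loop, closed parallel
β-sheet, open +5 site) that stabilises the autoinhibited assembly. Three
inter-atom distances act as order parameters:

| order parameter | atoms | α | β |
|---|---|---|---|
| pY-loop opening | Lys35 Cα – Thr42 Cα | ~9 Å | ~11 Å |
| β-sheet spread | Gly39 C – Asn58 N | ~12 Å | ~4 Å |
| +5-site opening | Tyr66 Cα – Leu88 Cα | ~7 Å | ~12 Å |

Deciding which state an ensemble populates, how the three sites couple,
and how mutations or ligands shift the equilibrium requires a pipeline of
standard but error-prone machinery: least-squares superposition, core-fit
PCA with loop subvectors, state classification, GROMOS clustering for
umbrella-window seeding, WHAM free-energy profiles with Bayesian
bootstrap errors (G_j = −kBT ln p_j from the self-consistent window
equations), Crooks/Bennett nonequilibrium ΔG estimation
(P_F(W)/P_R(−W) = e^{β(W−ΔG)}; BAR as the maximum-likelihood solution),
thermodynamic-cycle ΔΔG composition, and simulated tempering
(Metropolis rung exchange with Park–Pande initial weights and
Wang–Landau adaptation) coupled to constant-velocity pulling.

`sh2states` implements that pipeline as tested, reusable R functions.
Every stochastic method is validated end-to-end on synthetic systems with
analytically known ground truth: exact Boltzmann samples of 1-D model
potentials, Crooks-consistent Gaussian work pairs, and pseudo-N-SH2
two-state ensembles with stored per-frame labels. For whom: anyone
building or checking conformational-state and free-energy analyses of
MD-style ensembles who wants each stage exercised against an oracle
before trusting it on real trajectories.

## Worked example

```r
library(sh2states)

# a synthetic two-state ensemble with known labels
gen <- build_two_state_ensemble(n_frames = 2000, alpha_fraction = 0.7,
                                noise_sd = 0.3, seed = 42)
ops <- order_parameters(gen$ensemble)      # pY / sheet / plus5, Angstrom
cls <- classify_states(ops)
print(cls)
#> state_labels over 2000 frames:
#>   alpha 0.690  (95% CI 0.669-0.710)
#>   beta  0.299  (95% CI 0.280-0.320)
#>   mixed 0.011  (95% CI 0.007-0.016)
mean(cls$labels == gen$labels)             # 0.9895 against ground truth
pearson(ops$sheet, ops$pY)                 # -0.905: sheet spread vs pY opening
pearson(ops$pY, ops$plus5)                 #  0.898: pY vs +5 opening

# first collective mode and the loop-subvector identity
cv <- pca(gen$ensemble, nsh2_selection("analysis"), n_vectors = 1)[[1]]
subvector_agreement(cv, gen$ensemble, nsh2_selection("py_loop"))  # 1

# WHAM on 24 exact-sampled umbrella windows over U(x) = 25 x^2
pot <- potential_1d("harmonic", K = 50)
uws <- sample_umbrella_windows(pot, seq(-0.6, 0.6, length.out = 24),
                               force_constant = 1000, n_per_window = 10000,
                               seed = 42)
prof <- wham_solve(uws)                    # max |G - U| over the span: 0.21 kJ/mol

# Crooks-consistent work pairs and the two estimators
ws  <- gaussian_work_pairs(true_dg = 10, sigma = 5, temperature = 300,
                           n_per_direction = 200, seed = 42)
work_bootstrap(ws, bar_solve, n_boot = 100, seed = 43)
#> dG = 9.909 +/- 0.263 kJ/mol  [bar; 200 fwd / 200 rev at 300 K]
crossing_estimate(ws)
#> dG = 10.36  kJ/mol  [crossing; 200 fwd / 200 rev at 300 K]

# a mutation thermodynamic cycle
cycle_ddg(delta_g(12.0, 0.5, "bar", 200, 200),
          delta_g(5.0, 0.5, "bar", 200, 200), "alpha-vs-beta-preference")
#> ddG = 7 +/- 0.7071 kJ/mol [alpha-vs-beta-preference]: augmented preference
#> for the alpha state
```

The classification recovers the generating α fraction (0.69 vs 0.70)
with 99% label accuracy; the correlation signs reproduce the allosteric
coupling structure (sheet–pY negative, pY–+5 positive); BAR recovers the
generating ΔG = 10 kJ/mol within its bootstrap error.

Configuration-driven runs (`parse_config()` / `run_command()`, or the
wrapper `inst/scripts/sh2states-cli.R`) chain the stages — `generate`,
`states`, `cluster`, `wham`, `cft`, `temper` — with explicit seeds,
resolved-config provenance and JSON run records.

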