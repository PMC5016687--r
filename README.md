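# anisofit

Equilibrium binding thermodynamics for tetrameric DNA-binding sensor
proteins of the RcnR/CsoR (DUF156) family — the formaldehyde sensor FrmR
and the Ni(II)/Co(II) sensor RcnR of *Salmonella* being the motivating
systems — for biochemists who quantify repressor–operator interactions by
fluorescence anisotropy and want the downstream thermodynamic modelling
to be scripted, tested and reproducible.

The package covers four linked computations:

1. **Equilibrium speciation.** A binding mechanism is written as
   *components* (protein tetramer `T`, DNA probe `D`, …) with total
   concentrations, plus *complexes* with overall dissociation constants
   `[complex] = Π_i [free_i]^ν_i / K`. The coupled mass balances are
   solved by damped Newton iteration on log free concentrations, which
   keeps every concentration positive. The workhorse mechanism is the
   two-nondissociable-tetramer model of operator binding,

   T + D ⇌ TD (K₁ = K_DNA),  T + TD ⇌ T₂D (K₂ = K_DNA),

   i.e. two tetramers binding a single operator–promoter fragment with
   equal stepwise affinity; the titrant is entered as monomer and
   divided by four (the nondissociable-tetramer convention).

2. **Anisotropy titration simulation and fitting.** The anisotropy
   change is linear in the number of bound tetramers
   (Δr = Δr_max·(½[TD] + [T₂D])/D_tot, so the normalised signal is the
   site occupancy of the probe). `fit_kdna()` minimises
   Σ(Δr_obs − Δr_model)² over log₁₀K (and Δr_max unless fixed) with
   Levenberg–Marquardt and seven log-spaced multistarts. Titrations
   that cannot saturate within the accessible protein range are
   reported as **lower bounds** ("≥ K"), and flat titrations return the
   design's detection limit rather than an error.
   `stoichiometry_breakpoint()` analyses titrations run at probe ≫ K,
   where the rising-line/plateau intersection gives the binding
   stoichiometry in monomer equivalents per DNA (8 for two tetramers).

3. **Allosteric coupling free energy.** `coupling_energy()` computes
   ΔG_C = RT·ln(K_DNA^effector / K_DNA^apo) for every pairwise
   permutation of replicate apo and effector-bound constants (equally
   weighted) and reports mean ± SD; positive values mean the effector
   weakens DNA binding. Lower-bound K's propagate to a "≥" ΔG_C.

4. **Intracellular formaldehyde partitioning.** `modification_curve()`
   solves the competition of a trace sensor (effective formaldehyde
   affinity 10⁻⁵ M for FrmR, 10⁻⁴ M for RcnR) against the bulk
   glutathione pool (S-(hydroxymethyl)glutathione Kd 1.77 × 10⁻³ M,
   1.2 mM GSH) for free formaldehyde, returning the modified fraction
   of each pool; `copies_per_cell()` converts molarity to molecules per
   cell (1 fl default volume).

A seeded synthetic-titration generator (`gen_titration()`,
`gen_effector_series()`) produces replicate data with additive Gaussian
noise so the entire pipeline is testable without instrument data, and a
CSV dialect plus CLI (`inst/scripts/anisofit.R`) tie the stages into a
reproducible pipeline.

## Worked example

Simulate three noisy replicates of an apo-FrmR-like titration
(K_DNA = 9.9 × 10⁻⁸ M, 10 nM probe, 0–2 μM monomer, 5% noise), refit,
and compute a coupling energy and the cell model:

```r
library(anisofit)
resp  <- response_model(0.1)                    # delta_r_max = 0.1
sched <- titration_schedule("trace")            # 20 pts, 0-2 uM monomer
reps  <- gen_titration(9.9e-8, 1e-8, sched, resp, noise_spec(0.005, 42, 3))
fit_kdna(reps)
#> K_DNA 8.909e-08 M (delta_r_max 0.09687, sse 0.001783)
#>   replicates: n = 3, K = 8.909e-08 +/- 9.944e-09 M
#>   saturation at final point: 88.2%

coupling_energy(1.5e-7, 5.9e-6, effector_is_bound = TRUE)
#> Coupling free energy: >= +2.18 +/- 0.00 kcal/mol (n = 1 pairs, T = 298.15 K)

p <- cell_model_params("FrmR")
modification_curve(p, formaldehyde_at_gsh_fraction(p, 0.04))
#>      f_total_M  f_free_M frac_sensor frac_gsh
#> 1 0.0001218067 7.375e-05    0.880597     0.04

copies_per_cell(16.1e-9)
#> [1] 9.695645
```

The refit K (8.9 ± 1.0 × 10⁻⁸ M across replicates) recovers the
generating constant within its replicate scatter; the Ni(II)-bound vs
apo pair of operator affinities corresponds to ≈ +2.2 kcal/mol of
allosteric coupling, reported as a lower bound because the effector
titration cannot saturate; and at the formaldehyde level where only 4%
of the glutathione pool carries formaldehyde, the tighter-binding FrmR
sensor is already 88% modified — the thermodynamic basis for the sensor
responding before the detoxification substrate accumulates.

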