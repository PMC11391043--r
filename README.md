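# phbind

Analysis toolkit for pH-dependent ligand binding to small
odorant-binding-protein-like carriers, motivated by the fire-ant venom
protein Sol g 2.1: a five-helix, disulfide-stabilised protein with a
hydrophobic cavity that binds semiochemicals such as (E)-β-farnesene at
physiological pH and tends to release them in acidic environments.
The package is aimed at structural-bioinformatics users who want to
quantify that pH contrast from fluorescence titrations and molecular
dynamics trajectories without any external software, and at method
developers who need a small, fully testable reimplementation of the
standard analysis chain.

## What it computes

**Binding assays.** Saturation fluorescence titrations are fit to the
one-site model

    Y = Bmax · X / (Kd + X)

by Levenberg–Marquardt least squares, with the Scatchard linearisation
(bound/free vs bound; slope = −1/Kd) as a diagnostic. Competitive
displacement curves are fit to the concentration-form logistic with Hill
slope 1 and converted to the competitor constant by Cheng–Prusoff,

    EC50 = Ki · (1 + [probe] / Kd_probe).

**Trajectory descriptors.** Kabsch-superposed backbone RMSD, per-residue
Cα RMSF about the time-average structure, mass-weighted radius of
gyration (nm), and Shrake–Rupley solvent-accessible surface area (nm²)
on a deterministic Fibonacci lattice.

**Binding free energy.** Per-frame receptor–ligand interaction energies
(Coulomb + Lennard-Jones cross terms), an MM-PBSA-style term table
ΔG_gas = ΔG_ele + ΔG_vdW, ΔG_sol = ΔG_np + ΔG_pb, ΔG_MM-PBSA = ΔG_gas +
ΔG_sol, the interaction-entropy estimator

    −TΔS = k_B T · ln ⟨ exp(β ΔE_fluct) ⟩,   β = 1/(k_B T),

and per-residue decomposition of the interaction energy. The polar
solvation term is a Generalized-Born surrogate (Still functional,
HCT pairwise-descreening Born radii) and is labelled
`pb_surrogate(GB)` in every output.

**Protonation.** Henderson–Hasselbalch protonated fractions
f = 1/(1 + 10^(pH − pKa)), expected per-residue charges at a given pH,
group-average pKas (acidic Asp/Glu, basic His/Lys/Arg, neutral Cys/Tyr,
with "> 12" ceiling entries counted as 12), and flagging of residues
with large pKa shifts against model values.

**Conformational analysis.** Two-component Cartesian PCA of Cα
coordinates with per-frame scores in nm, plus spread metrics (score
ranges, mean distance to the medoid) that quantify how localised the
sampled conformations are.

A seeded synthetic-data module generates every input — toy
receptor–ligand complexes, fluctuating multi-frame trajectories with a
pH-like "loose residues" control, Gaussian energy series, and noisy
titration curves — so the whole pipeline runs offline and each estimator
can be checked against known ground truth.

## Worked example

```r
library(phbind)

# a saturation titration at the probe's pH 7.4 constant, 2% noise
sat <- fit_saturation(simulate_titration(kd = 2.33, bmax = 1e6,
                                         noise_cv = 0.02, seed = 11,
                                         ph_label = "pH 7.4"))
sat
#> One-site saturation fit [pH 7.4]
#>   Kd   = 2.361 +/- 0.056 uM
#>   Bmax = 9.985e+05 +/- 7.2e+03 counts/s
#>   R^2  = 0.9997;  Scatchard Kd = 2.323 uM (slope -0.4305 /uM)

# displacement by a farnesene-like competitor (Ki 0.72 uM), 5 uM probe
cmp <- fit_competition(simulate_competition(ki = 0.72, kd_probe = sat$kd,
                                            radioligand_conc = 5,
                                            noise_cv = 0.02, seed = 12),
                       kd_probe = sat$kd)
cmp
#> One-site competitive displacement fit
#>   EC50 = 2.197 +/- 0.021 uM
#>   Ki   = 0.7047 +/- 0.0068 uM (probe 5 uM, probe Kd 2.36 uM)

# interaction entropy of a Gaussian energy series (sigma = 1 kcal/mol):
# the estimator converges to beta sigma^2 / 2 = 0.8387 kcal/mol
interaction_entropy(simulate_energy_series(-30, 1, 1e5, seed = 42))
#> [1] 0.8481

# group-average pKas from the bundled per-residue prediction table
tab <- read_pka_csv(system.file("extdata", "solg21_pka_predictions.csv",
                                package = "phbind"))
protonation_summary(tab, "farnesene_pH7.4", ph = 7.4)
#> Protonation summary [farnesene_pH7.4] at pH 7.40
#>   mean pKa: acidic 3.40, basic 10.53, neutral 10.63
```

The fitted Kd/Ki sit within a few percent of the generating constants —
the level of agreement the estimators are required to reach in the test
suite. The two-condition pipeline (`pipeline_config()` →
`run_pipeline()` → `render_report()`) chains all stages for a pH 7.4 vs
pH 5.5 comparison and writes CSV/JSON artifacts plus a manifest with
file hashes.

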