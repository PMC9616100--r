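# confmodel

Kinetic and thermodynamic analysis of enzymes whose resting state hides a
slow conformational equilibrium — built around the designed Kemp eliminase
lineage HG3 → HG3.7 → HG3.17, whose inactive/active interconversion
(k\_obs ~ 10⁻⁴–10⁻³ s⁻¹) is slow enough to duplicate NMR resonances, shape
stopped-flow binding kinetics, and bias classical steady-state analysis.

The package is for enzymologists and biophysicists who need to:

* simulate and globally fit **transition-state-analogue (TSA) binding** under
  conformational selection (`I ⇌ A + L ⇌ AL`), with an induced-fit extension
  (`AL ⇌ AL*`) — microscopic rates in, equilibrium constants
  `K1 = k_ai/k_ia`, `K2 = k_off/k_on`, `K3 = k_ir/k_if` and the macroscopic
  `K_D = K2(1+K1)/(1+1/K3)` out;
* fit **full substrate-depletion progress curves** to an extended
  Michaelis–Menten scheme with the conformational step and product
  inhibition (`I ⇌ A; A+S ⇌ AS → A+P; A+P ⇌ AP`), recovering `k_cat`, `K_M`,
  `K_S`, `K_P` even when solubility keeps `S0` far below saturation;
* quantify the **slow exchange by NMR**: inactive populations from duplicated
  cross-peak volumes, pH-jump relaxation rates, and the split
  `k_ina→act = p_active·k_obs`, `k_act→ina = (1−p_active)·k_obs`;
* connect catalysis to binding through **transition-state theory**:
  `K_TX = (K_S/k_cat)·k_uncat`, its log–log correlation with `K_2` across
  variants, and fold-change tables.

Everything runs on a declarative mass-action scheme engine (stiff
Rosenbrock integration with analytic Jacobians, compiled; equilibrium by
damped Newton on log-concentrations) and is validated end-to-end by seeded
synthetic-data generators that emulate the three experimental data streams.

## Worked example

The full pipeline on the most evolved variant (HG3.17), using only
synthetic data — NMR populations feed the relaxation split, whose rates are
fixed inside the stopped-flow global fit, exactly as the combined
experimental strategy prescribes:

```r
library(confmodel)
p <- variant_preset("HG3.17")

# 1. populations from a slow-exchange peak pair
sp <- gen_nmr_peaks(p$p_inactive_25C, centers = c(8.3, 8.8),
                    noise = noise_model(0.02, seed = 1))
pI <- population_from_volumes(
  v_active   = integrate_peak(sp, c(8.05, 8.55)),
  v_inactive = integrate_peak(sp, c(8.55, 9.05)))$p_inactive

# 2. interconversion rate from a pH jump
jump <- gen_ph_jump(p$binding$k_ia, p$binding$k_ai, p_start = 0.3,
                    noise = noise_model(0.01, seed = 1))
kobs  <- fit_relaxation(jump)$k_obs
rates <- activation_rate(kobs, 1 - pI)

# 3. global fit of six stopped-flow traces (CS + induced fit)
ds <- gen_stopped_flow(p$binding, confmodel:::preset_ligand_ladder(p),
                       E0 = 5e-7, noise = noise_model(0.004, seed = 1))
bind <- global_fit_binding(ds, scheme = "cs-if",
                           fixed = c(k_ia = rates$k_ina_act$value,
                                     k_ai = rates$k_act_ina$value), seed = 1)
```

Output of this exact script:

```
p_inactive = 0.038          # truth 0.05; +/-0.02 is the stated accuracy
k_obs      = 3.976e-04 /s   # truth 4.0e-04
k_ina_act  = 3.823e-04 /s   # truth 3.8e-04
k_act_ina  = 1.527e-05 /s   # truth 2.0e-05
K2         = 4.2 uM         # truth 4.4 uM (TSA dissociation constant)
KD_macro   = 1.52 uM        # K2(1+K1)/(1+1/K3)
K3         = 0.536          # truth 0.5 ([AL]/[AL*])
```

`K2` lands within 5% of the generating 4.4 μM even though the fixed
interconversion rates carry the NMR stage's own noise. Running
`scripts/acceptance.R` repeats this for all three variants: with seed 1 it
recovers K2 = 272, 16.3 and 4.2 μM against the generating
276 / 16.5 / 4.4 μM ladder — a 62.7-fold affinity gain over the lineage —
and reports a progress-curve `k_cat` median bias of 2.7% where the
initial-rate route is off by 79% at the same sub-saturating substrate
concentrations.

## Command line

A thin umbrella CLI ships in `inst/exec/confmodel`:

```
confmodel synth         --kind stopped-flow|progress|nmr|ph-jump --preset HG3.17 --seed 3 --out DIR
confmodel fit-binding   --manifest DIR --scheme cs-if --fix k_ia=3.8e-4,k_ai=2e-5 --out PREFIX
confmodel fit-progress  --manifest DIR --eps 4000 --fix k_ia=6e-4,k_ai=2e-4 --out PREFIX
confmodel interconvert  --mode relax --in ph_jump.csv --out PREFIX
confmodel tst-summary   --in summaries.csv --kuncat 1e-6 --ref HG3 --out PREFIX
```

Exit codes: 0 success, 2 validation error, 3 fit non-convergence. Datasets
are plain CSV plus a JSON manifest; generator truths live in a sidecar
`truth.json` that the fitting tools never read.

## Documentation

`vignettes/conformational-kinetics.Rmd` documents the models and their
assumptions, every numerical choice (integrator, tolerances, multistart,
variable projection, identifiability flags), the synthetic world's stated
parameters and what a green recovery test does and does not establish.
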