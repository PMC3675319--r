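# tim2iron

Kinetic modelling of iron uptake, storage and export through the mouse
H-ferritin receptor TIM-2 in TCMK-1 kidney cells.

Exogenous iron-loaded H-ferritin (Fe-HFt) binds membrane TIM-2, the
complex is internalised into an endosome, most of the ferritin is
degraded there — its iron joining the labile iron pool (LIP) — while a
fraction survives intact and degrades slowly; LIP iron is either stored
in endogenous ferritin or exported through ferroportin. `tim2iron`
implements this as a deterministic compartmental ODE model for ⁵⁵Fe
tracer and reproduces the associated analysis workflow: forward
simulation of the three in vitro protocols, synthetic triplicate data
generation, and joint parameter estimation across experiments.

## Model

State variables: labelled iron in the LIP (`x1`), endogenous-ferritin
iron (`x4`), free membrane TIM-2 capacity (`x6`), iron in membrane
receptor–ligand complexes (`x7`), endosomal TIM-2 capacity (`x8`),
surviving exogenous HFt iron (`x9`), the regulatory pools TfR1 (`x2`),
ferroportin (`x3`), IRPs (`x5`), and two media bookkeeping pools. The
TIM-2 pathway is

    dx6/dt = γ₆·x8 − α₇Ft·x6·φ
    dx7/dt = α₇Ft·x6·φ − F
    dx8/dt = F − γ₆·x8
    dx9/dt = α₉·F − γ₉·x9          with  F = γ₇·x7·K₄₇/(K₄₇ + x4 + x9)

where φ is the remaining-media fraction and the iron released at
endocytosis, `(1 − α₉)·F`, plus the slow-degradation flux `γ₉·x9`, feed
the LIP equation of the core iron-homeostasis model. Endocytosis slows
as intracellular ferritin accumulates, halving at the threshold `K₄₇`.
Estimation minimises the normalised error sum across all experiments,

    SSNE = Σⱼ (mⱼ − yⱼ)² / σⱼ²,

by Latin-hypercube multi-start Levenberg–Marquardt on log-scaled,
bounded parameters.

## Worked example

```r
library(tim2iron)
p <- table1_parameters()          # packaged reference rate constants

derive_quantities(p)
#> TIM-2 binding probability with Fe-HFt: 16.6% per min
#> Mean endosome formation time: 8.5 min
#> HFt surviving endocytosis: 28%
#> LIP export rate: 0.2% per min
#> Second-phase HFt degradation: 1.8% per h

# pulse-chase storage experiment: 2 h loading, wash, 48 h chase
traj <- simulate_protocol(build_protocol("storage", "tim2"), p,
                          times = seq(24, 48) * 60)
phase_two_decay_rate(observe(traj, "biotinylated_55fe"), c(24, 48) * 60)
#> [1] 0.0003200788
```

The derived quantities convert rate constants into their interpretable
forms: a free receptor has a 16.6% chance per minute of binding Fe-HFt;
a bound complex needs 8.5 min on average to internalise; 28% of
internalised ferritin survives endocytosis; the LIP loses 0.2% of its
label per minute to export. The decay rate read off the late chase
(3.2e-4/min) is the slow HFt degradation constant `gamma9` plus a small
residue of late endocytosis of surface-bound complexes.

Synthetic triplicate data and co-fitting:

```r
suite <- fixture_suite(seed = 1)            # uptake / storage / export
protocols <- list(uptake_tim2 = build_protocol("uptake", "tim2"),
                  uptake_vector = build_protocol("uptake", "vector"),
                  storage_tim2 = build_protocol("storage", "tim2"))
fit <- fit_timecourses(list(suite$uptake, suite$storage), protocols,
                       seed = 1)
derive_quantities(fit)
```

A thin command-line wrapper lives at `inst/cli/tim2iron.R`
(`Rscript inst/cli/tim2iron.R report`, `... generate --seed 7 --out data/`,
etc.); see `?run_pipeline`.

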