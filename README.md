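# sdaflux

Post-prandial energetics and nitrogen/acid–base budget analysis for small
aquatic animals.

When a fish eats, its metabolic rate rises transiently — the specific dynamic
action (SDA) — while protein catabolism drives a wave of ammonia excretion
and gastric acid secretion perturbs whole-animal acid–base balance. Studies
of these phenomena (for example in gastric proton-pump knockout or
proton-pump-inhibitor-treated fish) produce four kinds of raw data, and
`sdaflux` turns each of them into the summary statistics physiologists
compare between groups:

* **Intermittent-flow respirometry** — per-cycle oxygen consumption rates
  from sealed-phase O₂ declines, `ṀO₂ = −b·(V_chamber − V_fish)/M`; standard
  metabolic rate (SMR) as a low-quantile floor of late-record cycles; and the
  SDA response: net peak `max(ṀO₂) − SMR`, duration, and magnitude
  `∫(ṀO₂ − SMR)⁺ dt`, with quality control and activity/regurgitation
  exclusion rules.
* **Static flux chambers** — net fluxes `J_X = ([X]_f − [X]_i)·V/(M·t)` of
  total ammonia and titratable alkalinity, net acid–base flux
  `J_TAlk − J_TAmm`, cumulative above-baseline ammonia budgets, NH₃/NH₄⁺
  speciation, and an oxygen-cost model for gastric acid secretion
  (`cost = acid load / ρ` with ρ the H⁺:O₂ pump stoichiometry).
* **Growth trials** — specific growth rate `G = 100·(ln M₂ − ln M₁)/Δt`,
  feed conversion ratio, Fulton's condition factor `K = 100·M/L³`.
* **qPCR Ct tables** — relative expression by `2^−ΔΔCt` with multi-reference
  geometric-mean normalization.

A seeded synthetic-data generator (`sim_config()` and the `simulate_*`
functions) emulates every one of these inputs with recorded ground truth, so
the whole pipeline is covered by parameter-recovery and round-trip tests. A
thin statistics layer (`compare_groups()`, `rm_anova()`) reproduces the
conventional testing cascade (Shapiro–Wilk → Levene → Student/Welch/Wilcoxon,
and repeated-measures ANOVA with Tukey week contrasts) with an auditable
decision trail.

## Worked example

Simulate a small two-genotype cohort, run the full respirometry pipeline,
and compare the groups:

```r
library(sdaflux)

cfg   <- sim_config(n_per_group = 4)
study <- simulate_respirometry_study(cfg, seed = 7)
res   <- sda_table(lapply(study$traces, analyze_sda))

analyze_sda(study$traces$wt01)
#> <sda_result> animal wt01 (wt)
#>   SMR       5.067 umol O2 g-1 h-1
#>   SDA       0.08 -> 14.58 h (duration 14.50 h)
#>   net peak  2.694 umol O2 g-1 h-1
#>   magnitude 22.578 umol O2 g-1
```

`analyze_sda()` chains the three respirometry stages: `compute_mo2()`
regresses each sealed cycle's O₂ decline (here 96 cycles over 24 h, all
passing QC), `estimate_smr()` takes the smoothed low-quantile floor of the
final quarter of the record, and `extract_sda()` finds where the rate returns
to within 10% of SMR. For this animal the response lasted 14.5 h, peaked
2.69 µmol O₂ g⁻¹ h⁻¹ above an SMR of 5.07, and integrated to an SDA
magnitude of 22.6 µmol O₂ g⁻¹.

Group summaries and the variance-robust comparison:

```r
with(res, tapply(smr, genotype, mean))
#>       ko       wt
#> 4.967394 5.405834
compare_groups(res$magnitude[res$genotype == "wt"],
               res$magnitude[res$genotype == "ko"], policy = "welch")
#> <comparison_result> Welch t: statistic 1.493, df 5.68, p = 0.1888
#>   trail: policy: welch | test: welch
```

At n = 4 per group the ~21% magnitude contrast built into the generator is
not yet resolvable (p = 0.19); the acceptance analysis below runs the same
contrast at the study scale of 12 + 12, where it is.

Pricing an acid load of 2.82 µmol H⁺ g⁻¹ at the ideal 5 H⁺ : O₂ pump
stoichiometry against an SDA magnitude of 21.47:

```r
acid_cost(h_o2_ratio = 5, acid_load = 2.82, sda_magnitude = 21.47)
#> <acid_cost> load 2.820 umol H+ g-1, H+:O2 = 5.0
#>   O2 cost  0.564 umol O2 g-1
#>   share    2.6% of SDA magnitude
```

Direct acid secretion accounts for only ~2.6% of the post-prandial response —
the core quantitative argument that reduced SDA in achlorhydric animals
reflects impaired protein handling rather than the missing pump work itself.

See the vignette (`vignettes/postprandial-energetics.Rmd`) for the models,
parameter defaults and design rationale.

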