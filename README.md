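# dynbridge

Dynamic-network analysis of comorbid depression and anxiety from
ecological momentary assessment (EMA) data. The package is for
researchers in network psychometrics and psychiatric epidemiology who
want to test the *bridge symptom hypothesis* — that mental states shared
by two disorders funnel activation between their symptom clusters — with
temporal (lagged) rather than cross-sectional networks.

## What it computes

Seven momentary mental states (1–7 scale) are tracked across three
diagnostic groups. Within persons, dynamics follow a latent-mean-centered
multilevel VAR(1) on a 180-minute lattice,

    y_it − μ_i = Φ_i (y_i,t−1 − μ_i) + ε_it,   ε_it ~ N(0, Σ),

with person-level random effects on all 49 lagged coefficients and 7
means, and group dummies at the between level, so each group g has an
average network Φ⁽ᵍ⁾. The model is fitted by a Gibbs sampler (2 chains)
with forward-filter/backward-sample imputation of missing lattice cells
(nights, missed prompts).

The headline statistic is the **bridge effect** of a candidate node b:
the sum over all qualifying lag-2 paths i → b → j (start and end at
different non-bridge nodes, crossing between clusters) of
φ⁽ᵍ⁾_{b←i} · φ⁽ᵍ⁾_{j←b}, evaluated at every posterior draw. With the
7-item catalog the path counts are 22 (overlapping bridge), 24 (pure
anxiety) and 26 (pure depression); the **mean bridge effect**
(bridge effect / path count) makes nodes comparable. Group differences,
one-tailed posterior probabilities, and comparison-to-best rankings are
all drawwise posterior functionals.

Because the motivating cohort data are access-restricted, the package
includes a synthetic-panel generator that reproduces the study design
(group sizes 143/40/37, 5 prompts/day × 14 days at 3-hour intervals with
night gaps, prompt jitter, 8% nonresponse) with a known multilevel
VAR(1) ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(dynbridge)

# a small three-group panel with known dynamics (30 persons/group)
fx <- make_fixtures("small")
panel   <- reverse_code(fx$panel)       # flip CHE and REL to 8 - score
gridded <- align_to_grid(panel, 180)    # snap prompts to the 180-min lattice

fit <- fit_mlvar(gridded, mlvar_spec(chains = 2, iterations = 2000, seed = 1))
psr_diagnostic(fit)                     # split-chain R-hat per parameter

effects <- bridge_effects(fit)
effects[["WOR"]][["comorbid"]]
#> bridge WOR (comorbid): 0.0630 [0.0111, 0.1185], one-tailed p = 0.007 * (paths = 22)

compare_groups(effects[["WOR"]][["comorbid"]], effects[["WOR"]][["anxiety_only"]])
#> delta(WOR) comorbid - anxiety_only: 0.0754 [0.0154, 0.1377], p1 = 0.003 *

head(rank_bridges(lapply(item_catalog()$code,
                         function(b) effects[[b]][["comorbid"]])), 3)
#>   bridge    group count mean_effect            lo          hi p_one_tailed is_best differs_from_best rank
#> 1    WOR comorbid    22 0.002863316  5.030365e-04 0.005386600       0.0070    TRUE             FALSE    1
#> 2    DOW comorbid    26 0.001595435 -1.574501e-04 0.003602803       0.0515   FALSE             FALSE    2
#> 3    REL comorbid    24 0.001264954 -3.456666e-05 0.002965394       0.0320   FALSE             FALSE    3
```

The first line reads: summed over the 22 qualifying indirect paths
through worrying, the comorbid group's posterior-mean bridge effect is
0.063 with a 95% credible interval excluding zero — worrying funnels
activation between the clusters in that (synthetic) group. The ranking
table divides by path counts so nodes with different counts compare
fairly (worrying tops the comorbid ranking here); `differs_from_best`
flags nodes whose drawwise difference from the top node excludes zero.

The full pipeline (simulate/load → preprocess → fit → bridge summaries →
CSV/JSON reports with a checksummed manifest) is one call —
`run_pipeline(pipeline_config(out_dir = "out", seed = 1))` — or one shell
command via `exec/dynbridge run --out out --seed 1`.

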