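---
title: "Bridge effects in dynamic mental-state networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridge effects in dynamic mental-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynbridge)
```

## The scientific question

Depression and anxiety co-occur far more often than chance. One network-
theoretic explanation is that particular *bridge symptoms* — experiences
shared by both disorders, such as worrying or irritability — transmit
activation from one symptom cluster to the other. dynbridge implements a
dynamic (temporal) test of that idea on ecological momentary assessment
(EMA) data: repeated momentary self-reports collected several times a day
over weeks.

Seven momentary mental states are tracked, each on a 1–7 scale:

```{r}
item_catalog()
```

Three items belong to the depression cluster only, two to the anxiety
cluster only, and two (worrying, feeling irritated) to both. "Not
cheerful" and "not relaxed" come from positively worded prompts and are
reverse-coded (`8 - score`) before analysis so that higher always means
worse.

## The dynamic model

The within-person dynamics are a first-order vector autoregression on an
equally spaced time lattice,

$$ y_{it} - \mu_i \;=\; \Phi_i\,(y_{i,t-1} - \mu_i) + \varepsilon_{it},
   \qquad \varepsilon_{it} \sim N(0, \Sigma), $$

where $y_{it}$ is person $i$'s 7-vector of states at lattice slot $t$,
$\mu_i$ the person's latent mean profile, and $\Phi_i$ the person's
$7\times 7$ matrix of autoregressive (diagonal) and cross-lagged
(off-diagonal) coefficients, entry $\phi_{j\leftarrow k}$ giving the
effect of state $k$ at $t-1$ on state $j$ at $t$.

All 49 coefficients and all 7 means receive person-level Gaussian random
effects. At the between level their means are regressed on diagnostic
group dummies (comorbid = reference), so every group has its own average
network $\Phi^{(g)}$ and group contrasts are available drawwise:

$$ \Phi^{(\mathrm{comorbid})} = \gamma_0,\qquad
   \Phi^{(g)} = \gamma_0 + \gamma_g \ \text{entrywise.} $$

Estimation is by Gibbs sampling (two independent chains by default). The
centering uses the *latent* person means, i.e. $\mu_i$ is estimated
inside the model rather than subtracting each person's observed average;
observed-mean pre-centering is known to bias lagged coefficients at
EMA-typical series lengths.

### Unequal spacing and missing data

Real prompts drift around their nominal times and nights are unobserved.
Records are therefore snapped onto a fixed lattice (180 minutes by
default): each answered record goes to its nearest slot
(`round((t - t0)/delta)`, ties away from zero, person-local origin at the
first answered prompt), intervening slots become explicit missing cells,
and two records falling into one slot keep the earlier one (the drop is
logged). The exact binning rule used by commercial DSEM implementations
is not published; nearest-slot rounding preserves the median spacing and
is easy to reason about, which is why it is the package's rule. After
alignment, a lag-1 coefficient always refers to an (approximately)
180-minute interval.

Missing cells — nights, missed prompts, collision drops — are not
deleted: at every MCMC iteration the sampler draws them from their exact
full conditional by forward-filtering/backward-sampling each person's
state sequence given the current $(\Phi_i, \mu_i, \Sigma)$. The number of
imputed cells is constant over iterations and recorded in the fit object.
Cells before a person's first or after their last observation are
trimmed, not extrapolated.

### Priors and numerical choices

* Between-level regression coefficients: $N(0, 10^2)$ — a proper
  stand-in for flat priors; the data dominate at study scale.
* Random-effect variances: Inverse-Gamma(0.001, 0.001), one per
  parameter; the 56-dimensional random-effect covariance is diagonal. A
  full covariance of that size is not estimable with a few hundred
  persons, and nothing downstream uses its off-diagonals.
* Innovation covariance $\Sigma$: full $7\times 7$, shared across
  persons and groups, with an Inverse-Wishart(9, I) prior. (A scalar
  inverse-gamma family does not define a conjugate prior for a full
  covariance, so the Wishart family is used for this one block.)
* Defaults: 2 chains × 4000 iterations, 50% burn-in, no thinning.
  Convergence is screened with split-chain potential scale reduction
  (threshold 1.1); failures warn and list the worst parameters rather
  than aborting.
* Person-level stationarity is screened, not enforced: the sampler
  aborts only on numerical divergence, with chain/iteration context.

## The bridge effect

For a candidate bridge node $b$, a lag-2 indirect effect
$i \rightarrow b \rightarrow j$ qualifies when it starts and ends at
different non-bridge nodes and crosses between clusters — there must be a
role assignment with $i$ acting for one cluster and $j$ for the other.
Pairs whose endpoints are both pure members of the same cluster are
excluded; each qualifying *ordered* pair counts once, even when two
overlapping endpoints would qualify under both role directions. The
*bridge effect* is the posterior functional

$$ B^{(g)}(b) \;=\; \sum_{(i,j)} \phi^{(g)}_{b\leftarrow i}\,
   \phi^{(g)}_{j\leftarrow b}, $$

evaluated at **every retained draw**, which yields its full posterior —
means, central 95% credible intervals, and one-tailed posterior
probabilities (the smaller of $\Pr(B\le 0)$ and $\Pr(B\ge 0)$). Because
the path counts differ by bridge kind (22 for an overlapping bridge, 24
pure-anxiety, 26 pure-depression), cross-node rankings use the *mean
bridge effect* $B/\text{count}$:

```{r}
sapply(item_catalog()$code, function(b) enumerate_bridge_paths(b)$count)
```

Group differences are drawwise subtractions on aligned draws (automatic,
since all groups derive from shared between-level draws). Rankings
identify the node with the highest posterior-mean mean-bridge-effect and
flag every other node whose drawwise difference from that best node has a
95% interval excluding zero; ties for the best point estimate are broken
by catalog order with a warning. Central (equal-tailed) intervals are
used throughout rather than HPD intervals, matching standard DSEM output.

Two conventions deserve a note. The source literature is internally
inconsistent about which items are the "original" bridge states (one
passage names worrying and feeling down; the rest names worrying and
feeling irritated); the package follows the reading consistent with the
printed path counts, under which the overlapping items — worrying and
feeling irritated, 22 paths each — are the a priori bridges. And since
the literature reports $p$ values without defining their sidedness, both
one- and two-tailed posterior probabilities are emitted for differences.

## What the synthetic generator emulates — and what it does not

The empirical data this design emulates are access-restricted, so the
package ships a generator whose defaults reproduce the *study
conditions*: three diagnostic groups (comorbid $n=143$, depression-only
$n=40$, anxiety-only $n=37$); 5 prompts/day at 180-minute intervals for
14 days (70 prompts max) with 10-minute prompt jitter (median realized
spacing ≈ 183 min); 8% missed prompts (matching a mean of ~64.5 completed
assessments); group mean profiles and innovation scales placed at the
published person-mean and within-person-SD descriptives; and group
coefficient matrices *qualitatively* shaped like the published group
networks (densest and bidirectional in the comorbid group, a sparse
one-directional depression→worry→anxiety chain in the depression-only
group, the strongest worry autocorrelation in the anxiety-only group;
autoregressive entries 0.2–0.36, positive cross effects 0.05–0.13). The
true coefficient matrices are illustrative ground truth for testing, not
estimates of any empirical network.

The latent process advances through unobserved night slots rather than
restarting each morning, matching the equal-interval model the estimator
assumes. Person heterogeneity is Gaussian per entry (SD 0.05 for
coefficients, 0.8 for means), with non-stationary draws rejected and
redrawn (at most 100 times, then an error naming the group). Severity
metadata is a noisy monotone function of the person's mean state — it
exists to exercise subgroup filters, not as a joint model of symptom
severity. Continuous emission is the default because the analysis model
treats the items as continuous; 1–7 rounding (`likert = TRUE`) is
available for robustness exercises, and parameter-recovery statements are
made for the continuous case.

Passing recovery tests on these panels shows the estimator recovers the
generating process *under the model's own assumptions* (linear dynamics,
Gaussian innovations, missingness unrelated to state). They cannot show
robustness to ordinal measurement, floor effects on rare symptoms,
time-of-day cycles, or state-dependent nonresponse — all present in real
EMA data and all outside this model, as they are outside the model the
design emulates.

## Stationarity screening

Each person × item series (observed subsequence of the gridded series) is
screened with the KPSS level-stationarity test — null hypothesis:
stationary around a constant level — using a Bartlett-kernel long-run
variance with the deterministic truncation
$\lceil 12 (n/100)^{1/4} \rceil$; the statistic agrees with the standard
reference implementation to $10^{-9}$ on shared fixtures. Series shorter
than 20 observed points are marked untestable and excluded from the
per-item stationary fractions. An exactly constant series is defined
stationary (statistic 0). Following the emulated design, screening
informs but does not gate the fit, and no detrending is applied.

## Problem sizes used by the shipped checks

The packaged test suite keeps simulation sizes at desk scale, chosen once:
the least-squares equivalence check uses one group of 50 persons × 56
complete slots (2 × 2000 iterations), three-group recovery uses the
`make_fixtures("small")` panel (30 persons/group on the full 70-prompt
design with nights, jitter and 8% nonresponse; person-coefficient SD
0.05), null calibration uses three groups of 20 on a gap-free 56-slot
lattice, and the interval-coverage study runs 100 replicates of 8 persons
× 40 slots. The recovery tolerance (±0.05 on ≥90% of entries) sits at
the information limit of 30-person groups — posterior SDs there are
≈0.03, so that check certifies calibration as much as precision.

## Known limitations

* Discrete-time model: coefficients refer to the 180-minute lattice
  interval; no continuous-time (differential-equation) translation.
* No ordinal measurement model; Likert rounding is treated as noise.
* Diagonal random-effect covariance and a shared innovation covariance —
  deliberate simplifications, documented above.
* Bridge effects are on the raw coefficient scale (no standardization),
  so cross-study comparisons require comparable scales and intervals.
* Subgroup sensitivity analyses refit the model on the filtered panel;
  severity tertiles use sample terciles with ties going to the lower
  tertile.
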