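# boaspom

Bayesian extinction-risk assessment for plant metapopulations with a soil
seed bank, observed through yearly presence/absence inventories.

## The problem

Annual plants living in lines of small, frequently disturbed patches —
the motivating case is the spontaneous flora of street tree bases, which
gardeners clear every year — persist through a balance of local
extinction, recolonisation from the two neighbouring patches, and seeds
that lie dormant in the soil for several years.  Surveys of such systems
record only which patches show standing plants each year.  `boaspom`
answers, from those records alone: *can this species survive and spread
through these patches on its own, or does it persist only because seeds
keep arriving from outside?*

## The model and metrics

The package implements the **Best Occupancy Achievable (BOA) process**, a
stochastic patch occupancy model on a line of `N` patches.  Each
generation, patches with viable seeds (age ≤ `H + 1`, where `H` is the
maximal dormancy duration) grow plants; each patch with plants is wiped
with probability `p_ext`; survivors re-seed their own and both
neighbouring patches.  A noisy variant adds a parameter `ε`: after the
extinction step every plant-free patch shows plants with probability `ε`,
buffering false positives and weak external colonisation.  The process
has a critical threshold `p_c(H)`: for `p_ext > p_c(H)` the
metapopulation dies out almost surely, below it survives and spreads
with positive probability.

Observing presence/absence after the extinction step makes the process a
hidden Markov model whose exact likelihood the package evaluates in
closed form, and a Metropolis-within-Gibbs sampler returns the posterior
`P(s, p_ext, H, ε | Obs)` (with `s`, `p_ext` per street portion and `H`,
`ε` shared across portions of a species; missing survey entries are
handled by data augmentation).  Risk metrics computed from the posterior
and a Monte-Carlo table of `p_c(H)`:

* `GER  = P(p_ext > p_c(H) | Obs)` — global extinction risk;
* `H_inf` — smallest dormancy duration not rejected at the 5% level;
* `MaxGER = P(p_ext > p_c(H_inf) | H = H_inf, Obs)` — risk at the most
  pessimistic plausible dormancy duration;
* `LER` — posterior mean of `p_ext` (local risk);
* `SMD` — standardised mean difference of `p_ext` between two portions.

## Worked example

```r
library(boaspom)

# simulate ten years of surveys of one street portion (50 tree bases)
truth <- boa_params(s = 0.5, p_ext = 0.55, H = 2)
traj  <- boa_simulate(truth, N = 50, T_gen = 10, seed = 1)

# posterior sampling under the noisy BOA model
fit <- fit_posterior(metapop_dataset(traj$obs, species = "example"),
                     inference_config(epsilon_max = 0.05, seed = 2))
summary(fit)

# extinction risk against the shipped critical-threshold table
risk_report(fit, default_pc_table())
```

The summary prints the per-portion posterior of `p_ext` and the
distribution of `H`:

```
Posterior summary (2000 draws)
Per-segment patch extinction probability:
   segment s_mean  s_sd p_ext_mean p_ext_sd p_ext_lo p_ext_hi
1 segment1  0.511 0.123      0.597   0.0261    0.548    0.646
P(H = h | Obs):
    0     1     2     3     4     5     6     7     8     9    10
0.000 0.000 0.841 0.078 0.016 0.018 0.010 0.013 0.009 0.010 0.006
P(H >= 1 | Obs) = 1.000
epsilon: mean 0.0105 (95% CI 0.0004-0.0353)
```

Both true parameters are recovered: the posterior mean of `p_ext` is
0.597 (truth 0.55) and 84% of the posterior mass of `H` sits on the true
value 2.  The risk report reads

```
  species  segment GER MaxGER H_inf   LER n_cond maxger_fallback
1 example segment1   0      0     2 0.597   1682           FALSE
```

the local extinction risk is high (`LER` ≈ 0.6: each patch loses its
plants most years), yet the street-scale risk is null: even at the
shortest plausible dormancy duration (`H_inf = 2`, critical threshold
`p_c(2) = 0.744`) the posterior leaves no mass above the threshold, so
the seed bank lets the metapopulation persist and spread without
external seed input — the signature pattern the MaxGER metric is built
to detect.

A thin command-line wrapper around the same functions ships in
`inst/scripts/boa` (subcommands `simulate`, `corrupt`, `pc-table`,
`fit`, `risk`, `evaluate`).

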