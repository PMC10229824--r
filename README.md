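# erpdcm

Dynamic causal modelling of two-region evoked responses in R: infer the
directed (effective) connectivity between the medial cerebellar nucleus
(MCN) and the ventrolateral periaqueductal gray (vlPAG) from event-related
potentials (ERPs) recorded at the offset of a conditioned tone, and relate
the strength of that coupling to extinction progress and freezing
behaviour.

The package is aimed at systems neuroscientists who have (or simulate)
paired subcortical LFP recordings and want a fully scripted, testable
version of the evoked-response DCM workflow: preprocessing, generative
modelling, Bayesian inversion, group model selection, and a hierarchical
second level over connection strengths.

## The model in brief

Each region is a three-population neural mass (output, excitatory
interneuron, inhibitory interneuron). A receptor channel converts
presynaptic firing rate into membrane potential by convolution with the
alpha kernel

    p(t) = A (H/tau) t exp(-t/tau),      tau_e = 8 ms, tau_i = 16 ms

and population potential maps to normalized firing rate through the odd
sigmoid `S(V) = 1/(1+exp(-0.56 V)) - 1/2`. Conduction delays are 2 ms
within and 16 ms between regions; the tone-offset stimulus is a pair of
Gaussian bumps (onsets 10/40 ms, dispersions 8 ms) driving both regions;
each region is observed as a scalar gain times its output population's
potential, at 1 kHz on the 1-200 ms window.

Five extrinsic-connectivity hypotheses (glutamatergic targets only the
output population; plus GABAergic; all populations; all in both
directions; or no coupling at all) are fitted per subject by variational
Laplace (`fit_dcm`), compared by random-effects Bayesian model selection
with exceedance probabilities (`rfx_bms`), and the winning model's two
coupling strengths are regressed on [mean, trial block, freezing %] in a
parametric empirical Bayes second level (`fit_peb`) pruned by Bayesian
model reduction (`bmr`, `compare_reduced_models`).

Because paired recordings of this kind are not public, `generate_cohort()`
produces ground-truth cohorts (6 subjects x 5 blocks x 7 trials at 10 dB
trial SNR by default) whose couplings covary with block and freezing, so
the whole pipeline is validated by parameter-recovery studies.

## Worked example

```r
library(erpdcm)
ms <- build_model_space()

## simulate one extinction block with a known forward coupling (+0.5 on the
## latent log scale), 7 trials at 10 dB, and invert under M1
clean  <- simulate_erp(ms$M1, c(A_MCN_to_vlPAG = 0.5))
trials <- make_noisy_trials(clean, 7, snr_db = 10)   # uses the current RNG
data   <- erp_pair(clean$time_ms, apply(trials, c(1, 2), mean), n_trials = 7)
fit    <- fit_dcm(data, ms$M1)
fit
#> <dcm_fit> variant M1: F = 329.96 nats, 7 iterations, converged
#>   A_MCN_to_vlPAG: 0.504 (sd 0.260)
#>   A_vlPAG_to_MCN: -0.182 (sd 0.313)
```

(output from `set.seed(7)` before `make_noisy_trials`; the perturbed
forward connection is recovered near its true value and clearly above the
unperturbed return connection).

A full second-level analysis on a synthetic cohort with a negative
freezing effect (-0.05 per percentage point) injected on the MCN-to-vlPAG
connection:

```r
coh  <- generate_cohort(cohort_config(seed = 1), ms$M1)
fits <- lapply(coh$erps, fit_dcm, variant = ms$M1)
peb  <- fit_peb(fits, build_design(coh$covariates))
cmp  <- compare_reduced_models(peb)
round(cmp$probability, 3)
#> mean + trial + freezing         mean + freezing            mean + trial
#>                   0.934                   0.066                   0.000
#>               mean only
#>                   0.000
cmp$bma$mu["A_MCN_to_vlPAG:freezing"]
#> A_MCN_to_vlPAG:freezing
#>             -0.04546
posterior_prob_nonzero(cmp, "A_MCN_to_vlPAG:freezing")
#> [1] 1
```

The full model (trial + freezing) wins, the injected freezing slope is
recovered (-0.045 vs -0.05 truth) with posterior probability > 0.95, and
the uninjected return direction stays below threshold.

## Command line

`inst/cli/erpdcm.R` exposes `simulate`, `preprocess`, `forward`, `invert`,
`bms` and `peb` subcommands over CSV/JSON files; see the header of that
script for usage.

## Documentation

The methods vignette (`vignettes/two-region-dcm.Rmd`) describes the model
and its assumptions, the priors and numerical choices, what the synthetic
cohort does and does not emulate, and the design decisions taken where the
specification of this circuit is genuinely open.
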