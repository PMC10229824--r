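---
title: "Modelling cerebellar-periaqueductal gray evoked responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebellar-periaqueductal gray evoked responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdcm)
```

## The scientific problem

During fear extinction, the medial cerebellar nucleus (MCN) and the
ventrolateral periaqueductal gray (vlPAG) generate event-related potentials
(ERPs) time-locked to the offset of a conditioned tone. The question this
package addresses is *directed*: how strongly does each region drive the
other, and how does that effective connectivity covary with extinction
progress (block number) and with freezing behaviour? Correlational measures
cannot answer this; instead a biophysical generative model of the two
coupled regions is fitted to the ERP waveforms by Bayesian inversion, and
hypotheses about the anatomy of the coupling are compared by their model
evidence.

`erpdcm` implements the full chain: LFP preprocessing, the neural-mass
forward model, variational-Laplace inversion, random-effects Bayesian model
selection (BMS), and a parametric empirical Bayes (PEB) second level with
Bayesian model reduction (BMR). Because paired MCN-vlPAG recordings of
this kind are not publicly available, the package ships a synthetic-cohort generator with
known ground truth; every downstream claim is validated by recovery studies
against that ground truth.

## The generative model

Each region is a three-population neural mass: an output (projection)
population, an excitatory interneuron (relay) population and an inhibitory
interneuron population. Synaptic dynamics follow the classical convolution
formulation: the membrane potential contributed by each receptor channel is
the convolution of presynaptic firing rate with the alpha kernel

$$p(t) = A \frac{H_{e/i}}{\tau_{e/i}}\, t\, e^{-t/\tau_{e/i}},$$

with maximum post-synaptic potential $H$ and time constant $\tau$ (8 ms
for excitatory/AMPA channels, 16 ms for inhibitory/GABA-A). As a
state-space system each channel obeys
$\ddot v = (H/\tau)u - (2/\tau)\dot v - v/\tau^2$. Population firing rate
is the odd sigmoid $S(V) = 1/(1+e^{-rV}) - 1/2$ with fixed curvature
$r = 0.56$. Conduction delays are 2 ms within a region and 16 ms between
regions. The stimulus (tone offset) drives the excitatory-interneuron
population of both regions through two Gaussian bumps (onsets 10 and 40 ms,
dispersions 8 ms). The observed LFP of a region is a scalar lead-field
gain times its output population's composite potential, sampled at 1 kHz on
the 1-200 ms window.

Five hypotheses about the extrinsic (between-region) coupling form the
model space (`build_model_space()`): M1 couples the regions through
glutamatergic projections onto the output populations (the vlPAG-to-MCN
projection is "IO-type", terminating on the MCN relay population); M2 adds
the GABAergic population as an MCN-to-vlPAG target (prior rate 1/2 per
target); M3 targets all vlPAG populations (rate 1/8); M4 applies
all-population targeting in both directions; M5 is the null model with no
extrinsic coupling (those parameters are pinned to zero with zero prior
variance and excluded from the free set). An optional inhibitory
self-connection on the inhibitory interneurons ("ii-to-ii") is available in
both sources; the default is off, matching the architecture that model
selection favours for this circuit.

### Free parameters and priors

Every physical parameter is its prior mean times $e^\theta$, so inference
runs on the latent log-scale with Gaussian priors centred at zero. Prior
variances are 1/2 for the quantities of interest (extrinsic coupling per
direction, input amplitudes, lead-field gains) and 1/16 for biophysical
constants (intrinsic gains, $H$ scalings). The extrinsic prior *rates*
(1, 1/2, 1/8) encode the specificity of each targeting hypothesis (the
more populations a projection reaches, the smaller its per-target rate); time constants,
delays and the sigmoid curvature are fixed constants, not estimated.

### Constants the literature does not pin down

No published values exist for this circuit's intrinsic gains or for the
absolute scale of its extrinsic coupling. They were fixed once from a small-signal
loop-gain analysis (sigmoid slope $r/4$ at rest, channel DC gain
$H\tau$ per unit coupling): intrinsic gains (0.15, 0.15, 0.15, 0.05) and a
fixed extrinsic scale of 0.05 keep every feedback loop's gain below unity
at the prior means and leave a stability margin for parameters several
prior SD away, while giving the extrinsic connections a clearly visible
waveform footprint (~15-25% of waveform variance in M1). The default input
amplitude (0.25 per component) puts simulated deflections at a few mV with
moderate sigmoid engagement. Because the sigmoid saturates, waveforms
remain finite for any parameter setting; extreme couplings merely saturate.

### Numerics

Integration is a fixed-step Heun (explicit trapezoid) scheme at
dt = 0.1 ms with a per-population history buffer for the delays; both Heun
stages sample the history on the step grid, so delayed firing rates are
memoized exactly when delays are multiples of dt (the default), with linear
interpolation otherwise. Against an independent fine-grid convolution
oracle the channel response is accurate to well under 1% of peak, and
halving dt changes trajectories by under 0.5%.

## Inversion

`fit_dcm()` is a Gauss-Newton / EM ascent on the variational (Laplace)
free energy: accuracy is the Gaussian log-likelihood of the residuals at
the posterior mean under noise precision $e^\lambda$; complexity is the KL
divergence from prior to posterior; $\lambda$ carries a Gaussian prior
(mean tuned to the data variance, variance 1) and is updated by a 1-D
Newton M-step each iteration. Jacobians are central finite differences
(step $10^{-3}$ on the latent scale). Levenberg-style damping guarantees
that only free-energy-increasing steps are accepted, so the recorded trace
is monotone and the best-so-far posterior is returned; convergence is
declared after four consecutive iterations improving by less than 0.01
nats (at most 64 iterations). With noiseless residuals the M-step is
floored at a relative noise power of $10^{-10}$ to keep $e^\lambda$ finite.

## Model selection and the second level

Fixed-effects BMS pools free energies; random-effects BMS follows the
variational Dirichlet scheme over population model frequencies
(Dirichlet(1) prior, responsibilities iterated to $10^{-4}$), with
exceedance probabilities estimated from $10^5$ seeded Dirichlet draws. For
two models the estimate agrees with the regularized-incomplete-beta closed
form. A practical note: with six subjects all preferring one model by a
wide margin, the concentration reaches (7, 1, 1, 1, 1), whose true winner
exceedance is about 0.97 -- a ceiling implied by the update itself.

The PEB second level regresses the two extrinsic log-couplings on a design
of [group mean, centred block index, centred freezing]. Each first-level
posterior enters through its full Gaussian density; because those
posteriors are shrunk toward the first-level prior, that prior is divided
out of each row's likelihood before the second-level (empirical) prior is
applied -- without this, injected slopes are attenuated by roughly half.
Covariate columns are standardized internally so the coefficient prior
(variance 1/2 per 1-SD covariate change) is unit-invariant; results are
reported in user units, and the reported evidence is unchanged by this
reparametrization. The random-effect precision is a single scalar with a
log-normal hyperprior (mean log 32, variance 1), profiled by 1-D
optimization of the exact linear-Gaussian evidence. BMR re-evaluates the
evidence under reduced priors analytically (verified in the tests against
a from-scratch evidence computation), the reduced-model space enumerates
on/off combinations of the trial and freezing columns, and reported
posterior probabilities come from Bayesian model averaging over that set
-- which is also what keeps the false-positive rate on null cohorts
controlled: with no injected effects the mean-only model dominates and the
averaged coefficients collapse toward zero. The 0.95 threshold is applied
only when reporting.

## The synthetic cohort: what it emulates, and what a green test establishes

`generate_cohort()` mirrors a typical cued-fear-extinction recording
session for this preparation: 6 subjects, 5 extinction blocks, 7 trials
per block. Each cell's latent log coupling is
a linear model in centred block index and centred freezing plus a
per-subject offset (SD 0.1); the forward model simulates the ERP and
i.i.d. Gaussian trial noise is added at 10 dB per-channel SNR (an AR(1)
option exists but is off by default), with the 7 trials averaged as in
standard ERP practice. Freezing declines linearly from 80% to 10% with 10
percentage points of block noise and, importantly, per-subject start/end
heterogeneity (SD 10 points): without between-animal variation the block
index and the freezing trajectory are ~97% collinear and no second-level
method could separate their effects. The injected effects are -0.05 per
freezing percentage point (the scale the validation studies prescribe) and
-0.4 per block on the MCN-to-vlPAG direction, sized by a design power
analysis (z of roughly 6 and 3 respectively at the measured first-level
posterior uncertainty of ~0.25-0.45).

The generator emulates none of the following, so green tests say nothing
about them: spike trains or vocalizations, acquisition-phase dynamics,
electrode drift or artifacts, 50 Hz contamination, non-Gaussian or
correlated noise (by default), or between-region differences in noise
level. A green recovery test establishes that *if* data were generated by
this model family at this SNR, the pipeline identifies the generating
architecture and the injected covariate structure -- not that the in-vivo
conclusions are correct.

## Preprocessing

`decimate()` applies an order-8 zero-phase Butterworth anti-alias low-pass
at a quarter of the target rate before subsampling (30 kHz to 1 kHz in one
step or in stages -- the tests check cascade equivalence). `bandpass()` is
the 1-32 Hz order-4 Butterworth, realized as the forward-backward
(squared-magnitude) response applied in the frequency domain with
reflection padding: exactly zero-phase, because phase distortion would
shift the ERP latencies the model fits. Epochs are averaged on a 1 ms grid
time-locked to tone offset; channel selection takes the largest
peak-to-trough amplitude within 1-200 ms, ties to the lowest index.

One measured limitation: this package's model ERPs carry a net-area (DC)
component that an AC-coupled in-vivo recording would not, and the 1 Hz
high-pass removes it. The preprocessing chain reproduces an ideally
band-limited copy of the generating ERP to better than 0.1% nRMSE, but
differs from the *raw* generating waveform by 11-12%, almost entirely from
that high-pass. The tests assert the band-limited comparison tightly and
keep a 15% envelope on the raw comparison.

## Design choices on genuinely open points

* **M3 vs M4.** The model space's two "all"-targeting variants are not
  structurally distinguished by the anatomy alone; here M3 keeps the
  IO-type return projection and M4 applies all-population targeting in both
  directions. The builder accepts an override.
* **Input targeting.** The stimulus enters the excitatory-interneuron
  population of both regions; the circuit offers no stronger constraint
  than that both regions respond to the stimulus.
* **Trial covariate.** Encoded at block resolution (index 1-5, centred),
  one first-level model per block.
* **BMA vs best reduced model.** Reported posterior probabilities average
  over the reduced-model set (toggleable by calling
  `posterior_prob_nonzero()` on a single `reduced_model` instead).
* **Freezing trajectory defaults.** 80% to 10% spans high-to-low freezing;
  no numeric trajectory is published, and the validation studies rest on
  recovery of injected effects, not on matching a figure.

## Worked example

```{r example, eval = FALSE}
ms <- build_model_space()

# one synthetic block at known coupling, inverted under M1
truth <- c(A_MCN_to_vlPAG = 0.5)
clean <- simulate_erp(ms$M1, truth)
trials <- make_noisy_trials(clean, 7, snr_db = 10)
data <- erp_pair(clean$time_ms, apply(trials, c(1, 2), mean), n_trials = 7)
fit <- fit_dcm(data, ms$M1)
fit$posterior$mean["A_MCN_to_vlPAG"]

# a full cohort through the second level
coh <- generate_cohort(cohort_config(seed = 1), ms$M1)
fits <- lapply(coh$erps, fit_dcm, variant = ms$M1)
peb <- fit_peb(fits, build_design(coh$covariates))
cmp <- compare_reduced_models(peb)
cmp$probability
posterior_prob_nonzero(cmp, "A_MCN_to_vlPAG:freezing")
```

## Known limitations

* No dopaminergic or other neuromodulatory population; no climbing-fiber
  pathway; conduction delays and sigmoid curvature are fixed, not
  estimated.
* Jacobians are finite differences; fits cost a few hundred milliseconds
  each, and the free-energy surface is multimodal enough that single-trial
  10 dB data confuse the two coupling directions in ~20% of runs
  (block-averaged data reduce this to ~10%).
* The second level models a single scalar random-effect precision; no
  leave-one-out cross-validation, protected exceedance probabilities or
  family-level inference.
* The "all"-targeting model with prior rate 1/8 per target (M4) is so
  weakly coupled that, on data generated *without* coupling, its evidence
  sits within about a nat of the null model's: its extra parameters barely
  move from their priors, so they carry almost no Occam penalty. Null-model
  identification by RFX exceedance consequently fluctuates between ~0.5
  and ~0.95 across noise seeds -- an information ceiling of this model
  space, not an estimation defect. Identification of a truly coupled
  generating model (M1) is robust (~0.96).
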