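---
title: "Measuring binaural diplacusis: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring binaural diplacusis: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diplacusr)
```

`diplacusr` implements an interaural pitch-comparison experiment and its
analysis end to end. This vignette documents the underlying models, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions that were genuinely open.

## The measurement model

On each trial of the pitch test a listener hears a reference tone of fixed
frequency $f_{ref}$ in one ear and a comparison tone of frequency
$f_{comp} = f_{ref}\,2^{k/16}$, $k \in \{-4,\dots,4\}$, in the other, and
reports which had the higher pitch. With counts of "comparison higher"
responses per offset, the psychometric function is a binomial logistic
model on the octave axis $x = \log_2(f_{comp}/f_{ref})$:

$$P(\text{comparison higher}) = \mathrm{logistic}(a + b\,x).$$

The point of subjective equality (PSE) is the 50% crossing $-a/b$, and the
PSE *shift* is the PSE expressed relative to $f_{ref}$, reported in
sixteenths of an octave (the grid step). With the reference in the better
ear, a negative shift means the comparison (worse) ear must be given a
*lower* frequency to match — equivalently, the worse ear hears a given
frequency as higher in pitch.

Two fits of the same likelihood are computed:

* **Maximum likelihood** via `stats::glm` (binomial family). When the data
  are completely separated — step-like counts, common for steep observers
  at 10 trials per offset — the MLE does not exist; the fit then falls
  back to a ridge-penalised likelihood (Gaussian penalty, sd 10 on both
  coefficients) and is flagged `penalized`. The penalty trades exact
  translation equivariance for existence; unpenalised fits are exactly
  equivariant.
* **Bayesian** posterior under priors $a \sim N(0, 10)$,
  $b \sim N(0, 10)$ truncated to $b > 0$: the design guarantees that a
  cooperative listener answers "higher" more often as the comparison
  frequency rises, so negative slopes are excluded a priori. Both prior
  SDs are configurable. Sampling uses a self-contained adaptive
  random-walk Metropolis chain (1000 warmup iterations with the proposal
  scale adapted toward ~30% acceptance every 50 iterations, 3000 retained
  draws by default, initialised at the penalised MLE). The shift draws are
  $-16\,a/b$; significance is declared when the equal-tailed 95% credible
  interval excludes zero, with an endpoint exactly at zero counting as
  inclusion. Reported diagnostics are the acceptance rate and a
  batch-means effective sample size; a fit with acceptance outside
  (0.05, 0.9) or ESS below 50 is marked non-converged and yields no
  significance verdict.

A shift is *abnormal* when its magnitude strictly exceeds the normative
boundary, 1.5/16 octave (about 7% in frequency). Shifts whose magnitude
exceeds 1/4 octave lie outside the measured grid and are flagged
`extrapolated`; they are reported but should be read cautiously.

Interval estimates for a *group mean* shift use the exact posterior of a
normal mean under the reference prior $p(\mu, \sigma^2) \propto
\sigma^{-2}$, whose marginal for $\mu$ is a scaled Student-$t$ with
$n - 1$ degrees of freedom. This is deterministic, has exactly nominal
coverage for normal data, and avoids a sampler where none is needed; it is
equivalent in practice to a weakly informative normal model at these
group sizes.

## Audiometric derivations

* **Better ear**: the lower mean threshold across 500, 1000, 2000 and
  4000 Hz; exact ties go to the left ear (arbitrary but deterministic).
  The better ear is the reference ear for hearing-impaired testing.
* **Cutoff frequency Fc**: scanning consecutive audiometric frequencies,
  the first pair whose slope exceeds 10 dB *per octave* marks Fc (the
  pair's lower frequency); audiograms that never reach the criterion fall
  back to 2000 Hz, the modal Fc in sloping-loss cohorts. Two points here
  were genuinely open. First, the criterion could also be read as a raw
  10-dB rise between adjacent test frequencies; because the frequency grid
  is not uniform in octaves the two readings differ, and the per-octave
  reading is the default with `per_octave = FALSE` exposed as a switch.
  Second, which ear's audiogram defines Fc is not fixed by the protocol;
  the package computes it on the better ear, which is the ear that sets
  the reference frequency for testing.
* **Presentation level**: threshold $+ 0.7 \times$ (MCL $-$ threshold),
  the 70% point of the dynamic range; the fraction is a parameter.
* **Asymmetry**: worse-ear minus better-ear threshold at the test
  frequency, signed — it can be negative at a frequency where the
  globally worse ear happens to be better.

## Behavioural procedures

* **MCL ascent**: from $\max(60, \text{threshold} + 5)$ dB HL upward in
  5-dB steps until the observer reports discomfort; the MCL is the last
  acceptable level. A starting level already above the comfort limit is
  returned flagged.
* **Loudness balance**: one-down/one-up staircase on the comparison-ear
  level, which converges on the 50% point of the loudness psychometric
  function — the equal-loudness level. Two runs, starting 10 dB above and
  10 dB below the nominal match (the comparison-ear level at the same
  dynamic-range fraction as the reference); each run stops after two
  reversals, and the matched level is the mean over all reversal levels
  pooled across runs. Three of these settings are not prescribed by the
  protocol and are package defaults: the step size (5 dB, matching the
  MCL step; configurable), the ±10-dB starting offsets (chosen to bracket
  the match within a few trials), and pooled rather than per-run-averaged
  reversal means (`per_run_mean = TRUE` gives the alternative; the two
  differ only when a run's reversal counts differ, which the two-reversal
  rule prevents, so the choice is cosmetic here). Comparison levels are
  clamped to (threshold + 1 dB, MCL); a clamp that blocks the staircase
  counts as a reversal and flags the result rather than looping forever.
* **Balanced levels between anchors**: the balance is measured at
  $f_{ref}$ and $f_{ref} \pm 1/4$ octave only; levels at the nine
  comparison offsets are linearly interpolated in log2-frequency between
  the three anchors (the protocol leaves the interpolation unspecified;
  linear-in-log-frequency is the least-structured monotone choice).
* **Pitch block**: 9 offsets × 10 trials in a seeded random order, the
  comparison level roved uniformly over a 10-dB range centred on its
  balanced level ("varied randomly" fixed to uniform as the maximum
  entropy choice on a bounded range).

## The virtual observer and cohort generator

The observer is a *decision-level* stand-in, not an auditory model: no
basilar-membrane, excitation-pattern or spike-timing simulation. Its three
behavioural rules are

* pitch: $P(\text{comparison higher}) = \lambda/2 + (1-\lambda)\,
  \mathrm{logistic}(\beta_p d)$ with $d$ the perceived-pitch difference in
  octaves, where each ear's perceived pitch is $\log_2 f$ plus a per-ear
  offset map (anchored offsets, linear in log2-frequency, constant
  extrapolation). The logistic family matches the fitted model, which
  makes parameter recovery well-posed; $\lambda$ is a lapse rate,
  default 0.
* loudness: logistic in the difference of dynamic-range fractions
  $(\text{level} - \text{threshold})/(\text{MCL} - \text{threshold})$.
  Any monotone loudness proxy would serve; this one makes the balance
  target analytic — equal fractions are equally loud, so the staircase's
  50% point is exactly the nominal match.
* discomfort: deterministic (a tone is uncomfortable iff it exceeds the
  ear's true comfort limit), which keeps the MCL map a pure function of
  the profile.

Defaults $\beta_p = 20$ logit/octave (1.25 logit per sixteenth, the
mid-range of slopes the pipeline recovers from its own cohorts) and
$\beta_l = 16$ per unit fraction (a 10% dynamic-range difference maps to
83% "louder" responses) were fixed once as realistic discriminabilities.

`make_cohort()` draws 12 normal-hearing and 43 hearing-impaired listeners
by default. Hearing-impaired audiograms are a flat base plus a sloped
segment beyond a per-listener knee — knee frequencies sampled with the
weights of `fc_distribution`, slopes $N(30, 10)$ clipped to [12, 60]
dB/octave, 3-dB per-frequency jitter — recentred so the better-ear
four-frequency average equals a draw from $N(40, 15.8)$ dB HL. The worse
ear adds a per-listener asymmetry: at least 15 dB (15 + exponential with
mean 8, capped at 40) for the asymmetric subgroup (fraction 20/43),
uniform 0–12 dB otherwise, which places the worse-ear average near
$N(53, 15.5)$. Comfort limits saturate near 105 dB HL (recruitment), so
dynamic ranges shrink as thresholds rise. True pitch shifts are planted as
$\text{shift} = -0.004\,\text{oct/dB} \times \text{asymmetry} + N(0,
0.075\ \text{oct})$ at 500 Hz and at the detected Fc, encoded as an offset
map on the detected worse ear so the full pipeline recovers them; with
typical asymmetry spreads this coupling yields shift–asymmetry
correlations near −0.5 and roughly half the cohort beyond the normative
boundary at Fc, the regime the method is meant to operate in.
Normal-hearing listeners have all thresholds at or below 20 dB HL and
constant interaural offsets with SD 0.5/16 octave, so they rarely cross
the 1.5/16 boundary.

What the generator does **not** emulate — and hence what passing recovery
tests do not establish about real listeners: frequency-dependent lapse or
attention drift, loudness–pitch interactions (the observer's pitch rule
ignores level, so the rove is inert by construction rather than by
control), non-logistic responding, dead cochlear regions, and test–retest
drift. Recovery tolerances are therefore statements about the artifact's
own generative model.

## Numerical choices and degenerate inputs

* Log-likelihoods use a stable `log(1 + e^x)` (linear branch above 35) so
  steep slopes do not overflow.
* `glm` separation is detected via its fitted-probability warning or
  absurd coefficients (>150) and triggers the penalised fallback.
* The MH sampler restricts $b > 0$ by rejection ($-\infty$ log posterior),
  equivalent to truncation.
* Reversed responders (fitted $b \le 0$) raise a typed error rather than
  reporting a meaningless PSE; fewer than two informative offsets likewise.
* Correlations require ≥3 complete pairs and positive variance in both
  variables; leave-one-out requires ≥4.
* Every stochastic stage is driven by explicit integer seeds: the cohort
  by its spec seed, each condition's procedures and each MCMC chain by
  offsets derived from the pipeline's master seed, so a report is
  reproducible from its configuration alone.

## Scale of the validation suite

The test suite validates the chain at sizes chosen to make Monte-Carlo
error small relative to the tolerances while keeping a full run in a few
minutes: 200 replicate pitch blocks for recovery bias (tolerance ±0.3
sixteenth on the mean), 300 blocks for credible-interval calibration
(coverage required in 92–98%), 1000 staircase replicates (mean within half
a step of the 50% point), 20 datasets against a two-stage exhaustive
likelihood grid (agreement within 0.05 on both coefficients), and 200
replicate 43-listener cohorts for the direction of the shift–asymmetry
correlation (negative in ≥95%).

## Interface notes and limitations

The package is a library: `run_pipeline()` plus the readers and writers
are the entry points, and all tabular interchange is long-format CSV with
JSON for nested results — psychophysics has no entrenched binary trial
format, and text keeps the artifacts diffable. A shell wrapper would add
nothing over `Rscript -e`.

The psychometric-slope group comparison reports slopes per sixteenth of an
octave alongside per-octave values; published slope figures in this
paradigm do not always state their axis, and the per-sixteenth convention
is the one consistent with geometric means near 1.3 for cohorts like the
default one. The printed "95% confidence interval" accompanying a
geometric-mean slope in this literature is numerically a *population
coverage* interval $\exp(\overline{\log s} \pm 1.96\,sd(\log s))$, not an
interval for the mean — the package computes and labels it as a geometric
coverage interval.

Known limitations: PSEs beyond ±1/4 octave rest on extrapolation of the
logistic tail; the Bayesian group summary models point estimates rather
than propagating individual posteriors (adequate when per-listener
uncertainty is small relative to between-listener spread, as here); and
the normative boundary is a fixed convention, not re-estimated from the
simulated normal-hearing group.
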