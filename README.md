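# diplacusr

Simulation and analysis of binaural pitch diplacusis experiments.

Binaural pitch diplacusis is a perceptual anomaly in which the same pure
tone evokes a different pitch depending on whether it is played to the left
or the right ear of one listener. It is of clinical interest in asymmetric
hearing loss — the pitch is typically heard *higher* in the ear with the
worse thresholds — and of theoretical interest in the place-vs-temporal
debate on pitch coding. `diplacusr` implements the complete measurement and
analysis chain used to study it at cohort scale, for audiologists and
psychoacousticians who want to run the analysis on their own 2AFC
interaural-comparison data, and for methodologists who want to study the
estimator's behaviour on simulated listeners with known ground truth.

## What it computes

For each listener and reference frequency, an interaural pitch-comparison
block presents a fixed reference tone in one ear and a comparison tone in
the other at nine frequencies spanning ±1/4 octave in 1/16-octave steps
(10 trials each, levels loudness-balanced and roved over 10 dB). The count
of "comparison higher" responses per offset is fitted with a binomial
logistic model on the octave axis,

    P(comparison higher) = logistic(a + b·x),    x = log2(f_comp / f_ref),

and the **point of subjective equality** (PSE) is the 50% crossing,
`−a/b`. The **PSE shift** (PSE minus the reference frequency, reported in
sixteenths of an octave) measures the interaural pitch difference: with the
reference in the better ear, negative shifts mean a higher pitch in the
worse ear. Uncertainty comes from the Bayesian posterior of the same model
(adaptive random-walk Metropolis; priors `a ~ N(0,10)`,
`b ~ N(0,10)` truncated positive): a shift is *significant* when its
equal-tailed 95% credible interval excludes zero, and *abnormal* when its
magnitude exceeds the normative boundary of 1.5/16 octave (≈ 7%).

Around this core the package provides:

* **audiometry** — better-ear rule (four-frequency pure-tone average),
  audiogram cutoff frequency Fc (first slope > 10 dB/octave, 2000-Hz flat
  fallback), interaural threshold asymmetry, dynamic range and
  presentation levels;
* **behavioural procedures** — the 5-dB ascending MCL measurement, the
  adaptive one-down/one-up interaural loudness balance (two runs, two
  reversals each) at the three anchor frequencies, and the randomized
  pitch block;
* **virtual observers** — decision-level simulated listeners with per-ear
  audiograms, comfort limits, interaural pitch maps and logistic decision
  noise, plus a cohort generator (12 normal-hearing + 43 hearing-impaired
  by default) with known true shifts for parameter-recovery studies;
* **group statistics** — Pearson correlation of shift vs threshold
  asymmetry with leave-one-out influence diagnostics, pooled t-test on
  log psychometric slopes with geometric means, and prevalence tables.

## Worked example

A virtual listener whose right ear hears every tone 1.7/16 octave too high,
tested with the reference in the left ear at 1000 Hz:

```r
library(diplacusr)
obs <- make_observer(list(
  id = "demo",
  left_audiogram  = audiogram(rep(10, 9)),
  right_audiogram = audiogram(rep(10, 9)),
  left_comfort  = level_map(rep(100, 6)),
  right_comfort = level_map(rep(100, 6)),
  pitch_shift = list(left = 0, right = 1.7 / 16),
  beta_p = 20, beta_l = 16))

set.seed(1)
bal <- balance_profile(obs, 1000, "left")         # loudness balancing
lvl <- presentation_level(threshold_at(obs$left_audiogram, 1000),
                          level_at(obs$left_mcl, 1000))   # 70% dynamic range
blk <- run_pitch_block(obs, 1000, "left", lvl, bal$levels)
fit_psychometric(blk$data)
#> Logistic psychometric fit: a = 3.937, b = 33.12 /octave (2.070 /sixteenth)
#>   PSE shift = -1.90/16 octave (8.59% magnitude)
fit_bayes_psychometric(blk$data, seed = 2)
#> Posterior PSE shift: median -1.90/16 octave, 95% CrI [-2.43, -1.41]
#>   significant: TRUE | acceptance 0.35, ESS 507
```

The estimated shift of −1.90/16 octave recovers the planted +1.7/16-octave
right-ear offset (the sign flips because the PSE is expressed on the
comparison-ear axis) up to the binomial sampling noise of a 90-trial block;
the credible interval excludes zero, so the shift would be classified
significant, and `classify_shift(-1.9)` labels it abnormal with the pitch
higher in the worse ear.

A full synthetic study — 55 listeners, all procedures, both fits, group
statistics — runs in under half a minute:

```r
report <- run_pipeline(run_config(seed = 123))
report
#> Diplacusis pipeline report: 182 rows (55 participants)
#>   HI shift~asymmetry at 500: r = -0.43 (p = 0.00421, n = 43)
#>   HI shift~asymmetry at fc: r = -0.51 (p = 0.000495, n = 43)
#>   HI at 500: 33/43 significant, 19 abnormal (19 worse-ear-higher)
#>   HI at fc: 30/43 significant, 20 abnormal (17 worse-ear-higher)
```

Negative correlations say that larger interaural threshold asymmetries go
with more negative pitch shifts, i.e. the pitch is heard higher in the
worse ear — the generator plants exactly this coupling, and the pipeline
recovers it through the full measurement chain. The same `run_pipeline()`
accepts CSV audiograms and trial-count files in place of the simulator
(see `?run_config`).

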