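# swimhide

Two-state state-space modelling of resident fish acoustic telemetry under
motorboat noise.

## What it does

Resident reef fish alternate between **swimming** within a home range and
**hiding** in shelter. Acoustic telemetry sees neither state nor position:
each tagged fish emits a coded ping every 120 s, and an array of moored
receivers decodes it with a probability that falls off with distance.
`swimhide` implements the full state-space model linking the three layers
and uses it to test whether motorboat-noise peaks change the switching
behaviour:

* **Movement** (swimming): a biased random walk — a discrete-time
  Ornstein–Uhlenbeck step
  `r[n] = r[n-1] + k·dt·(r_HR − r[n-1]) + N(0, σ²·dt·I)`, with the
  innovation variance calibrated so the home-range `radius` is the 95%
  quantile of the stationary distance to the centre `r_HR`. Hidden steps
  keep the position exactly.
* **Switching**: a two-state Markov chain with transition matrix
  `T = [[p, 1−p], [1−q, q]]` (`p` = stay swimming, `q` = stay hidden),
  with one matrix per combination of two binary covariates — daylight ×
  boat-noise presence — i.e. 4 matrices and 8 free probabilities per fish.
* **Observation**: counts per receiver per 12-min step are
  `Binomial(6, logit⁻¹(slope·(d − d50)))` in the fish–receiver distance
  `d`, with `d50` the 150-m inflection point of the receivers.
* **Noise covariate**: hydrophone WAVs are calibrated to µPa; per-second
  SPL = `10·log10(mean(p²)/1 µPa²)`; a second holds a boat-noise peak when
  its mean squared pressure is ≥ 1.8× the basal level (+2.55 dB); a step
  is noisy when any of its seconds is.
* **Inference**: a purpose-built Metropolis-within-Gibbs sampler (Rcpp)
  over all parameters and the latent track, with the reference priors
  (truncated-normal logits, `d50 ~ U(−1000, 200)` m,
  `radius ~ U(50, 1000)` m, `k ~ Gamma(0.1, 0.1)`, centre uniform within
  1000 m of the detection-weighted receiver centroid), 3 chains,
  burn-in/thinning, Gelman–Rubin diagnostics (< 1.1 = converged) and 95%
  credibility intervals.

A synthetic-data generator reproduces the study geometry (14 receivers on
a 150-m grid) and the shy / intermediate / bold behavioural regimes, so
the whole pipeline is testable without any field data.

## Worked example

```r
library(swimhide)

# simulate one intermediate fish: 1000 twelve-minute steps on the field grid
ds  <- make_dataset(scenario("intermediate", n_steps = 1000, seed = 3))
fit <- run_mcmc(ds$detections, ds$receivers, ds$covariates,
                config = mcmc_config(n_chains = 3, n_keep = 1000,
                                     burn_in = 2000, thin = 10, seed = 1))
s <- summarize_posterior(fit)
s$truth <- ds$truth[s$parameter]
print(s[1:6, ], digits = 3)
```

```
  parameter      mean     lower     upper rhat    truth
1      hr_x  2.05e+01  1.20e+01  2.89e+01 1.00  20.0000
2      hr_y -1.91e+01 -2.73e+01 -1.06e+01 1.00 -15.0000
3         k  4.08e-04  3.02e-04  5.36e-04 1.06   0.0005
4    radius  1.02e+02  9.47e+01  1.11e+02 1.00 100.0000
5       d50  1.50e+02  1.48e+02  1.51e+02 1.00 150.0000
6     slope -1.99e-02 -2.02e-02 -1.96e-02 1.00  -0.0200
```

Every 95% credibility interval above covers its generating value, and
`home_range_area(102) ≈ 0.033 km²` converts the posterior-mean radius to
a home-range area. The remaining 8 rows of `s` are the switching
probabilities per covariate cell; their posteriors are wide (sparsely
observed covariate combinations inherit the bathtub-shaped reference
prior) and their Gelman–Rubin statistics need longer chains than this
quick demo to settle below 1.1 — the vignette discusses chain lengths.

A command-line interface wraps the same functions:

```sh
exec/swimhide simulate     --config cfg.yaml --out data/
exec/swimhide noise-detect --config cfg.yaml --out noise/ rec1.wav rec2.wav
exec/swimhide fit          --config cfg.yaml --data data/ --out fit/
exec/swimhide recover      --config cfg.yaml --out recovery/
```

`fit` exits non-zero when any Gelman–Rubin statistic is ≥ 1.1.

## Package layout

* `R/movement.R`, `R/behaviour.R`, `R/observation.R` — process and
  observation models plus text-format I/O.
* `R/noise.R`, `R/wav.R` — the passive-acoustics pipeline (PCM WAV →
  SPL → boat-noise flags aligned to 12-min steps).
* `R/priors.R`, `R/inference.R`, `src/ssm_mcmc.cpp` — priors, the MCMC
  driver and the compiled sampler core.
* `R/fixtures.R` — synthetic datasets and WAV fixtures with ground truth.
* `R/cli.R`, `exec/swimhide` — configuration handling and the CLI.
* `vignettes/swimhide-methods.Rmd` — model, assumptions, numerical
  choices and sampler validation.
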