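# adacode

Adaptive neural coding for dynamic Bayesian inference.

Sensory systems must infer the state of a changing environment from
incoming stimuli, but encoding stimuli in neural activity costs energy.
`adacode` is a simulator for studying how a resource-constrained encoder
should *adapt* its fidelity over time when its goal is accurate inference
rather than faithful stimulus reconstruction. It is aimed at computational
neuroscientists and students of efficient coding / Bayesian observer
models.

## The model

A latent state θ_t switches between two values θ_L and θ_H with hazard
rate h (default 0.01), and sets either the mean (x_t ~ N(θ_t, σ²)) or the
standard deviation (x_t ~ N(μ, θ_t²)) of a Gaussian stimulus distribution.
A Bayesian observer tracks the posterior P_t^L = p(θ_t = θ_L | y_{τ≤t})
through encoded responses y_t:

    P_t^L ∝ N(x_t; μ_L, σ_L²) · [(1−h) P_{t−1}^L + h (1−P_{t−1}^L)],

marginalized over the decoding distribution p(x_t | y_t) when the encoder
hides the raw stimulus, with point estimate
θ̂_t = P_t^L θ_L + (1−P_t^L) θ_H fed back to the encoder. Three encoder
families adapt to that feedback:

* **Discretization** — N response levels, Lloyd-optimized per belief under
  the inference distortion (θ̂_x − θ̂_y)² or the reconstruction distortion
  (x − y)²; coding cost is the entropy of level usage (bits).
* **Temporal filtering** — y_t = α x_t + (1−α) x_{t−1}, α ∈ [0.5, 1]
  chosen per belief to minimize error + β · H(y_t, y_{t+1}) with an
  analytic joint-entropy penalty and closed-form Gaussian decoding.
* **Stimulus selection** — transmit x_t verbatim only when the running
  misalignment M_t (windowed average surprise minus predicted entropy)
  exceeds a threshold V; otherwise send an explicit null symbol and let
  the observer marginalize over its own prediction.

Inference-optimized encoders devote fidelity to *surprising* stimuli at
times of *uncertainty*, producing low baseline activity with transient
post-switch bursts; reconstruction-optimized encoders devote fidelity to
*likely* stimuli, producing sustained higher activity. The package also
computes the stationary impact maps (how much one stimulus moves a
Bayesian estimate, as a function of prior entropy and stimulus surprise,
for generalized Gaussian stimulus distributions) and a diagnostic battery:
speed/accuracy of inference, entropy-coded spike rasters, metamer
probabilities, and robustness to transmission noise.

## Worked example

```r
library(adacode)
cfg <- experiment_config(env_config("mean"), encoder = "discretize",
                         goal = "inference", n_levels = 3,
                         n_cycles = 100, seed = 1)
sim <- simulate_coding(cfg)
summary(sim)
#> discretize encoder, mean mode (goal = inference): 20000 steps
#>   mean inference error:      0.016573
#>   mean reconstruction error: 0.69178
#>   mean entropy rate:         0.4763 bits
#>   fraction transmitted:      1.000
#>   accuracy low/high: 0.988 / 0.991;  speed down/up: 0.125 / 0.125
```

A 3-level encoder optimized for inference tracks the switching mean almost
as well as the ideal observer (mean squared estimate discrepancy 0.017,
against a state separation of 2) while spending only ~0.48 bits per
symbol — note the large reconstruction error (0.69): the encoder is
deliberately bad at representing the stimulus itself. The same
configuration with `goal = "reconstruction"` costs ~1.5 bits and incurs
roughly seven times the inference error. `plot(sim)` shows the
cycle-averaged estimate and posterior; `cycle_average()`,
`speed_accuracy()`, `spike_raster()` and `metamer_probability()` expose
the individual diagnostics, and `quantizer_bank()` / `filter_policy()`
the fitted encoder policies.

A thin command-line wrapper with `simulate`, `maps`, `sweep-levels`,
`sweep-beta`, `sweep-threshold`, `raster`, `metamer` and `noise`
subcommands is installed at `inst/scripts/adacode.R`; configurations
round-trip through YAML (`save_config()` / `load_config()`) and runs are
reproducible bit-for-bit from a manifest (`write_manifest()`) plus seed.

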