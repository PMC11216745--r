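# cdjsdm

Context-dependent joint species distribution models for camera-trap
communities.

## The problem

Camera-trap surveys record where and when medium and large mammals
occur along gradients of human disturbance. Two species can co-occur
because they respond to the same habitat, or because something beyond
the measured habitat ties them together — and that residual tie can
itself change with disturbance. Classical joint species distribution
models (JSDMs) estimate a single residual correlation per species
pair; this package fits a *context-dependent* JSDM in which the
residual associations are functions of disturbance covariates, so you
can ask how the association network looks at low, moderate and high
human modification or human presence. It also implements the matching
temporal analyses: solar-time diel classification, nocturnality shifts
between disturbance strata, and bootstrap contrasts of the time
between successive detections of different species (time-to-encounter).

It is written for quantitative ecologists working with station-level
camera-trap data: a detections table, a station table with covariates,
and a species table.

## The model

Presence–absence of species *j* at station *i* follows a multivariate
probit:

    y_ij ~ Bernoulli(Ψ_ij),   Ψ_ij = Φ(η_ij)
    η_ij = Σ_k x_ik β_jk + Σ_h z_ih λ_jh(x*_i)

with latent station scores `z_ih ~ N(0, 1)` and factor loadings that
are linear in a context vector `x*_i` (intercept, human modification,
human presence):

    λ_jh(x*_i) = Σ_k x*_ik λ_jhk

The residual covariance at context `x*` is `Ω(x*) = Λ(x*) Λ(x*)ᵀ` and
the association matrix is its correlation scaling
`R_j1j2 = Ω_j1j2 / √(Ω_j1j1 Ω_j2j2)`. Priors are independent normals;
posterior draws come from a fully conjugate Gibbs sampler (probit data
augmentation), so fits are fast and exactly reproducible under a fixed
seed. Loadings are not rotation-identified; every reported quantity
(R, Ψ, DIC) is rotation-invariant and R is computed per draw before
averaging.

## A worked example

Simulate a small community with known ground truth, fit the model, and
compare the association network at the extremes of the
human-modification gradient:

```r
library(cdjsdm)

cfg      <- sim_config(n_stations = 150, n_species = 6, n_factors = 2, seed = 1)
stations <- sim_covariates(150, seed = 1)
truth    <- sim_community(cfg, stations)

fit <- cdjsdm(truth$occupancy, truth$covariates, nf = 2,
              n_chains = 2, n_burn = 500, n_samples = 1000, seed = 1)

predict(fit, context = "human_modification", level = "min")
#> Residual species associations at context:
#>            intercept human_modification_z  human_presence_logz
#>                1.000               -1.749                0.000
#>   15 pairs: 6 positive (40%), 9 negative (60%)
#>   significant (95% CI excludes 0): 0 positive, 1 negative

predict(fit, context = "human_modification", level = "max")
#> Residual species associations at context:
#>            intercept human_modification_z  human_presence_logz
#>                1.000                3.012                0.000
#>   15 pairs: 15 positive (100%), 0 negative (0%)
#>   significant (95% CI excludes 0): 8 positive, 0 negative
```

The generator's ground truth strengthens a community-wide factor with
human modification, and the fitted model recovers exactly that: at the
observed minimum of the gradient only 40% of pairs are positively
associated, at the maximum all of them are. (This quick demo uses
short chains; the defaults are 3 chains × 3000 draws after 2000
burn-in, and `summary(fit)` reports split R-hat per coefficient.)

The temporal side works from the same detection records:

```r
records <- filter_independent(sim_detections(truth))
strata  <- disturbance_strata(stations, "human_presence")
ann     <- diel_annotate(records, stations)
species_meta <- data.frame(species = truth$species, mass_kg = 10,
                           guild = rep(c("carnivore", "ungulate"), 3))
shift   <- nocturnality_shift(ann[ann$station_id %in% strata$low, ],
                              ann[ann$station_id %in% strata$high, ],
                              species_meta, n_boot = 10000, seed = 1)
tte_lo  <- time_to_encounter(records, strata$low)
tte_hi  <- time_to_encounter(records, strata$high)
bootstrap_diff(tte_lo$log_delta, tte_hi$log_delta, seed = 1)
```

`run_pipeline()` chains all stages (prep → fit → associations at
min/mean/max of both gradients → temporal) from three CSV files and a
YAML config, and writes a machine-readable `summary.json`.

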