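# csfields

Spatio-temporal small-area estimation of Caesarean-section (CS) rates
from individual birth records.

Crude municipal CS rates are noisy (many municipalities record fewer
than a hundred births a year) and confound case mix with obstetric
practice. `csfields` fits, by maximum likelihood, an individual-level
logistic model with a smooth latent spatio-temporal field:

    logit P(CS_i) = x_i' beta + omega * (t_i - t0) + u(s_i, t_i)

* `x_i` — clinical covariates (smoking, maternal age class, parity /
  previous CS, gestational-age class, unit volume, induction,
  complication, infant sex, macrosomia, breech); odds ratio = exp(beta);
* `omega` — global linear time trend on the logit scale per year;
* `u` — zero-mean Gaussian field, Matérn in space (smoothness 1,
  range `rho` = distance where correlation ≈ 0.1, via the SPDE
  finite-element GMRF construction) and stationary AR(1) in time
  (year-to-year correlation `alpha`, innovation SD `sigma_eps`,
  marginal variance `sigma_eps^2 / (1 - alpha^2)`).

The field is integrated out by a Laplace approximation around its
conditional mode (sparse supernodal Cholesky, profiled fixed effects);
empirical-Bayes field modes give per-municipality-year rate surfaces
at the reference covariate profile. The package also ships a
registry-style simulator with known ground truth, the cohort exclusion
rules with flowchart-style accounting, the WHO Robson ten-group
classification with stratified fits (groups 1, 3, 5, 6), and reporting
(parameter and OR tables, trajectories, GeoJSON export). Everything —
Bowyer–Watson mesher, FEM assembly, Kronecker space-time precision,
Laplace machinery — is implemented on top of the `Matrix` package; no
INLA/TMB installation is needed.

Intended users: biostatisticians and epidemiologists doing disease
mapping / small-area estimation on registry outcome data, and anyone
needing a self-contained, oracle-tested reference implementation of
the separable Matérn × AR(1) logistic model.

## Worked example

Simulate a registry-like dataset (60 municipalities, 2001–2008, the
published-magnitude truth `sigma_eps = 0.125`, `rho = 114` km,
`alpha = 0.92`, `omega = 0.024`), filter, classify, fit and map:

```r
library(csfields)

cfg <- sim_config(n_municipalities = 60, years = 2001:2008,
                  births_meanlog = 4.4, births_sdlog = 0.9, seed = 42)
sim <- simulate_dataset(cfg, max_edge_km = 45, extension_km = 114)

fl  <- filter_cohort(sim$records, sim$geo)
fl$report
#> Cohort filter: 52633 records in, 49448 out
#>   - home_delivery      95 removed
#>   - age_outside_range  0 removed
#>   - ga_below_minimum   0 removed
#>   - outside_domain     0 removed
#>   - missing_values     0 removed
#>   - low_volume         3090 removed

table(classify_robson(fl$records))
#>     1    10     2     3     4     5     6     7     8     9
#> 13908  2225  4678 15865  5343  4436   824  1063   864   242

fit <- fit_cs_model(aggregate_births(fl$records), sim$mesh)
fit
#> Spatio-temporal CS model fit (converged)
#>   marginal NLL 20331.9849 after 6 outer iterations
#>   parameter    estimate          se
#> 1 sigma_eps  0.13452248  0.02032452
#> 2    rho_km 97.18478214 28.67773335
#> 3     alpha  0.90225057  0.03101936
#> 4     omega  0.02860942  0.01063780

head(or_table(fit), 4)
#>       covariate        or         se
#> 1 smoking_begin 1.1046706 0.05804191
#> 2   smoking_end 1.0100382 0.06561126
#> 3      age15_19 0.5659858 0.05266713
#> 4      age35_44 1.5982413 0.05031853

surf <- predict_rates(fit)
head(surf, 3)
#>   municipality_id year       rate
#> 1           M0001 2001 0.06085636
#> 2           M0002 2001 0.05687015
#> 3           M0003 2001 0.05657686
```

Reading the output: every true hyperparameter lies within ~1 SE of its
estimate (`sigma_eps` 0.135 ± 0.020 vs 0.125; `rho` 97 ± 29 vs 114;
`alpha` 0.902 ± 0.031 vs 0.92; `omega` 0.029 ± 0.011 vs 0.024), and the
odds ratios recover their simulated values (e.g. smoking-at-beginning
1.10 vs true 1.12, age 15–19 0.57 vs 0.57). `predict_rates()` returns
the model-smoothed municipal rate at the reference covariate profile:
rates range 0.037–0.127 in 2001 and 0.038–0.149 in 2008, the upward
drift being the `omega` trend.

Stratified Robson fits use the same machinery with the group-defining
covariates removed:

```r
fits <- fit_robson(fl$records, sim$mesh, groups = c(1, 3, 5, 6))
parameter_table(fits[["1"]])
```

## Command line

```sh
Rscript inst/cli/csfields simulate --out-dir data --seed 1
Rscript inst/cli/csfields filter   --in data/records.csv \
        --geo data/municipalities.csv --out data/clean.csv \
        --report data/filter.json
Rscript inst/cli/csfields classify --in data/clean.csv --out data/robson.csv
Rscript inst/cli/csfields fit      --in data/clean.csv \
        --geo data/municipalities.csv --out data/fit.json
```

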