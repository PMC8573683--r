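# Registry-style birth-record simulator with known ground truth.
#
# The generator states a world resembling the Norwegian setting: a
# 420 km x 1752 km planar domain, 14 annual cohorts (2001-2014), around
# 440 municipalities with annual birth counts from below 50 to the
# thousands, Bernoulli CS outcomes driven by fixed effects (the
# registry covariate set), a linear time trend and a known separable
# spatio-temporal latent field. Covariate prevalences are placeholders
# (the source tables report odds ratios, not prevalences) and are
# documented as such.

#' Default covariate prevalences (placeholders)
#'
#' Rough population frequencies chosen once for plausibility; they are
#' NOT registry estimates. Categorical entries must sum to one.
#'
#' @return named list of probabilities.
#' @export
default_covariate_freqs <- function() {
  list(
    smoking_begin = 0.15,
    smoking_end_given_begin = 0.60,  # quitting is common; end implies begin
    age_class = c("15-19" = 0.03, "20-34" = 0.82, "35-44" = 0.15),
    parity_class = c(nulliparous = 0.42, multi_no_cs = 0.48,
                     multi_prev_cs = 0.10),
    ga_mean_days = 280, ga_sd_days = 13,
    sex_male = 0.514,
    birthweight_mean_g = 3500, birthweight_sd_g = 550,
    unit_volume = c(small = 0.20, medium = 0.50, large = 0.30),
    onset = c(spontaneous = 0.75, induced = 0.15, prelabour_cs = 0.10),
    complication = 0.08,
    presentation = c(cephalic = 0.955, breech = 0.04, other = 0.005),
    plurality_multiple = 0.017,
    home_delivery = 0.002
  )
}

#' Default true fixed effects (log odds ratios of the main analysis)
#'
#' The published odds ratios of the main-analysis covariates, on the
#' log scale, in design-column order of [build_design()]. The intercept
#' is `NA`, meaning "centre it so the marginal CS rate is close to
#' `target_rate`" (about 16% nationally).
#'
#' @return named numeric vector.
#' @export
default_true_beta <- function() {
  c("(Intercept)" = NA_real_,
    smoking_begin = log(1.12), smoking_end = log(1.00),
    age15_19 = log(0.57), age35_44 = log(1.70),
    nulliparous = log(2.71), prev_cs = log(14.27),
    ga_preterm = log(2.52), ga_post_term = log(1.59),
    unit_small = log(0.96), unit_large = log(0.96),
    induction = log(0.88), complication = log(3.36),
    sex_female = log(0.88), macrosomia = log(2.09),
    breech = log(14.40))
}

#' Simulation configuration
#'
#' @param n_municipalities number of municipalities (>= 3).
#' @param domain_width_km,domain_length_km planar domain size in km.
#' @param years integer vector of consecutive study years.
#' @param births_meanlog,births_sdlog log-normal parameters of the
#'   per-municipality mean annual birth count.
#' @param true_params a [cs_params()]; `beta` must be named in
#'   design-column order (see [default_true_beta()]); an `NA` intercept
#'   is auto-centred at `target_rate`.
#' @param covariate_freqs see [default_covariate_freqs()].
#' @param target_rate marginal CS probability used to centre an `NA`
#'   intercept (default 0.16).
#' @param missing_frac fraction of each filterable column blanked to
#'   `NA` (default 0, i.e. off).
#' @param seed master seed; expanded into independent per-stage streams.
#' @return object of class `cs_sim_config`.
#' @export
sim_config <- function(n_municipalities = 440,
                       domain_width_km = 420,
                       domain_length_km = 1752,
                       years = 2001:2014,
                       births_meanlog = 4.6,
                       births_sdlog = 1.1,
                       true_params = NULL,
                       covariate_freqs = default_covariate_freqs(),
                       target_rate = 0.16,
                       missing_frac = 0,
                       seed = 1L) {
  if (is.null(true_params))
    true_params <- cs_params(beta = default_true_beta(), omega = 0.024,
                             sigma_eps = 0.125, rho = 114, alpha = 0.92)
  stopifnot(n_municipalities >= 3L, domain_width_km > 0,
            domain_length_km > 0, length(years) >= 1L,
            missing_frac >= 0, missing_frac < 1,
            inherits(true_params, "cs_params"))
  for (nm in c("age_class", "parity_class", "unit_volume", "onset",
               "presentation")) {
    p <- covariate_freqs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop2("covariate_freqs$", nm, " must be non-negative and sum to 1")
  }
  structure(list(n_municipalities = as.integer(n_municipalities),
                 domain_width_km = domain_width_km,
                 domain_length_km = domain_length_km,
                 years = as.integer(years),
                 births_meanlog = births_meanlog,
                 births_sdlog = births_sdlog,
                 true_params = true_params,
                 covariate_freqs = covariate_freqs,
                 target_rate = target_rate,
                 missing_frac = missing_frac,
                 seed = as.integer(seed)),
            class = "cs_sim_config")
}

#' Simulate municipality centroids
#'
#' Uniform on the rectangle with a minimum separation of 5 km enforced
#' by resampling (isotropy makes the layout irrelevant to model
#' correctness, so real clustering is not emulated).
#'
#' @param config a [sim_config()].
#' @return data frame `municipality_id`, `x_km`, `y_km`.
#' @export
simulate_municipalities <- function(config) {
  stopifnot(inherits(config, "cs_sim_config"))
  set.seed(derive_seeds(config$seed, 5L)[1L])
  n <- config$n_municipalities
  min_sep <- 5
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    x <- runif(1, 0, config$domain_width_km)
    y <- runif(1, 0, config$domain_length_km)
    if (length(xs) == 0L ||
        min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1L
    if (tries > 200L * n)
      stop2("could not place ", n, " municipalities with ", min_sep,
            " km separation in the domain; enlarge it")
  }
  data.frame(municipality_id = sprintf("M%04d", seq_len(n)),
             x_km = xs, y_km = ys)
}

#' Simulate the latent spatio-temporal field
#'
#' Year one is drawn from the stationary distribution (spatial GMRF
#' scaled by `1/sqrt(1 - alpha^2)`); later years follow
#' `x_t = alpha x_{t-1} + eps_t` with `eps_t` a fresh spatial draw of
#' marginal SD `sigma_eps`, so the marginal variance at every vertex is
#' `sigma_eps^2 / (1 - alpha^2)` in every year.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param params a [cs_params()].
#' @param years year labels.
#' @param seed integer seed.
#' @return matrix, vertices x years, with `years` as column names.
#' @export
simulate_field <- function(mesh, params, years, seed) {
  stopifnot(inherits(params, "cs_params"))
  set.seed(as.integer(seed))
  n_time <- length(years)
  Qs <- spde_precision(mesh, params$sigma_eps, params$rho)
  eps <- rgmrf(Qs, n = n_time)
  field <- matrix(0, nrow(mesh$vertices), n_time,
                  dimnames = list(NULL, years))
  field[, 1L] <- eps[, 1L] / sqrt(1 - params$alpha^2)
  if (n_time > 1L)
    for (t in 2:n_time)
      field[, t] <- params$alpha * field[, t - 1L] + eps[, t]
  field
}

draw_category <- function(n, probs) {
  names(probs)[1L + findInterval(runif(n), cumsum(probs), left.open = TRUE)]
}

simulate_covariates <- function(n, freqs) {
  smoking_begin <- as.integer(runif(n) < freqs$smoking_begin)
  smoking_end <- as.integer(smoking_begin == 1L &
                              runif(n) < freqs$smoking_end_given_begin)
  age_class <- draw_category(n, freqs$age_class)
  age <- ifelse(age_class == "15-19", runif(n, 15, 20),
                ifelse(age_class == "20-34", runif(n, 20, 35),
                       runif(n, 35, 45)))
  parity_class <- draw_category(n, freqs$parity_class)
  ga_days <- round(rnorm(n, freqs$ga_mean_days, freqs$ga_sd_days))
  ga_days <- pmin(pmax(ga_days, 150), 310)
  sex <- ifelse(runif(n) < freqs$sex_male, "M", "F")
  bw <- round(rnorm(n, freqs$birthweight_mean_g, freqs$birthweight_sd_g))
  bw <- pmax(bw, 400)
  unit_volume <- draw_category(n, freqs$unit_volume)
  onset <- draw_category(n, freqs$onset)
  presentation <- draw_category(n, freqs$presentation)
  plurality <- ifelse(runif(n) < freqs$plurality_multiple, 2L, 1L)
  data.frame(
    maternal_age_years = round(age, 1), smoking_begin = smoking_begin,
    smoking_end = smoking_end, parity_class = parity_class,
    ga_days = as.integer(ga_days), sex = sex, birthweight_g = as.integer(bw),
    unit_volume = unit_volume,
    induction = as.integer(onset == "induced"),
    complication = as.integer(runif(n) < freqs$complication),
    breech = as.integer(presentation == "breech"),
    presentation = presentation,
    plurality = plurality, onset = onset,
    home_delivery = as.integer(runif(n) < freqs$home_delivery),
    stringsAsFactors = FALSE)
}

# centre an NA intercept so that the covariate-averaged linear
# predictor sits at logit(target_rate)
centre_intercept <- function(beta, freqs, target_rate) {
  if (!is.na(beta[1L])) return(beta)
  ef <- function(nm, p) p * beta[[nm]]
  shift <-
    ef("smoking_begin", freqs$smoking_begin) +
    ef("smoking_end", freqs$smoking_begin * freqs$smoking_end_given_begin) +
    ef("age15_19", freqs$age_class[["15-19"]]) +
    ef("age35_44", freqs$age_class[["35-44"]]) +
    ef("nulliparous", freqs$parity_class[["nulliparous"]]) +
    ef("prev_cs", freqs$parity_class[["multi_prev_cs"]]) +
    ef("ga_preterm", stats::pnorm(258.5, freqs$ga_mean_days, freqs$ga_sd_days)) +
    ef("ga_post_term", 1 - stats::pnorm(293.5, freqs$ga_mean_days, freqs$ga_sd_days)) +
    ef("unit_small", freqs$unit_volume[["small"]]) +
    ef("unit_large", freqs$unit_volume[["large"]]) +
    ef("induction", freqs$onset[["induced"]]) +
    ef("complication", freqs$complication) +
    ef("sex_female", 1 - freqs$sex_male) +
    ef("macrosomia", 1 - stats::pnorm(4500, freqs$birthweight_mean_g,
                                      freqs$birthweight_sd_g)) +
    ef("breech", freqs$presentation[["breech"]])
  beta[1L] <- qlogis(target_rate) - shift
  beta
}

#' Simulate birth records from a latent field
#'
#' Each record's outcome is Bernoulli with
#' `logit p = x'beta + omega (year - reference year) + field value at
#' the mother's municipality`. The reference year is the midpoint of
#' the configured range. Returns the records together with the ground
#' truth needed for recovery tests.
#'
#' @param geo [simulate_municipalities()] output.
#' @param mesh mesh built over `geo`.
#' @param field [simulate_field()] output.
#' @param config a [sim_config()].
#' @return list with `records` (data frame, one row per delivery) and
#'   `truth` (params with centred intercept, field, per-record linear
#'   predictors, reference year).
#' @export
simulate_births <- function(geo, mesh, field, config) {
  stopifnot(inherits(config, "cs_sim_config"))
  seeds <- derive_seeds(config$seed, 5L)
  freqs <- config$covariate_freqs
  params <- config$true_params
  params$beta <- centre_intercept(params$beta, freqs, config$target_rate)
  years <- config$years
  ref_year <- mean(range(years))

  set.seed(seeds[3L])
  mean_births <- stats::rlnorm(nrow(geo), config$births_meanlog,
                               config$births_sdlog)
  counts <- matrix(stats::rpois(nrow(geo) * length(years),
                                rep(mean_births, length(years))),
                   nrow(geo), length(years))

  set.seed(seeds[4L])
  mid <- rep(rep(seq_len(nrow(geo)), length(years)), as.vector(counts))
  tid <- rep(rep(seq_along(years), each = nrow(geo)), as.vector(counts))
  n <- length(mid)
  cov <- simulate_covariates(n, freqs)
  records <- cbind(
    data.frame(record_id = sprintf("B%07d", seq_len(n)),
               year = years[tid],
               municipality_id = geo$municipality_id[mid],
               stringsAsFactors = FALSE),
    cov)

  X <- build_design(records, standard_covariates())
  if (!identical(colnames(X), names(params$beta)))
    stop2("true beta names must match design columns: ",
          paste(colnames(X), collapse = ", "))
  Pf <- as.matrix(mesh$projector %*% field)
  eta <- drop(X %*% params$beta) +
    params$omega * (records$year - ref_year) + Pf[cbind(mid, tid)]
  if (any(!is.finite(eta))) stop2("non-finite linear predictor")
  p <- plogis(eta)
  if (any(p <= 0 | p >= 1))
    stop2("simulated CS probability outside (0, 1)")
  records$cs <- rbinom(n, 1L, p)
  records <- records[, c("record_id", "year", "municipality_id", "cs",
                         setdiff(names(records),
                                 c("record_id", "year", "municipality_id", "cs")))]

  if (config$missing_frac > 0) {
    set.seed(seeds[5L])
    for (col in c("municipality_id", "maternal_age_years", "ga_days",
                  "sex", "birthweight_g", "unit_volume", "presentation")) {
      blank <- runif(n) < config$missing_frac
      records[[col]][blank] <- NA
    }
  }

  list(records = records,
       truth = list(params = params, field = field, eta = eta,
                    reference_year = ref_year))
}

#' Simulate births with an explicit custom covariate design
#'
#' Lower-level generator for simulation studies: instead of the full
#' registry covariate set, draws user-specified covariate columns and
#' a fixed number of births per municipality-year. `params$beta` must
#' be named `(Intercept)` followed by the covariate names.
#'
#' @param geo municipality table.
#' @param mesh mesh over `geo`.
#' @param field latent field (vertices x years).
#' @param params a [cs_params()].
#' @param years year labels matching the field columns.
#' @param births_per_cell expected births per municipality-year
#'   (Poisson).
#' @param covariate_sampler function(n) returning a data frame of the
#'   covariate columns for n records; default: iid Bernoulli(0.3)
#'   columns named after `params$beta[-1]`.
#' @param seed integer seed.
#' @return data frame of records (record_id, year, municipality_id,
#'   cs, covariates).
#' @export
simulate_custom_births <- function(geo, mesh, field, params, years,
                                   births_per_cell,
                                   covariate_sampler = NULL, seed = 1L) {
  stopifnot(inherits(params, "cs_params"))
  set.seed(as.integer(seed))
  cov_names <- setdiff(names(params$beta), "(Intercept)")
  covariate_sampler <- covariate_sampler %||% function(n) {
    as.data.frame(setNames(
      lapply(cov_names, function(nm) rbinom(n, 1L, 0.3)), cov_names))
  }
  ref_year <- mean(range(years))
  n_cell <- stats::rpois(nrow(geo) * length(years), births_per_cell)
  mid <- rep(rep(seq_len(nrow(geo)), length(years)), n_cell)
  tid <- rep(rep(seq_along(years), each = nrow(geo)), n_cell)
  n <- length(mid)
  recs <- cbind(
    data.frame(record_id = sprintf("B%07d", seq_len(n)),
               year = years[tid], municipality_id = geo$municipality_id[mid],
               stringsAsFactors = FALSE),
    covariate_sampler(n))
  X <- build_design(recs, cov_names)
  Pf <- as.matrix(mesh$projector %*% field)
  eta <- drop(X %*% params$beta) +
    params$omega * (recs$year - ref_year) + Pf[cbind(mid, tid)]
  recs$cs <- rbinom(n, 1L, plogis(eta))
  recs
}

#' One-call simulation of a full registry-like dataset
#'
#' Convenience wrapper: municipalities, mesh, latent field, records.
#'
#' @param config a [sim_config()].
#' @param max_edge_km,extension_km mesh controls (defaults `rho / 3`
#'   and `rho` of the true parameters).
#' @return list with `geo`, `mesh`, `field`, `records`, `truth`,
#'   `config`.
#' @export
simulate_dataset <- function(config,
                             max_edge_km = config$true_params$rho / 3,
                             extension_km = config$true_params$rho) {
  geo <- simulate_municipalities(config)
  mesh <- build_mesh(geo, max_edge_km = max_edge_km,
                     extension_km = extension_km)
  field <- simulate_field(mesh, config$true_params, config$years,
                          seed = derive_seeds(config$seed, 5L)[2L])
  sim <- simulate_births(geo, mesh, field, config)
  list(geo = geo, mesh = mesh, field = field, records = sim$records,
       truth = sim$truth, config = config)
}

#' Write a simulated dataset to plain-text files
#'
#' `records.csv`, `municipalities.csv` and a `ground_truth.json`
#' sidecar (true parameters, reference year) plus `true_field.csv`
#' (vertex, year, value).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$records, file.path(dir, "records.csv"), row.names = FALSE)
  write.csv(sim$geo, file.path(dir, "municipalities.csv"), row.names = FALSE)
  tp <- sim$truth$params
  jsonlite::write_json(
    list(beta = as.list(tp$beta), omega = tp$omega,
         sigma_eps = tp$sigma_eps, rho = tp$rho, alpha = tp$alpha,
         reference_year = sim$truth$reference_year,
         seed = sim$config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  fld <- data.frame(vertex = rep(seq_len(nrow(sim$field)), ncol(sim$field)),
                    year = rep(as.integer(colnames(sim$field)),
                               each = nrow(sim$field)),
                    value = as.vector(sim$field))
  write.csv(fld, file.path(dir, "true_field.csv"), row.names = FALSE)
  invisible(dir)
}
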