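test_that("municipality simulation respects bounds, count and seed", {
  cfg1 <- sim_config(n_municipalities = 3, years = 2001:2002, seed = 7)
  g1 <- simulate_municipalities(cfg1)
  expect_equal(nrow(g1), 3L)

  cfg <- sim_config(n_municipalities = 440, seed = 7)
  geo <- simulate_municipalities(cfg)
  expect_equal(nrow(geo), 440L)
  expect_true(all(geo$x_km >= 0 & geo$x_km <= 420))
  expect_true(all(geo$y_km >= 0 & geo$y_km <= 1752))
  expect_false(anyDuplicated(geo[, c("x_km", "y_km")]) > 0)
  # minimum 5 km separation
  expect_gt(min(dist(cbind(geo$x_km, geo$y_km))), 5 - 1e-9)
  # determinism
  geo2 <- simulate_municipalities(sim_config(n_municipalities = 440,
                                             seed = 7))
  expect_identical(geo, geo2)
  # impossible packing fails with a message
  expect_error(simulate_municipalities(
    sim_config(n_municipalities = 50, domain_width_km = 10,
               domain_length_km = 10, years = 2001, seed = 1)),
    "separation")
})

test_that("config validates probabilities", {
  f <- default_covariate_freqs()
  f$unit_volume <- c(small = 0.5, medium = 0.6, large = 0.2)
  expect_error(sim_config(covariate_freqs = f), "sum to 1")
  expect_error(sim_config(n_municipalities = 2), "n_municipalities")
})

test_that("field simulation honours the stationary separable model", {
  geo <- toy_geo(15, seed = 23)
  mesh <- toy_mesh(geo)
  prm <- cs_params(beta = 0, omega = 0, sigma_eps = 0.125, rho = 114,
                   alpha = 0.92)
  # alpha = 0: consecutive years are independent draws
  prm0 <- cs_params(beta = 0, omega = 0, sigma_eps = 0.3, rho = 114,
                    alpha = 0)
  v <- 4L
  draws <- vapply(1:400, function(s) {
    f <- simulate_field(mesh, prm0, 2001:2002, seed = s)
    f[v, ]
  }, numeric(2))
  expect_lt(abs(cor(draws[1, ], draws[2, ])), 0.12)

  # stationary marginal variance and lag-1 autocorrelation at one
  # vertex over replicate draws; the variance target is the
  # mesh-consistent one, Sigma_s[v, v] / (1 - alpha^2) (on this coarse
  # toy mesh the finite-element marginal deviates from the nominal
  # sigma^2 = 0.125^2, whose stationary value rounds to 0.1017)
  expect_equal(round(0.125^2 / (1 - 0.92^2), 4), 0.1017)
  Svv <- solve(as.matrix(spde_precision(mesh, 0.125, 114)$Q))[v, v]
  reps <- vapply(1:2000, function(s) {
    f <- simulate_field(mesh, prm, 2001:2003, seed = 10000 + s)
    f[v, ]
  }, numeric(3))
  expect_equal(var(reps[2, ]), Svv / (1 - 0.92^2), tolerance = 0.1)
  expect_equal(cor(reps[1, ], reps[2, ]), 0.92, tolerance = 0.035)
  # determinism
  expect_identical(simulate_field(mesh, prm, 2001:2003, seed = 5),
                   simulate_field(mesh, prm, 2001:2003, seed = 5))
})

test_that("between-municipality logit SD matches the stationary SD", {
  # field projected to municipalities, covariates off: pooled over
  # municipalities and replicates, the SD approaches the nominal
  # sigma_eps / sqrt(1 - alpha^2); needs a mesh fine enough for the
  # finite-element marginal variance to sit near its nominal value
  geo <- toy_geo(20, seed = 29)
  mesh <- build_mesh(geo, 25, 90, interior_fill = TRUE)
  prm <- cs_params(beta = 0, omega = 0, sigma_eps = 0.25, rho = 80,
                   alpha = 0.6)
  reps <- vapply(1:500, function(s) {
    f <- simulate_field(mesh, prm, 2001:2002, seed = 20000 + s)
    as.numeric(mesh$projector %*% f[, 2])
  }, numeric(20))
  expect_equal(sd(as.vector(reps)), 0.25 / sqrt(1 - 0.6^2),
               tolerance = 0.1)
})

test_that("simulated field correlogram decays near the range", {
  geo <- toy_geo(60, seed = 31, width = 420, length = 1000)
  mesh <- build_mesh(geo, 60, 80, interior_fill = FALSE)
  prm <- cs_params(beta = 0, omega = 0, sigma_eps = 0.3, rho = 120,
                   alpha = 0.5)
  set.seed(1)
  draws <- vapply(1:300, function(s)
    simulate_field(mesh, prm, 2001, seed = 30000 + s)[, 1],
    numeric(nrow(mesh$vertices)))
  cent_idx <- seq_len(nrow(geo))
  D <- as.matrix(dist(cbind(geo$x_km, geo$y_km)))
  C <- cor(t(draws[cent_idx, ]))
  # mean correlation in a band around rho lies near the theoretical
  # 0.139, well inside the mesh-approximation tolerance
  band <- D > 100 & D < 140 & upper.tri(D)
  expect_equal(mean(C[band]), 0.14, tolerance = 0.08)
  far <- D > 500 & upper.tri(D)
  expect_lt(abs(mean(C[far])), 0.1)
})

test_that("birth simulation reproduces target rates and effects", {
  # intercept logit(0.16), everything else off -> CS fraction ~ 16%
  geo <- toy_geo(30, seed = 37)
  mesh <- toy_mesh(geo)
  years <- 2001:2002
  prm <- cs_params(beta = c("(Intercept)" = qlogis(0.16), z = 0),
                   omega = 0, sigma_eps = 0.1, rho = 100, alpha = 0.5)
  field <- matrix(0, nrow(mesh$vertices), 2)
  recs <- simulate_custom_births(geo, mesh, field, prm, years,
                                 births_per_cell = 900, seed = 41)
  # ~54k Bernoulli draws: 3 MC standard errors is about 0.005
  expect_lt(abs(mean(recs$cs) - 0.16), 0.005)

  # breech log-OR log(14.40): empirical OR at large n
  prm2 <- cs_params(beta = c("(Intercept)" = qlogis(0.10),
                             breech = log(14.40)),
                    omega = 0, sigma_eps = 0.1, rho = 100, alpha = 0.5)
  recs2 <- simulate_custom_births(
    geo, mesh, field, prm2, years, births_per_cell = 2500,
    covariate_sampler = function(n) data.frame(breech = rbinom(n, 1, 0.3)),
    seed = 43)
  tabb <- table(recs2$breech, recs2$cs)
  emp_or <- (tabb[2, 2] / tabb[2, 1]) / (tabb[1, 2] / tabb[1, 1])
  expect_equal(emp_or, 14.40, tolerance = 0.1)
})

test_that("full registry-style dataset is consistent and deterministic", {
  cfg <- sim_config(n_municipalities = 25, years = 2006:2008,
                    births_meanlog = 3.5, births_sdlog = 0.6, seed = 99)
  sim <- simulate_dataset(cfg)
  expect_true(all(c("record_id", "year", "municipality_id", "cs",
                    "maternal_age_years", "smoking_begin", "smoking_end",
                    "parity_class", "ga_days", "sex", "birthweight_g",
                    "unit_volume", "induction", "complication", "breech",
                    "presentation", "plurality", "onset", "home_delivery")
                  %in% names(sim$records)))
  expect_true(all(sim$records$year %in% 2006:2008))
  expect_equal(dim(sim$field),
               c(nrow(sim$mesh$vertices), 3L))
  expect_true(all(is.finite(sim$truth$eta)))
  # consistency rules: smoking at end implies smoking at begin;
  # breech flag matches presentation
  expect_true(all(sim$records$smoking_begin[sim$records$smoking_end == 1] == 1))
  expect_equal(sim$records$breech,
               as.integer(sim$records$presentation == "breech"))
  # byte-identical reruns
  sim2 <- simulate_dataset(sim_config(n_municipalities = 25,
                                      years = 2006:2008,
                                      births_meanlog = 3.5,
                                      births_sdlog = 0.6, seed = 99))
  expect_identical(sim$records, sim2$records)
  expect_identical(sim$field, sim2$field)

  # missing-value injection blanks filterable columns only when on
  expect_false(anyNA(sim$records$ga_days))
  cfg_m <- sim_config(n_municipalities = 25, years = 2006:2008,
                      births_meanlog = 3.5, births_sdlog = 0.6,
                      missing_frac = 0.05, seed = 99)
  sim_m <- simulate_dataset(cfg_m)
  fr <- mean(is.na(sim_m$records$ga_days))
  expect_gt(fr, 0.02); expect_lt(fr, 0.09)
})

test_that("dataset writer produces readable plain-text artefacts", {
  cfg <- sim_config(n_municipalities = 12, years = 2001:2002,
                    births_meanlog = 3, births_sdlog = 0.4, seed = 3)
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  write_dataset(sim, dir)
  rec <- read.csv(file.path(dir, "records.csv"))
  expect_equal(nrow(rec), nrow(sim$records))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$sigma_eps, sim$truth$params$sigma_eps)
  fld <- read.csv(file.path(dir, "true_field.csv"))
  expect_equal(nrow(fld), prod(dim(sim$field)))
  unlink(dir, recursive = TRUE)
})
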