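test_that("with no data the marginal NLL is exactly zero", {
  geo <- toy_geo(5, seed = 51)
  mesh <- build_mesh(geo, 150, 0, interior_fill = FALSE)
  prm <- cs_params(beta = numeric(0) , omega = 0, sigma_eps = 0.4,
                   rho = 90, alpha = 0.7)

  # an empty table: pure Gaussian normalisation cancels identically
  tab0 <- structure(list(X = matrix(numeric(0), 0, 0),
                         municipality_id = character(0),
                         year = integer(0), n = integer(0),
                         k = integer(0), covariates = character(0)),
                    class = "cs_table")
  out0 <- laplace_marginal_nll(prm, tab0, mesh, reference_year = 2001,
                               years = 2001:2003)
  expect_equal(out0$nll, 0)
  expect_true(all(out0$field_mode == 0))

  # rows present but n = 0 everywhere
  recs <- toy_records(10, seed = 52, geo = geo)
  tab <- aggregate_births(recs, covariates = character(0))
  tab$n <- rep(0L, length(tab$n)); tab$k <- rep(0L, length(tab$k))
  prm1 <- cs_params(beta = c("(Intercept)" = -1), omega = 0,
                    sigma_eps = 0.4, rho = 90, alpha = 0.7)
  out <- laplace_marginal_nll(prm1, tab, mesh)
  expect_equal(out$nll, 0, tolerance = 1e-6)
  expect_lt(max(abs(out$field_mode)), 1e-8)
})

test_that("Laplace matches 1-D adaptive quadrature on a scalar model", {
  # one informative municipality, one year: the field marginalisation
  # reduces to a single scalar integral against the stationary normal;
  # counts are large so the integrand is near-Gaussian and the Laplace
  # machinery must agree to 1e-6 (its O(1/n) bias is below that here)
  geo <- data.frame(municipality_id = c("a", "b", "c"),
                    x_km = c(0, 100, 40), y_km = c(0, 10, 90))
  mesh <- build_mesh(geo, 200, 0, interior_fill = FALSE)
  prm <- cs_params(beta = c("(Intercept)" = qlogis(0.2)), omega = 0,
                   sigma_eps = 0.3, rho = 80, alpha = 0.6)
  n <- 1000000L; k <- 230000L
  tab <- aggregate_births(data.frame(municipality_id = "a", year = 2001L,
                                     cs = 0L), covariates = character(0))
  tab$n <- n; tab$k <- k
  lap <- laplace_marginal_nll(prm, tab, mesh, reference_year = 2001,
                              years = 2001)

  S11 <- solve(as.matrix(spde_precision(mesh, 0.3, 80)$Q))[1, 1] /
    (1 - 0.6^2)
  eta0 <- qlogis(0.2)
  lg <- function(x) k * (eta0 + x) - n * log1p(exp(eta0 + x)) +
    dnorm(x, 0, sqrt(S11), log = TRUE)
  xm <- optimize(function(x) -lg(x), c(-6, 6), tol = 1e-12)$minimum
  m0 <- lg(xm)
  I <- integrate(function(x) exp(lg(x) - m0), -Inf, Inf,
                 rel.tol = 1e-13)$value
  expect_equal(lap$nll, -(m0 + log(I)), tolerance = 1e-6)
})

test_that("Laplace matches a dense-matrix oracle on a 5-vertex toy", {
  geo <- toy_geo(5, seed = 13)
  mesh <- build_mesh(geo, 120, 0, interior_fill = FALSE)
  nv <- nrow(mesh$vertices)
  yrs <- 2001:2003
  recs <- toy_records(200, seed = 55, geo = geo, years = yrs)
  tab <- aggregate_births(recs, covariates = "smoking_begin")
  prm <- cs_params(beta = c("(Intercept)" = -1.3, smoking_begin = 0.25),
                   omega = 0.05, sigma_eps = 0.35, rho = 70, alpha = 0.8)

  # dense oracle: full matrices, dense Newton to machine precision
  Qs <- as.matrix(spde_precision(mesh, 0.35, 70)$Q)
  St <- outer(1:3, 1:3, function(i, j) 0.8^abs(i - j)) / (1 - 0.8^2)
  Q <- kronecker(solve(St), Qs)
  mid <- match(tab$municipality_id, geo$municipality_id)
  tid <- match(tab$year, yrs)
  A <- matrix(0, length(tab$n), nv * 3)
  P <- as.matrix(mesh$projector)
  for (r in seq_along(tab$n))
    A[r, ((tid[r] - 1) * nv + 1):(tid[r] * nv)] <- P[mid[r], ]
  offs <- drop(tab$X %*% prm$beta) + 0.05 * (tab$year - 2002)
  x <- rep(0, nv * 3)
  for (it in 1:60) {
    eta <- offs + A %*% x
    p <- plogis(eta)
    g <- Q %*% x - t(A) %*% (tab$k - tab$n * p)
    H <- Q + t(A) %*% (as.numeric(tab$n * p * (1 - p)) * A)
    x <- x - solve(H, g)
    if (max(abs(g)) < 1e-12) break
  }
  eta <- offs + A %*% x
  p <- plogis(eta)
  H <- Q + t(A) %*% (as.numeric(tab$n * p * (1 - p)) * A)
  joint <- 0.5 * drop(t(x) %*% Q %*% x) +
    sum(tab$n * log1p(exp(eta)) - tab$k * eta)
  dense <- joint - 0.5 * determinant(Q)$modulus +
    0.5 * determinant(H)$modulus

  lap <- laplace_marginal_nll(prm, tab, mesh, reference_year = 2002,
                              years = yrs)
  expect_equal(lap$nll, as.numeric(dense), tolerance = 1e-8)
  expect_equal(as.vector(lap$field_mode), as.vector(x), tolerance = 1e-6)
})

small_sim <- function(seed, n_muni = 30, years = 2001:2006,
                      births = 100, sigma = 0.3, rho = 120, alpha = 0.7,
                      omega = 0.03) {
  true <- cs_params(beta = c("(Intercept)" = qlogis(0.16), z = log(2)),
                    omega = omega, sigma_eps = sigma, rho = rho,
                    alpha = alpha)
  cfg <- sim_config(n_municipalities = n_muni, years = years, seed = seed)
  geo <- simulate_municipalities(cfg)
  mesh <- build_mesh(geo, 60, rho, interior_fill = FALSE)
  field <- simulate_field(mesh, true, years, seed = seed + 1L)
  recs <- simulate_custom_births(geo, mesh, field, true, years, births,
                                 seed = seed + 2L)
  list(true = true, geo = geo, mesh = mesh, field = field, recs = recs,
       tab = aggregate_births(recs, "z"), years = years)
}

test_that("a small fit recovers the truth and degrades gracefully", {
  s <- small_sim(101)
  fit <- fit_cs_model(s$tab, s$mesh)
  expect_true(fit$converged)
  expect_true(all(unlist(fit$se) > 0))
  # loose single-replicate sanity: within 4 SE
  expect_lt(abs(fit$estimates$sigma_eps - 0.3), 4 * fit$se$sigma_eps)
  expect_lt(abs(fit$estimates$alpha - 0.7), 4 * fit$se$alpha)
  expect_lt(abs(fit$estimates$beta[["z"]] - log(2)),
            4 * fit$se$beta[["z"]])

  # truth fits no worse than clearly perturbed hyperparameters
  m <- csfields:::make_machine(s$tab, s$mesh)
  nll_true <- csfields:::machine_nll(m, s$true)$nll
  pert <- s$true; pert$sigma_eps <- 0.9; pert$alpha <- 0.1
  expect_lt(nll_true, csfields:::machine_nll(m, pert)$nll)
})

test_that("profiled and all-parameter outer loops agree", {
  # identical objective, different optimisation strategy: the NLLs must
  # coincide closely; parameter agreement is looser because the
  # (sigma_eps, alpha, rho) likelihood surface has flat ridges at small
  # sample sizes
  s <- small_sim(101)
  f1 <- fit_cs_model(s$tab, s$mesh, profile = TRUE, se = FALSE)
  f2 <- fit_cs_model(s$tab, s$mesh, profile = FALSE, se = FALSE)
  # both stop within rel.tol = 1e-5 of the optimum, i.e. ~0.09 in
  # absolute NLL here
  expect_lt(abs(f1$marginal_nll - f2$marginal_nll), 0.1)
  expect_equal(f1$estimates$sigma_eps, f2$estimates$sigma_eps,
               tolerance = 0.1)
  expect_lt(abs(f1$estimates$alpha - f2$estimates$alpha), 0.05)
  expect_equal(f1$estimates$rho, f2$estimates$rho, tolerance = 0.15)
  expect_equal(f1$estimates$beta, f2$estimates$beta, tolerance = 0.02)
  expect_lt(abs(f1$estimates$omega - f2$estimates$omega), 0.01)
})

test_that("sigma at the boundary: near-zero field truth does not crash", {
  true <- cs_params(beta = c("(Intercept)" = qlogis(0.16)), omega = 0,
                    sigma_eps = 1e-4, rho = 120, alpha = 0.5)
  cfg <- sim_config(n_municipalities = 15, years = 2001:2003, seed = 107)
  geo <- simulate_municipalities(cfg)
  mesh <- build_mesh(geo, 80, 100, interior_fill = FALSE)
  field <- matrix(0, nrow(mesh$vertices), 3)
  recs <- simulate_custom_births(geo, mesh, field, true, 2001:2003, 80,
                                 covariate_sampler = function(n)
                                   data.frame()[seq_len(n), , drop = FALSE],
                                 seed = 108)
  tab <- aggregate_births(recs, character(0))
  fit <- suppressWarnings(fit_cs_model(tab, mesh, se = FALSE))
  expect_lt(fit$estimates$sigma_eps, 0.1)
  expect_true(is.finite(fit$marginal_nll))
})

test_that("standard errors of data-informed effects shrink like 1/sqrt(n)", {
  s1 <- small_sim(111, n_muni = 20, years = 2001:2004, births = 40)
  s2 <- small_sim(111, n_muni = 20, years = 2001:2004, births = 400)
  f1 <- fit_cs_model(s1$tab, s1$mesh)
  f2 <- fit_cs_model(s2$tab, s2$mesh)
  ratio <- f1$se$beta[["z"]] / f2$se$beta[["z"]]
  expect_gt(ratio, 2.2)   # sqrt(10) ~ 3.16, generous band
  expect_lt(ratio, 4.5)

  # prediction error also improves with 10x births
  surf1 <- predict_rates(f1)
  surf2 <- predict_rates(f2)
  truth_rate <- function(s, surf) {
    Pf <- as.matrix(s$mesh$projector %*% s$field)
    mid <- match(surf$municipality_id, s$geo$municipality_id)
    tid <- match(surf$year, s$years)
    plogis(qlogis(0.16) + 0.03 * (surf$year - mean(range(s$years))) +
             Pf[cbind(mid, tid)])
  }
  mae1 <- mean(abs(surf1$rate - truth_rate(s1, surf1)))
  mae2 <- mean(abs(surf2$rate - truth_rate(s2, surf2)))
  expect_lt(mae2, mae1)
})

test_that("predicted rate surfaces follow their closed forms", {
  s <- small_sim(115, n_muni = 15, years = 2001:2004, births = 60)
  fit <- fit_cs_model(s$tab, s$mesh, se = FALSE)
  surf <- predict_rates(fit)
  expect_s3_class(surf, "cs_surface")
  expect_equal(nrow(surf), 15L * 4L)
  expect_true(all(surf$rate > 0 & surf$rate < 1))
  expect_error(predict_rates(fit, years = 2011), "extrapolation")

  # field mode zero -> one shared rate per year, monotone in year
  fit0 <- fit
  fit0$field_mode[] <- 0
  surf0 <- predict_rates(fit0)
  for (y in s$years)
    expect_equal(length(unique(surf0$rate[surf0$year == y])), 1L)
  traj <- surf0$rate[surf0$municipality_id == surf0$municipality_id[1]]
  expect_true(all(diff(traj) > 0) || all(diff(traj) < 0))
})

test_that("delta-method probability-scale SD follows sigma p (1-p)", {
  expect_equal(delta_method_probability_sd(0, 0.3), 0)
  expect_equal(delta_method_probability_sd(0.125, 0.25), 0.0234375)
  expect_equal(delta_method_probability_sd(0.4, 0.5), 0.1)
  expect_error(delta_method_probability_sd(-1, 0.5), "sigma")
})

test_that("stratified fits use the reduced design and skip small strata", {
  cfg <- sim_config(n_municipalities = 12, years = 2001:2003,
                    births_meanlog = 4.2, births_sdlog = 0.4, seed = 121)
  sim <- simulate_dataset(cfg)
  fl <- filter_cohort(sim$records, sim$geo, min_births_per_year = 0)
  # group 6 (first births, breech) is rare: force it below the cutoff
  fits <- suppressWarnings(
    fit_robson(fl$records, sim$mesh, groups = c(1L, 6L),
               min_records = 300L, se = FALSE))
  expect_true("1" %in% names(fits))
  expect_false("6" %in% names(fits))
  f1 <- fits[["1"]]
  expect_s3_class(f1, "cs_fit")
  expect_false(any(c("nulliparous", "prev_cs", "ga_preterm", "induction",
                     "breech") %in% names(f1$estimates$beta)))
  expect_true("smoking_begin" %in% names(f1$estimates$beta))
})
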