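# Shared fixtures, built in code. Everything is seeded and small.

toy_geo <- function(n = 12, seed = 42, width = 300, length = 600) {
  set.seed(seed)
  data.frame(municipality_id = sprintf("m%02d", seq_len(n)),
             x_km = runif(n, 0, width), y_km = runif(n, 0, length))
}

toy_mesh <- function(geo = toy_geo(), ...) {
  build_mesh(geo, max_edge_km = 80, extension_km = 100,
             interior_fill = FALSE, ...)
}

# a minimal record table with every column the pipeline touches
toy_records <- function(n = 50, seed = 1, geo = toy_geo(),
                        years = 2001:2004) {
  set.seed(seed)
  data.frame(
    record_id = sprintf("B%05d", seq_len(n)),
    year = sample(years, n, TRUE),
    municipality_id = sample(geo$municipality_id, n, TRUE),
    cs = rbinom(n, 1, 0.2),
    maternal_age_years = round(runif(n, 18, 40), 1),
    smoking_begin = rbinom(n, 1, 0.15),
    smoking_end = rep(0L, n),
    parity_class = sample(c("nulliparous", "multi_no_cs", "multi_prev_cs"),
                          n, TRUE, prob = c(0.4, 0.5, 0.1)),
    ga_days = as.integer(round(rnorm(n, 280, 10))),
    sex = sample(c("M", "F"), n, TRUE),
    birthweight_g = as.integer(round(rnorm(n, 3500, 500))),
    unit_volume = sample(c("small", "medium", "large"), n, TRUE),
    induction = rbinom(n, 1, 0.15),
    complication = rbinom(n, 1, 0.08),
    breech = rep(0L, n),
    presentation = rep("cephalic", n),
    plurality = rep(1L, n),
    onset = sample(c("spontaneous", "induced", "prelabour_cs"), n, TRUE,
                   prob = c(0.75, 0.15, 0.10)),
    home_delivery = rep(0L, n),
    stringsAsFactors = FALSE)
}

# the 12-row cohort-filter toy: exactly one violation per row, one
# clean survivor; hand-enumerated expectations live in the tests
filter_toy_table <- function() {
  base <- toy_records(n = 12, seed = 7)
  base$home_delivery <- 0L
  base$maternal_age_years <- 30
  base$ga_days <- 280L
  base$year <- 2001L
  base$home_delivery[1] <- 1L          # rule 1: home delivery
  base$maternal_age_years[2] <- 14     # rule 2: too young
  base$maternal_age_years[3] <- 46     # rule 2: too old
  base$ga_days[4] <- 167L              # rule 3: below 24 weeks
  base$municipality_id[5] <- NA        # rule 5: missing municipality
  base$maternal_age_years[6] <- NA     # rule 5: missing age
  base$ga_days[7] <- NA                # rule 5: missing GA
  base$sex[8] <- NA                    # rule 5: missing sex
  base$birthweight_g[9] <- NA          # rule 5: missing birthweight
  base$unit_volume[10] <- NA           # rule 5: missing unit
  base$presentation[11] <- NA          # rule 5: missing presentation
  base                                 # row 12 survives
}

expect_params_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$beta, b$beta, tolerance = tol)
  expect_equal(a$omega, b$omega, tolerance = tol)
  expect_equal(a$sigma_eps, b$sigma_eps, tolerance = tol)
  expect_equal(a$rho, b$rho, tolerance = tol)
  expect_equal(a$alpha, b$alpha, tolerance = tol)
}
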