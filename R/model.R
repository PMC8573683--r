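# Joint model: binomial logistic observations with a separable
# spatio-temporal latent Gaussian field.
#
# logit P(CS) = x'beta + omega * (year - reference year) + u(s, t)
# where u is Matern-in-space (SPDE GMRF) and AR(1)-in-time with
# year-to-year correlation alpha and spatial innovation SD sigma_eps.
# The separable precision is Q_time(alpha) %x% Q_space(sigma_eps, rho);
# with a stationary first year the implied marginal variance at every
# location is sigma_eps^2 / (1 - alpha^2) and the lag-1 correlation is
# alpha exactly.

#' Model parameters of the spatio-temporal CS model
#'
#' @param beta named numeric vector of fixed effects on the logit scale
#'   (first element is the intercept).
#' @param omega annual linear time trend (logit scale per year).
#' @param sigma_eps spatial innovation standard deviation (logit scale, > 0).
#' @param rho spatial correlation range in km (> 0).
#' @param alpha year-to-year autocorrelation, in (-1, 1).
#' @return object of class `cs_params`.
#' @export
cs_params <- function(beta, omega, sigma_eps, rho, alpha) {
  stopifnot(is.numeric(beta), is.numeric(omega), length(omega) == 1L)
  if (!is.numeric(sigma_eps) || sigma_eps <= 0)
    stop2("sigma_eps must be positive")
  if (!is.numeric(rho) || rho <= 0) stop2("rho must be positive")
  if (!is.numeric(alpha) || abs(alpha) >= 1)
    stop2("alpha must lie strictly in (-1, 1)")
  if (is.null(names(beta)) && length(beta) > 0L)
    names(beta) <- c("(Intercept)",
                     paste0("beta", seq_len(length(beta) - 1L)))[seq_along(beta)]
  structure(list(beta = beta, omega = omega, sigma_eps = sigma_eps,
                 rho = rho, alpha = alpha),
            class = "cs_params")
}

#' @export
print.cs_params <- function(x, ...) {
  cat("Spatio-temporal CS model parameters\n")
  cat(sprintf("  sigma_eps = %.4g  rho = %.4g km  alpha = %.4g  omega = %.4g\n",
              x$sigma_eps, x$rho, x$alpha, x$omega))
  cat("  beta:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Stationary AR(1) precision matrix with unit innovation variance
#'
#' Tridiagonal; determinant `1 - alpha^2` for every length, so the
#' stationary marginal variance is `1 / (1 - alpha^2)`. For a single
#' time point it degenerates to the stationary marginal precision.
#'
#' @param alpha autocorrelation in (-1, 1).
#' @param n_time number of time points (>= 1).
#' @return sparse symmetric matrix.
#' @keywords internal
ar1_precision <- function(alpha, n_time) {
  if (abs(alpha) >= 1) stop2("alpha must lie strictly in (-1, 1)")
  if (n_time == 1L)
    return(Matrix::Matrix(1 - alpha^2, 1, 1, sparse = TRUE))
  d <- c(1, rep(1 + alpha^2, n_time - 2L), 1)
  Matrix::bandSparse(n_time, k = c(-1L, 0L, 1L),
                     diagonals = list(rep(-alpha, n_time - 1L), d,
                                      rep(-alpha, n_time - 1L)),
                     symmetric = FALSE)
}

#' Stationary moments of the separable space-time field
#'
#' @param params a [cs_params()].
#' @return list with `stationary_sd` = `sigma_eps / sqrt(1 - alpha^2)`
#'   and `lag1_corr` = `alpha`.
#' @export
marginal_moments <- function(params) {
  stopifnot(inherits(params, "cs_params"))
  if (abs(params$alpha) >= 1) stop2("alpha must lie strictly in (-1, 1)")
  list(stationary_sd = params$sigma_eps / sqrt(1 - params$alpha^2),
       lag1_corr = params$alpha)
}

#' Odds ratio of a logistic fixed effect
#'
#' @param beta_j coefficient(s) on the logit scale.
#' @return `exp(beta_j)`.
#' @export
odds_ratio <- function(beta_j) {
  stopifnot(is.numeric(beta_j), all(is.finite(beta_j)))
  exp(beta_j)
}

# ---- covariate design ------------------------------------------------

#' Standard covariate set of the main analysis
#'
#' Categorical groupings follow the registry convention: maternal age
#' 15-19 / 20-34 (ref) / 35-44, parity nulliparous / multiparous without
#' previous CS (ref) / multiparous with previous CS, gestational age
#' < 37 weeks / 37 to 41+6 (ref) / >= 42 weeks, unit volume small /
#' medium (ref) / large, macrosomia > 4500 g, plus binary smoking
#' (begin/end of pregnancy), induction, complication, female sex and
#' breech indicators.
#'
#' @return character vector of covariate names.
#' @export
standard_covariates <- function() {
  c("smoking_begin", "smoking_end", "age_class", "parity_class",
    "ga_class", "unit_volume", "induction", "complication", "sex",
    "macrosomia", "breech")
}

#' Covariates retained in the Robson-stratified models
#'
#' Parity, gestational-age class, induction and breech define the strata
#' and are removed from the stratified design.
#'
#' @return character vector of covariate names.
#' @export
stratified_covariates <- function() {
  setdiff(standard_covariates(),
          c("parity_class", "ga_class", "induction", "breech"))
}

ga_class_of <- function(ga_days) {
  cut(ga_days, c(-Inf, 258.5, 293.5, Inf),
      labels = c("preterm", "term", "post_term"))
}

age_class_of <- function(age) {
  cut(age, c(-Inf, 19.5, 34.5, Inf), labels = c("15-19", "20-34", "35-44"))
}

#' Build the fixed-effect design matrix for birth records
#'
#' Reference levels carry no column: age 20-34, multiparous without
#' previous CS, term gestation, medium unit, male sex, and absence of
#' each binary factor. Unknown covariate names are taken as numeric
#' columns of `records` used as-is (handy for simulation studies).
#'
#' @param records birth-record data frame.
#' @param covariates character vector (default [standard_covariates()]).
#' @return numeric matrix with an `(Intercept)` first column.
#' @export
build_design <- function(records, covariates = standard_covariates()) {
  n <- nrow(records)
  cols <- list("(Intercept)" = rep(1, n))
  for (cv in covariates) {
    if (cv %in% c("smoking_begin", "smoking_end", "induction",
                  "complication", "breech")) {
      cols[[cv]] <- as.numeric(records[[cv]])
    } else if (cv == "age_class") {
      a <- age_class_of(records$maternal_age_years)
      cols[["age15_19"]] <- as.numeric(a == "15-19")
      cols[["age35_44"]] <- as.numeric(a == "35-44")
    } else if (cv == "parity_class") {
      p <- records$parity_class
      cols[["nulliparous"]] <- as.numeric(p == "nulliparous")
      cols[["prev_cs"]] <- as.numeric(p == "multi_prev_cs")
    } else if (cv == "ga_class") {
      g <- ga_class_of(records$ga_days)
      cols[["ga_preterm"]] <- as.numeric(g == "preterm")
      cols[["ga_post_term"]] <- as.numeric(g == "post_term")
    } else if (cv == "unit_volume") {
      u <- records$unit_volume
      cols[["unit_small"]] <- as.numeric(u == "small")
      cols[["unit_large"]] <- as.numeric(u == "large")
    } else if (cv == "sex") {
      cols[["sex_female"]] <- as.numeric(records$sex == "F")
    } else if (cv == "macrosomia") {
      cols[["macrosomia"]] <- as.numeric(records$birthweight_g > 4500)
    } else {
      if (is.null(records[[cv]]))
        stop2("covariate column not found in records: ", cv)
      cols[[cv]] <- as.numeric(records[[cv]])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (any(!is.finite(X))) stop2("non-finite design entries; filter first")
  X
}

#' Aggregate Bernoulli birth records into binomial design rows
#'
#' Lossless for the likelihood: records sharing municipality, year and
#' covariate pattern collapse to one row with trial count `n` and CS
#' count `k`. Row order is canonical (sorted by key), so permuting the
#' input leaves the table identical.
#'
#' @param records birth-record data frame with `municipality_id`,
#'   `year`, `cs` and the covariate columns.
#' @param covariates passed to [build_design()].
#' @return object of class `cs_table`: list with design matrix `X`,
#'   vectors `municipality_id`, `year`, `n`, `k`, and the covariate set.
#' @export
aggregate_births <- function(records, covariates = standard_covariates()) {
  if (nrow(records) == 0L) {
    X <- matrix(numeric(0), 0L, 1L, dimnames = list(NULL, "(Intercept)"))
    return(structure(list(X = X, municipality_id = character(0),
                          year = integer(0), n = integer(0), k = integer(0),
                          covariates = covariates),
                     class = "cs_table"))
  }
  X <- build_design(records, covariates)
  key <- do.call(paste, c(list(records$municipality_id, records$year),
                          lapply(seq_len(ncol(X)), function(j) X[, j]),
                          sep = "\r"))
  ord <- order(key, method = "radix")
  key <- key[ord]
  first <- !duplicated(key)
  grp <- cumsum(first)
  n <- as.integer(rowsum(rep(1L, length(grp)), grp))
  k <- as.integer(rowsum(as.integer(records$cs[ord]), grp))
  sel <- ord[first]
  structure(list(X = X[sel, , drop = FALSE],
                 municipality_id = records$municipality_id[sel],
                 year = as.integer(records$year[sel]),
                 n = n, k = k, covariates = covariates),
            class = "cs_table")
}

#' @export
print.cs_table <- function(x, ...) {
  cat(sprintf("Binomial design table: %d rows, %d births (%d CS), %d covariate columns\n",
              length(x$n), sum(x$n), sum(x$k), ncol(x$X)))
  invisible(x)
}

# numerically safe binomial deviance pieces: n*log(1+e^eta) - k*eta
binom_nll_terms <- function(eta, n, k) {
  n * (pmax(eta, 0) + log1p(exp(-abs(eta)))) - k * eta
}

#' Joint negative log-likelihood of data and latent field
#'
#' `-log p(field; sigma_eps, rho, alpha) - log p(k | n, eta)` with
#' `eta = X beta + omega (year - reference_year) + projected field`.
#' The Gaussian prior uses the separable precision
#' `Q_time(alpha) %x% Q_space(sigma_eps, rho)` with stationary first
#' year; the binomial term omits the combinatorial constant, so it
#' equals the sum of the per-birth Bernoulli likelihoods.
#'
#' @param params a [cs_params()]; `params$beta` must match `table$X`.
#' @param field numeric matrix, mesh vertices x years (ordered as
#'   `years`).
#' @param table a [aggregate_births()] result.
#' @param mesh a [build_mesh()] mesh whose projector covers the table's
#'   municipalities.
#' @param reference_year year at which the linear trend is zero
#'   (default: midpoint of the observed years).
#' @param years the year labels of the field columns (default: the
#'   sorted unique years in `table`).
#' @return scalar negative log joint density.
#' @export
joint_nll <- function(params, field, table, mesh,
                      reference_year = NULL, years = NULL) {
  stopifnot(inherits(params, "cs_params"), inherits(table, "cs_table"))
  years <- years %||% sort(unique(table$year))
  reference_year <- reference_year %||% mean(range(years))
  nv <- nrow(mesh$vertices)
  field <- as.matrix(field)
  if (!all(dim(field) == c(nv, length(years))))
    stop2("field must be ", nv, " x ", length(years))
  Qs <- spde_precision(mesh, params$sigma_eps, params$rho)
  prior <- field_prior_nll(field, Qs, params$alpha)
  eta <- linear_predictor(params, field, table, mesh, reference_year, years)
  terms <- binom_nll_terms(eta, table$n, table$k)
  if (any(!is.finite(terms)))
    stop2("non-finite likelihood contribution at table row ",
          which(!is.finite(terms))[1L])
  prior + sum(terms)
}

field_prior_nll <- function(field, Qs, alpha) {
  nv <- nrow(field); n_time <- ncol(field)
  Qt <- ar1_precision(alpha, n_time)
  quad <- sum(field * as.matrix(Qs$Q %*% field %*% Matrix::t(Qt)))
  ldet_Qs <- 2 * as.numeric(Matrix::determinant(Qs$chol, sqrt = TRUE)$modulus)
  ldet_Qt <- log(1 - alpha^2)  # closed form for the stationary AR(1)
  0.5 * quad - 0.5 * (n_time * ldet_Qs + nv * ldet_Qt) +
    (nv * n_time / 2) * log(2 * pi)
}

linear_predictor <- function(params, field, table, mesh,
                             reference_year, years) {
  if (ncol(table$X) != length(params$beta))
    stop2("beta length (", length(params$beta),
          ") does not match design columns (", ncol(table$X), ")")
  eta <- drop(table$X %*% params$beta) +
    params$omega * (table$year - reference_year)
  if (length(table$n) > 0L) {
    mid <- match(table$municipality_id, mesh$municipality_id)
    if (anyNA(mid))
      stop2("municipality missing from mesh projector: ",
            table$municipality_id[which(is.na(mid))[1L]])
    tid <- match(table$year, years)
    Pf <- as.matrix(mesh$projector %*% field)
    eta <- eta + Pf[cbind(mid, tid)]
  }
  eta
}
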