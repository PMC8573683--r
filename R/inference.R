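# Maximum-likelihood inference via the Laplace approximation.
#
# The latent field is integrated out by a Gaussian (Laplace)
# approximation around its conditional mode, found by sparse Newton
# iterations; hyperparameters and fixed effects are then maximised by a
# quasi-Newton outer optimiser on transformed scales (log sigma_eps,
# log rho, scaled logit of alpha; beta and omega raw). Outer
# derivatives are central finite differences (step 1e-4) -- the
# portable stand-in for the automatic differentiation of TMB-style
# stacks. Heavy lifting (sparsity patterns, symbolic factorisations)
# is cached in the evaluation machine of machine.R.

#' Laplace-approximated marginal negative log-likelihood
#'
#' Integrates the latent field out of [joint_nll()] by a Gaussian
#' approximation at the conditional field mode (the empirical-Bayes
#' field estimate): `joint_nll(mode) + log det(H)/2 - d log(2 pi)/2`,
#' `H` being the curvature of the joint NLL at the mode. With no data
#' the result is exactly zero and the mode is zero.
#'
#' @inheritParams joint_nll
#' @return list: `nll`, `field_mode` (vertices x years matrix),
#'   `inner_iterations`, `inner_grad_max`.
#' @export
laplace_marginal_nll <- function(params, table, mesh,
                                 reference_year = NULL, years = NULL) {
  stopifnot(inherits(params, "cs_params"))
  m <- make_machine(table, mesh, reference_year, years)
  res <- machine_nll(m, params)
  list(nll = res$nll,
       field_mode = matrix(res$mode, m$nv, m$n_time,
                           dimnames = list(NULL, m$years)),
       inner_iterations = res$iterations,
       inner_grad_max = res$grad_max)
}

# ---- parameter transformations ---------------------------------------

pack_theta <- function(params) {
  c(params$beta, omega = unname(params$omega),
    log_sigma = log(params$sigma_eps), log_rho = log(params$rho),
    t_alpha = 2 * atanh(params$alpha))  # scaled logit onto (-1, 1)
}

unpack_theta <- function(theta, beta_names) {
  p <- length(beta_names)
  cs_params(beta = setNames(theta[seq_len(p)], beta_names),
            omega = theta[[p + 1L]],
            sigma_eps = exp(theta[[p + 2L]]),
            rho = exp(theta[[p + 3L]]),
            alpha = tanh(theta[[p + 4L]] / 2))
}

# moment-based starting values: beta and omega from a plain logistic
# fit, then alpha / sigma_eps / rho from the lag-1 correlation, excess
# variance and correlogram range of the cell-level residual logits.
# Only an initializer -- crude but cheap, and it roughly halves the
# outer iteration count.
moment_init <- function(table, mesh, m, beta_names) {
  Xi <- cbind(table$X, year_c = table$year - m$reference_year)
  g0 <- suppressWarnings(
    stats::glm.fit(Xi, cbind(table$k, table$n - table$k),
                   family = stats::binomial()))
  cf <- g0$coefficients
  cf[!is.finite(cf)] <- 0
  eta0 <- drop(Xi %*% cf)

  cell <- paste(table$municipality_id, table$year)
  K <- rowsum(table$k, cell); N <- rowsum(table$n, cell)
  Eta <- rowsum(table$n * eta0, cell) / N
  ids <- do.call(rbind, strsplit(rownames(K), " "))
  r <- qlogis((K + 0.5) / (N + 1)) - Eta
  phat <- pmin(pmax((K + 0.5) / (N + 1), 0.02), 0.98)
  noise <- 1 / (N * phat * (1 - phat))

  df <- data.frame(muni = ids[, 1], year = as.integer(ids[, 2]),
                   r = as.numeric(r), w = as.numeric(N),
                   noise = as.numeric(noise))
  df <- df[order(df$muni, df$year), ]
  lag_ok <- with(df, muni == c(muni[-1], NA) & year + 1L == c(year[-1], NA))
  alpha0 <- if (sum(lag_ok, na.rm = TRUE) > 10)
    suppressWarnings(stats::cor(df$r[which(lag_ok)],
                                df$r[which(lag_ok) + 1L])) else 0.5
  if (!is.finite(alpha0)) alpha0 <- 0.5
  alpha0 <- min(max(alpha0, 0.1), 0.95)

  v <- max(stats::var(df$r) - mean(df$noise), 1e-4)
  sigma0 <- min(max(sqrt(v * (1 - alpha0^2)), 0.02), 2)

  rbar <- rowsum(df$r, df$muni) / rowsum(rep(1, nrow(df)), df$muni)
  cent <- mesh$vertices[match(rownames(rbar), mesh$municipality_id), ,
                        drop = FALSE]
  keep <- !is.na(cent[, 1])
  rbar <- rbar[keep]; cent <- cent[keep, , drop = FALSE]
  rho0 <- NA_real_
  if (length(rbar) >= 20L) {
    D <- as.matrix(dist(cent))
    rc <- rbar - mean(rbar)
    v0 <- mean(rc^2)
    brks <- seq(0, max(D) / 2, length.out = 11L)
    cg <- vapply(seq_len(10L), function(b) {
      sel <- D > brks[b] & D <= brks[b + 1L]
      if (sum(sel) < 10) return(NA_real_)
      mean(outer(rc, rc)[sel]) / v0
    }, numeric(1))
    mids <- (brks[-1] + brks[-11L]) / 2
    below <- which(!is.na(cg) & cg < 0.14)
    if (length(below) > 0L) rho0 <- mids[below[1L]]
  }
  if (!is.finite(rho0)) {
    cs <- cent[seq_len(min(nrow(cent), 300L)), , drop = FALSE]
    rho0 <- median(dist(cs)) / 2
  }
  rho0 <- min(max(rho0, 5), 2000)

  cs_params(beta = setNames(cf[seq_along(beta_names)], beta_names),
            omega = unname(cf[["year_c"]]),
            sigma_eps = sigma0, rho = rho0, alpha = alpha0)
}

central_gradient <- function(fn, theta, h = 1e-4) {
  vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (fn(theta + e) - fn(theta - e)) / (2 * h)
  }, numeric(1))
}

#' Fit the spatio-temporal CS model by Laplace-approximated ML
#'
#' Outer quasi-Newton optimisation (`nlminb`) over the transformed
#' parameters with central-finite-difference gradients (step `1e-4`);
#' inner Newton tolerance `1e-8` on the gradient max-norm, at most 100
#' inner iterations. Standard errors come from the inverse numerical
#' Hessian of the marginal NLL, mapped to the natural scales by the
#' delta method. If that Hessian is not positive definite the fit is
#' still returned, with `NA` standard errors and a warning.
#'
#' @param table an [aggregate_births()] design table.
#' @param mesh a [build_mesh()] mesh covering the table's
#'   municipalities.
#' @param init optional [cs_params()] starting values; by default beta
#'   and omega come from a plain fixed-effects logistic fit,
#'   `sigma_eps = 0.1`, `rho` = median inter-centroid distance,
#'   `alpha = 0.5`.
#' @param reference_year year at which the linear trend is zero
#'   (default: midpoint of the observed years).
#' @param years field years (default: observed years).
#' @param outer_tol relative tolerance of the outer optimiser.
#' @param max_outer maximum outer iterations.
#' @param se compute standard errors (default `TRUE`; the extra
#'   Hessian evaluations roughly double the cost of a small fit).
#' @param inner_tol inner Newton gradient tolerance used during outer
#'   optimisation; the final evaluation always re-converges at `1e-8`.
#' @param profile profile the fixed effects (beta, omega) into the
#'   inner Newton problem (default `TRUE`), leaving only the three
#'   hyperparameters to the finite-difference outer optimiser; their
#'   standard errors then come from the profile-likelihood Hessian and
#'   those of the fixed effects from the Schur complement of the joint
#'   curvature at the mode. `FALSE` optimises every parameter in the
#'   outer loop (slower, identical estimates up to optimiser
#'   tolerance).
#' @return object of class `cs_fit`: `estimates` ([cs_params()]),
#'   `se` (same shape, natural scale), `field_mode` (empirical Bayes),
#'   `marginal_nll`, `converged`, iteration counts, and the inputs
#'   needed by [predict_rates()].
#' @export
fit_cs_model <- function(table, mesh, init = NULL,
                         reference_year = NULL, years = NULL,
                         outer_tol = 1e-5, max_outer = 200L, se = TRUE,
                         inner_tol = 1e-6, profile = TRUE) {
  if (length(table$n) == 0L) stop2("empty design table")
  m <- make_machine(table, mesh, reference_year, years)
  beta_names <- colnames(table$X)

  if (is.null(init)) init <- moment_init(table, mesh, m, beta_names)
  stopifnot(length(init$beta) == length(beta_names))

  if (profile) {
    fit_profiled(m, init, beta_names, outer_tol, max_outer, se,
                 inner_tol)
  } else {
    fit_full_outer(m, init, beta_names, outer_tol, max_outer, se,
                   inner_tol)
  }
}

# outer optimisation over the hyperparameters only; beta and omega
# solved in the inner Newton together with the field.
#
# The profiled objective evaluates the fixed effects at the joint
# (field, beta) mode, which neglects the d(log det H)/d(beta) term of
# the exact Laplace marginal; for covariates that push p far from 1/2
# this displaces beta by an amount comparable to its standard error at
# registry sample sizes. A final refinement stage therefore
# re-optimises (beta, omega) against the exact Laplace marginal at the
# converged hyperparameters (cheap: the prior assembly is cached, each
# evaluation is one warm inner Newton over the field alone).
fit_profiled <- function(m, init, beta_names, outer_tol, max_outer,
                         se, inner_tol) {
  warm <- new.env(parent = emptyenv())
  warm$z <- c(numeric(ncol(m$A)), init$beta, init$omega)
  n_eval <- 0L
  obj <- function(th) {
    sg <- exp(th[[1L]]); rh <- exp(th[[2L]]); al <- tanh(th[[3L]] / 2)
    if (rh < 1e-2 || rh > 1e5 || sg > 50 || abs(al) > 1 - 1e-10)
      return(1e10)
    res <- tryCatch({
      out <- machine_nll_profile(m, sg, rh, al, z0 = warm$z,
                                 tol = inner_tol)
      warm$z <- c(out$x, out$b)
      out$nll
    }, error = function(e) NA_real_)
    n_eval <<- n_eval + 1L
    if (!is.finite(res)) 1e10 else res
  }
  grad <- function(th) central_gradient(obj, th, h = 1e-4)
  th0 <- c(log(init$sigma_eps), log(init$rho), 2 * atanh(init$alpha))
  opt <- nlminb(th0, obj, gradient = grad,
                control = list(rel.tol = outer_tol, iter.max = max_outer,
                               eval.max = 4L * max_outer))
  sg <- exp(opt$par[[1L]]); rh <- exp(opt$par[[2L]])
  al <- tanh(opt$par[[3L]] / 2)
  final <- machine_nll_profile(m, sg, rh, al, z0 = warm$z, tol = 1e-8)
  p <- length(beta_names)

  # refinement: exact-marginal optimisation of (beta, omega) at the
  # converged hyperparameters
  wx <- new.env(parent = emptyenv())
  wx$x <- final$x
  obj_b <- function(bv) {
    prm <- cs_params(beta = setNames(bv[seq_len(p)], beta_names),
                     omega = bv[[p + 1L]],
                     sigma_eps = sg, rho = rh, alpha = al)
    res <- tryCatch({
      out <- machine_nll(m, prm, x0 = wx$x, tol = inner_tol)
      wx$x <- out$mode
      out$nll
    }, error = function(e) NA_real_)
    n_eval <<- n_eval + 1L
    if (!is.finite(res)) 1e10 else res
  }
  grad_b <- function(bv) central_gradient(obj_b, bv, h = 1e-4)
  opt_b <- nlminb(final$b, obj_b, gradient = grad_b,
                  control = list(rel.tol = outer_tol,
                                 iter.max = max_outer))
  est <- cs_params(beta = setNames(opt_b$par[seq_len(p)], beta_names),
                   omega = opt_b$par[[p + 1L]],
                   sigma_eps = sg, rho = rh, alpha = al)
  final_x <- machine_nll(m, est, x0 = wx$x, tol = 1e-8)
  final$x <- final_x$mode
  final$nll <- final_x$nll
  final$iterations <- final_x$iterations
  # joint curvature blocks at the refined mode, for the beta SEs
  eta_f <- drop(m$Xt %*% opt_b$par) + as.numeric(m$A %*% final$x)
  p_f <- plogis(eta_f)
  w_f <- pmax(m$table$n * p_f * (1 - p_f), 1e-12)
  B_f <- as.matrix(m$At %*% (w_f * m$Xt))
  D_f <- crossprod(m$Xt, w_f * m$Xt)
  HiB_f <- as.matrix(Matrix::solve(m$chol_H, B_f))
  final$schur <- D_f - crossprod(B_f, HiB_f)

  se_list <- NULL
  if (se) {
    Hout <- tryCatch(optimHess(opt$par, obj, gr = grad),
                     error = function(e) NULL)
    Vh <- if (!is.null(Hout))
      tryCatch(solve(Hout), error = function(e) NULL) else NULL
    Vb <- tryCatch(solve(final$schur), error = function(e) NULL)
    if (is.null(Vh) || any(diag(Vh) <= 0) || is.null(Vb) ||
        any(diag(Vb) <= 0)) {
      warning("curvature not positive definite; standard errors are ",
              "undefined", call. = FALSE)
      se_list <- list(beta = setNames(rep(NA_real_, p), beta_names),
                      omega = NA_real_, sigma_eps = NA_real_,
                      rho = NA_real_, alpha = NA_real_)
    } else {
      sh <- sqrt(diag(Vh)); sb <- sqrt(diag(Vb))
      se_list <- list(
        beta = setNames(sb[seq_len(p)], beta_names),
        omega = sb[p + 1L],
        sigma_eps = sg * sh[1L],               # d exp(t)/dt
        rho = rh * sh[2L],
        alpha = (1 - al^2) / 2 * sh[3L])       # d tanh(t/2)/dt
    }
  }

  structure(list(estimates = est, se = se_list,
                 field_mode = matrix(final$x, m$nv, m$n_time,
                                     dimnames = list(NULL, m$years)),
                 marginal_nll = final$nll,
                 converged = opt$convergence == 0,
                 message = opt$message,
                 n_outer_iterations = opt$iterations,
                 n_evaluations = n_eval,
                 n_inner_iterations = final$iterations,
                 years = m$years, reference_year = m$reference_year,
                 mesh = m$mesh, covariates = m$table$covariates),
            class = "cs_fit")
}

# outer optimisation over all parameters (transformed scales)
fit_full_outer <- function(m, init, beta_names, outer_tol, max_outer,
                           se, inner_tol) {
  warm <- new.env(parent = emptyenv())
  warm$x <- NULL
  n_eval <- 0L
  obj <- function(theta) {
    prm <- unpack_theta(theta, beta_names)
    # keep the optimiser off absurd scales where the FEM approximation
    # or the AR(1) determinant degenerate numerically
    if (prm$rho < 1e-2 || prm$rho > 1e5 || prm$sigma_eps > 50 ||
        abs(prm$alpha) > 1 - 1e-10)
      return(1e10)
    res <- tryCatch({
      out <- machine_nll(m, prm, x0 = warm$x, tol = inner_tol)
      warm$x <- out$mode
      out$nll
    }, error = function(e) NA_real_)
    n_eval <<- n_eval + 1L
    if (!is.finite(res)) 1e10 else res
  }
  grad <- function(theta) central_gradient(obj, theta, h = 1e-4)

  theta0 <- pack_theta(init)
  opt <- nlminb(theta0, obj, gradient = grad,
                control = list(rel.tol = outer_tol, iter.max = max_outer,
                               eval.max = 4L * max_outer))
  est <- unpack_theta(opt$par, beta_names)
  final <- machine_nll(m, est, x0 = warm$x, tol = 1e-8)

  se_list <- NULL
  if (se) {
    Hout <- tryCatch(optimHess(opt$par, obj, gr = grad),
                     error = function(e) NULL)
    V <- if (!is.null(Hout))
      tryCatch(solve(Hout), error = function(e) NULL) else NULL
    if (is.null(V) || any(diag(V) <= 0)) {
      warning("outer Hessian not positive definite; standard errors ",
              "are undefined", call. = FALSE)
      se_list <- list(beta = setNames(rep(NA_real_, length(beta_names)),
                                      beta_names),
                      omega = NA_real_, sigma_eps = NA_real_,
                      rho = NA_real_, alpha = NA_real_)
    } else {
      s <- sqrt(diag(V))
      p <- length(beta_names)
      se_list <- list(
        beta = setNames(s[seq_len(p)], beta_names),
        omega = s[p + 1L],
        sigma_eps = est$sigma_eps * s[p + 2L],        # d exp(t)/dt
        rho = est$rho * s[p + 3L],
        alpha = (1 - est$alpha^2) / 2 * s[p + 4L])    # d tanh(t/2)/dt
    }
  }

  structure(list(estimates = est, se = se_list,
                 field_mode = matrix(final$mode, m$nv, m$n_time,
                                     dimnames = list(NULL, m$years)),
                 marginal_nll = final$nll,
                 converged = opt$convergence == 0,
                 message = opt$message,
                 n_outer_iterations = opt$iterations,
                 n_evaluations = n_eval,
                 n_inner_iterations = final$iterations,
                 years = m$years, reference_year = m$reference_year,
                 mesh = m$mesh, covariates = m$table$covariates),
            class = "cs_fit")
}

#' @export
print.cs_fit <- function(x, ...) {
  cat("Spatio-temporal CS model fit",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  marginal NLL %.4f after %d outer iterations\n",
              x$marginal_nll, x$n_outer_iterations))
  print(parameter_table(x))
  invisible(x)
}

#' Predicted CS rates at the reference covariate profile
#'
#' `logit^-1(beta_0 + omega (year - reference year) + projected field
#' mode)` for every municipality-year: the small-area rate surface at
#' reference values of all covariates.
#'
#' @param fit a [fit_cs_model()] result.
#' @param years years to predict (must lie inside the fitted window; no
#'   extrapolation).
#' @return data frame of class `cs_surface` with `municipality_id`,
#'   `year`, `rate`.
#' @export
predict_rates <- function(fit, years = fit$years) {
  stopifnot(inherits(fit, "cs_fit"))
  if (!all(years %in% fit$years))
    stop2("no extrapolation: requested year(s) outside the fitted window: ",
          paste(setdiff(years, fit$years), collapse = ", "))
  P <- fit$mesh$projector
  ids <- fit$mesh$municipality_id
  Pf <- as.matrix(P %*% fit$field_mode)
  out <- do.call(rbind, lapply(years, function(y) {
    eta <- fit$estimates$beta[[1L]] +
      fit$estimates$omega * (y - fit$reference_year) +
      Pf[, match(y, fit$years)]
    data.frame(municipality_id = ids, year = y, rate = plogis(eta))
  }))
  rownames(out) <- NULL
  class(out) <- c("cs_surface", class(out))
  out
}

#' Delta-method standard error on the probability scale
#'
#' Transforms a logit-scale standard deviation to the probability scale
#' at probability `p`: `sigma * p * (1 - p)`.
#'
#' @param sigma_logit standard deviation on the logit scale (>= 0).
#' @param p probability in (0, 1).
#' @return standard error on the probability scale.
#' @export
delta_method_probability_sd <- function(sigma_logit, p) {
  stopifnot(all(sigma_logit >= 0), all(p > 0 & p < 1))
  sigma_logit * p * (1 - p)
}

#' Stratified fits for the Robson groups
#'
#' Classifies records, builds the requested strata and fits the same
#' spatio-temporal model to each with the reduced covariate set (no
#' parity, gestational-age class, induction or breech). Strata smaller
#' than `min_records` are skipped with a warning.
#'
#' @param records filtered birth records.
#' @param mesh mesh covering the records' municipalities.
#' @param groups Robson groups to fit (default `c(1, 3, 5, 6)`).
#' @param min_records minimum stratum size (default 1000).
#' @param ... passed to [fit_cs_model()].
#' @return named list of `cs_fit` objects.
#' @export
fit_robson <- function(records, mesh, groups = c(1L, 3L, 5L, 6L),
                       min_records = 1000L, ...) {
  strata <- stratify_robson(records, groups)
  out <- list()
  for (gr in names(strata)) {
    str <- strata[[gr]]
    if (nrow(str) < min_records) {
      warning("Robson group ", gr, " has only ", nrow(str),
              " records; skipped", call. = FALSE)
      next
    }
    tab <- aggregate_births(str, attr(str, "covariates"))
    out[[gr]] <- fit_cs_model(tab, mesh, ...)
  }
  out
}
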