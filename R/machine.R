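# Cached evaluation engine for the Laplace marginal likelihood.
#
# Everything that depends only on the mesh, the years and the design --
# finite-element matrices, the sparsity pattern of the separable
# precision Q_time %x% Q_space, slot maps into the compressed-column
# storage, the observation matrix A, and Cholesky symbolic analyses --
# is computed once. Each hyperparameter evaluation then only refills
# numeric values and runs numeric factorisations, which is what makes
# finite-difference outer optimisation affordable in plain R.

sparse_lookup <- function(M, i, j) {
  # values of sparse M at (i, j) positions, vectorised via key match
  Tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
  key <- (as.numeric(Tm@i)) * (ncol(M) + 1) + as.numeric(Tm@j)
  q <- (as.numeric(i) - 1) * (ncol(M) + 1) + (as.numeric(j) - 1)
  v <- Tm@x[match(q, key)]
  v[is.na(v)] <- 0
  v
}

make_machine <- function(table, mesh, reference_year = NULL, years = NULL) {
  stopifnot(inherits(table, "cs_table"))
  years <- years %||% sort(unique(table$year))
  reference_year <- reference_year %||% mean(range(years))
  nv <- nrow(mesh$vertices)
  n_time <- length(years)

  fem <- fem_matrices(mesh)
  cdiag <- Matrix::diag(fem$C)
  GCG <- Matrix::forceSymmetric(fem$G %*% ((1 / cdiag) * fem$G))

  # union sparsity pattern of Q_space, upper triangle (row <= col)
  patt <- as(as(Matrix::forceSymmetric(
    GCG + fem$G + Matrix::Diagonal(nv, 1)), "generalMatrix"),
    "TsparseMatrix")
  up <- patt@i <= patt@j
  iu <- patt@i[up] + 1L; ju <- patt@j[up] + 1L
  c_up <- ifelse(iu == ju, cdiag[iu], 0)
  g_up <- sparse_lookup(fem$G, iu, ju)
  gcg_up <- sparse_lookup(GCG, iu, ju)

  Qs_tmpl <- Matrix::sparseMatrix(i = iu, j = ju,
                                  x = seq_along(iu), dims = c(nv, nv),
                                  symmetric = TRUE)
  qs_slot <- Qs_tmpl@x  # triplet index occupying each storage slot

  # full (two-triangle) space pattern, with a map back to upper values
  off <- iu != ju
  if_ <- c(iu, ju[off]); jf <- c(ju, iu[off])
  mirror <- c(seq_along(iu), which(off))

  # upper triangle of Q_time %x% Q_space:
  #  T diagonal time-blocks carry the upper space pattern,
  #  T-1 superdiagonal time-blocks carry the full space pattern
  if (n_time > 1L) {
    kr_i <- c(rep(iu, n_time) + rep((0:(n_time - 1L)) * nv, each = length(iu)),
              rep(if_, n_time - 1L) + rep((0:(n_time - 2L)) * nv,
                                          each = length(if_)))
    kr_j <- c(rep(ju, n_time) + rep((0:(n_time - 1L)) * nv, each = length(ju)),
              rep(jf, n_time - 1L) + rep((1:(n_time - 1L)) * nv,
                                         each = length(jf)))
  } else {
    kr_i <- iu; kr_j <- ju
  }
  Q_tmpl <- Matrix::sparseMatrix(i = kr_i, j = kr_j, x = seq_along(kr_i),
                                 dims = c(nv * n_time, nv * n_time),
                                 symmetric = TRUE)
  q_slot <- Q_tmpl@x

  # observation matrix A: table rows -> vec(field), space within year
  mid <- match(table$municipality_id, mesh$municipality_id)
  if (anyNA(mid))
    stop2("municipality missing from mesh projector: ",
          table$municipality_id[which(is.na(mid))[1L]])
  tid <- match(table$year, years)
  if (anyNA(tid)) stop2("table contains a year outside `years`")
  N <- length(table$n)
  if (N > 0L) {
    Pm <- as(as(mesh$projector[mid, , drop = FALSE], "generalMatrix"),
             "TsparseMatrix")
    A <- Matrix::sparseMatrix(i = Pm@i + 1L,
                              j = Pm@j + 1L + (tid[Pm@i + 1L] - 1L) * nv,
                              x = Pm@x, dims = c(N, nv * n_time))
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(0L, nv * n_time))
  }

  m <- new.env(parent = emptyenv())
  m$table <- table; m$mesh <- mesh; m$years <- years
  m$reference_year <- reference_year
  m$nv <- nv; m$n_time <- n_time
  m$c_up <- c_up; m$g_up <- g_up; m$gcg_up <- gcg_up
  m$Qs_tmpl <- Qs_tmpl; m$qs_slot <- qs_slot
  m$Q_tmpl <- Q_tmpl; m$q_slot <- q_slot
  m$n_upper <- length(iu); m$mirror <- mirror
  m$A <- A; m$At <- Matrix::t(A)
  m$chol_Qs <- NULL; m$chol_H <- NULL
  m$prior_key <- NULL

  # pattern of H = Q + A'WA with slot maps for in-place numeric fill
  if (N > 0L) {
    AtWA0 <- Matrix::forceSymmetric(Matrix::crossprod(A))
    H0 <- Matrix::forceSymmetric(Q_tmpl + AtWA0)
    # dsCMatrix storage keys, in slot order
    slot_keys <- function(S) {
      ii <- S@i  # 0-based row indices per column
      jj <- rep.int(seq_len(ncol(S)) - 1L, diff(S@p))
      as.numeric(ii) * nrow(S) + as.numeric(jj)
    }
    hk <- slot_keys(H0)
    m$H_tmpl <- H0
    m$h_from_q <- match(slot_keys(as(Q_tmpl, "CsparseMatrix")), hk)
    m$h_from_a <- match(slot_keys(as(AtWA0, "CsparseMatrix")), hk)
    m$nnz_H <- length(hk)
  } else {
    m$H_tmpl <- Q_tmpl
    m$h_from_q <- seq_along(Q_tmpl@x)
    m$h_from_a <- integer(0)
    m$nnz_H <- length(Q_tmpl@x)
  }
  # dense fixed-effect design with the centred year column appended,
  # used by the profiled inner problem
  m$Xt <- cbind(table$X, year_c = table$year - reference_year)
  m
}

# refill Q_space and the Kronecker precision for given hyperparameters;
# returns list(Q, q_x, ldet); cached on the hyperparameter triple so
# fixed-effect-only perturbations skip the assembly entirely
machine_prior <- function(m, sigma_eps, rho, alpha) {
  key <- c(sigma_eps, rho, alpha)
  if (!is.null(m$prior_key) && identical(m$prior_key, key))
    return(m$prior_cache)
  kappa <- sqrt(8) / rho
  tau2 <- 1 / (sigma_eps^2 * kappa^2 * 4 * pi)
  qs_up <- tau2 * (kappa^4 * m$c_up + 2 * kappa^2 * m$g_up + m$gcg_up)

  Qs <- m$Qs_tmpl
  Qs@x <- qs_up[m$qs_slot]
  m$chol_Qs <- if (is.null(m$chol_Qs)) {
    Matrix::Cholesky(Qs, LDL = FALSE, perm = TRUE, super = TRUE)
  } else {
    Matrix::update(m$chol_Qs, Qs)
  }
  ldet_Qs <- 2 * as.numeric(Matrix::determinant(m$chol_Qs,
                                                sqrt = TRUE)$modulus)

  n_time <- m$n_time
  if (n_time > 1L) {
    qt_diag <- c(1, rep(1 + alpha^2, n_time - 2L), 1)
    qs_full <- qs_up[m$mirror]
    vals <- c(rep(qt_diag, each = m$n_upper) * rep(qs_up, n_time),
              rep(-alpha, (n_time - 1L) * length(qs_full)) *
                rep(qs_full, n_time - 1L))
  } else {
    vals <- (1 - alpha^2) * qs_up
  }
  Q <- m$Q_tmpl
  q_x <- vals[m$q_slot]
  Q@x <- q_x
  out <- list(Q = Q, q_x = q_x,
              ldet = n_time * ldet_Qs + m$nv * log(1 - alpha^2))
  m$prior_key <- key
  m$prior_cache <- out
  out
}

# one Laplace marginal NLL evaluation on the machine
machine_nll <- function(m, params, x0 = NULL,
                        tol = 1e-8, max_iter = 100L) {
  pr <- machine_prior(m, params$sigma_eps, params$rho, params$alpha)
  offs <- drop(m$table$X %*% params$beta) +
    params$omega * (m$table$year - m$reference_year)
  nw <- machine_newton(m, pr, offs, x0 = x0, tol = tol,
                       max_iter = max_iter)
  ldet_H <- 2 * as.numeric(Matrix::determinant(nw$chol, sqrt = TRUE)$modulus)
  list(nll = nw$value - 0.5 * pr$ldet + 0.5 * ldet_H,
       mode = nw$mode, iterations = nw$iterations,
       grad_max = nw$grad_max)
}

machine_newton <- function(m, pr, offs, x0 = NULL,
                           tol = 1e-8, max_iter = 100L) {
  d <- ncol(m$A)
  Q <- pr$Q
  x <- x0 %||% numeric(d)
  n <- m$table$n; k <- m$table$k
  f_of <- function(x) {
    eta <- offs + as.numeric(m$A %*% x)
    0.5 * sum(x * as.numeric(Q %*% x)) +
      sum(binom_nll_terms(eta, n, k))
  }
  f <- f_of(x)
  if (!is.finite(f)) { x <- numeric(d); f <- f_of(x) }
  factor_at <- function(w) {
    # in-place numeric fill of the fixed H = Q + A'WA pattern
    h_x <- numeric(m$nnz_H)
    h_x[m$h_from_q] <- pr$q_x
    if (length(m$h_from_a) > 0L) {
      AtWA <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% m$A)
      h_x[m$h_from_a] <- h_x[m$h_from_a] + AtWA@x
    }
    H <- m$H_tmpl
    H@x <- h_x
    if (is.null(m$chol_H)) {
      m$chol_H <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
    } else {
      m$chol_H <- tryCatch(Matrix::update(m$chol_H, H),
                           error = function(e)
                             Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE))
    }
    m$chol_H
  }
  for (it in seq_len(max_iter)) {
    eta <- offs + as.numeric(m$A %*% x)
    p <- plogis(eta)
    g <- as.numeric(Q %*% x) - as.numeric(m$At %*% (k - n * p))
    gmax <- if (length(g)) max(abs(g)) else 0
    w <- pmax(n * p * (1 - p), 1e-12)
    ch <- factor_at(w)
    if (gmax < tol)
      return(list(mode = x, chol = ch, iterations = it - 1L,
                  grad_max = gmax, value = f))
    dx <- -as.numeric(Matrix::solve(ch, g))
    step <- 1
    repeat {
      x_new <- x + step * dx
      f_new <- f_of(x_new)
      if (is.finite(f_new) && f_new <= f + 1e-12 * abs(f)) break
      step <- step / 2
      if (step < 1e-10)
        stop2("inner Newton line search failed; |grad|_max = ",
              signif(gmax, 4))
    }
    x <- x_new; f <- f_new
  }
  stop2("inner Newton did not converge in ", max_iter,
        " iterations; |grad|_max = ", signif(gmax, 4))
}

# Laplace marginal NLL with the fixed effects (beta, omega) profiled
# into the inner problem: the inner Newton solves jointly for
# z = (field, beta, omega) -- a sparse system bordered by the dense
# fixed-effect block, handled by block elimination with the same cached
# sparse factor -- and the log-determinant correction uses the
# field block only. This is the standard device of AD-based mixed-model
# stacks: it leaves only the three hyperparameters to the
# finite-difference outer optimiser, at the price of evaluating the
# fixed effects at the joint mode rather than the exact profile
# optimum (a negligible O(1/n) displacement for binomial data at this
# scale).
machine_nll_profile <- function(m, sigma_eps, rho, alpha,
                                z0 = NULL, tol = 1e-6, max_iter = 100L) {
  pr <- machine_prior(m, sigma_eps, rho, alpha)
  Q <- pr$Q
  d <- ncol(m$A)
  Xt <- m$Xt
  p <- ncol(Xt)
  n <- m$table$n; k <- m$table$k
  z <- z0 %||% c(numeric(d), qlogis(max(min(sum(k) / sum(n), 0.99), 0.01)),
                 numeric(p - 1L))
  x <- z[seq_len(d)]; b <- z[-seq_len(d)]
  f_of <- function(x, b) {
    eta <- drop(Xt %*% b) + as.numeric(m$A %*% x)
    0.5 * sum(x * as.numeric(Q %*% x)) + sum(binom_nll_terms(eta, n, k))
  }
  f <- f_of(x, b)
  if (!is.finite(f)) { x <- numeric(d); b[] <- 0; f <- f_of(x, b) }
  # gradient tolerance for the dense block: curvature there is O(sum n),
  # so a looser absolute threshold loses nothing at fit precision
  tol_b <- max(tol * 100, 1e-4)
  ch <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(Xt %*% b) + as.numeric(m$A %*% x)
    pfit <- plogis(eta)
    res <- k - n * pfit
    g_x <- as.numeric(Q %*% x) - as.numeric(m$At %*% res)
    g_b <- -drop(crossprod(Xt, res))
    w <- pmax(n * pfit * (1 - pfit), 1e-12)
    h_x <- numeric(m$nnz_H)
    h_x[m$h_from_q] <- pr$q_x
    AtWA <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% m$A)
    h_x[m$h_from_a] <- h_x[m$h_from_a] + AtWA@x
    H <- m$H_tmpl
    H@x <- h_x
    ch <- if (is.null(m$chol_H)) {
      Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
    } else {
      tryCatch(Matrix::update(m$chol_H, H),
               error = function(e) Matrix::Cholesky(H, LDL = FALSE,
                                                    perm = TRUE,
                                                    super = TRUE))
    }
    m$chol_H <- ch
    B <- as.matrix(m$At %*% (w * Xt))            # d x p border
    D <- crossprod(Xt, w * Xt)                   # p x p dense block
    HiB <- as.matrix(Matrix::solve(ch, B))
    S <- D - crossprod(B, HiB)                   # Schur complement
    if (max(abs(g_x)) < tol && max(abs(g_b)) < tol_b) {
      ldet_H <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
      return(list(nll = f - 0.5 * pr$ldet + 0.5 * ldet_H,
                  x = x, b = b, chol = ch, schur = S,
                  iterations = it - 1L,
                  grad_max = max(abs(g_x), abs(g_b))))
    }
    Hig <- as.numeric(Matrix::solve(ch, g_x))
    db <- solve(S, -g_b + drop(crossprod(B, Hig)))
    dx <- -Hig - drop(HiB %*% db)
    step <- 1
    repeat {
      x_new <- x + step * dx; b_new <- b + step * db
      f_new <- f_of(x_new, b_new)
      if (is.finite(f_new) && f_new <= f + 1e-12 * abs(f)) break
      step <- step / 2
      if (step < 1e-10)
        stop2("profiled inner Newton line search failed; |grad| = ",
              signif(max(abs(g_x), abs(g_b)), 4))
    }
    x <- x_new; b <- b_new; f <- f_new
  }
  stop2("profiled inner Newton did not converge in ", max_iter,
        " iterations")
}
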