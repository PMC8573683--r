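# SPDE representation of the isotropic Matern field (smoothness nu = 1).
#
# The continuous model is a zero-mean Gaussian random field with Matern
# correlation r(d) = kappa * d * K_1(kappa * d), kappa = sqrt(8) / rho,
# so that r(rho) ~ 0.14 -- the usual "correlation has dropped to about
# 0.1 at the range" convention. Discretising the order-2 SPDE with
# linear finite elements gives the sparse precision
#   Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G),
# with tau fixed by the nominal marginal variance 1 / (4 pi kappa^2 tau^2).

#' Matern correlation with smoothness one
#'
#' `r(d) = kappa d K_1(kappa d)` with `kappa = sqrt(8) / rho`; by
#' continuity `r(0) = 1`. Under this convention the correlation at
#' distance `rho` is about 0.14, conventionally read as "dropped to
#' approximately 0.1".
#'
#' @param d distances in km (vector, >= 0).
#' @param rho correlation range in km (> 0).
#' @return correlations in \[0, 1\].
#' @export
matern_correlation <- function(d, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop2("rho must be a single positive number")
  if (any(d < 0)) stop2("distances must be non-negative")
  kd <- sqrt(8) / rho * d
  r <- ifelse(kd == 0, 1, kd * besselK(pmax(kd, 1e-300), 1))
  # besselK underflows for very large arguments; the limit is 0
  r[!is.finite(r)] <- 0
  pmin(pmax(r, 0), 1)
}

#' Sparse SPDE precision of the Matern field on a mesh
#'
#' @param mesh a `cs_mesh` (see [build_mesh()]).
#' @param sigma target marginal standard deviation (logit scale, > 0).
#' @param rho correlation range in km (> 0).
#' @param fem optional pre-computed [fem_matrices()] result, so repeated
#'   assemblies during optimisation reuse the geometry.
#' @return object of class `cs_spde`: list with sparse SPD `Q`, and the
#'   parameters `kappa`, `tau`, `sigma`, `rho`.
#' @export
spde_precision <- function(mesh, sigma, rho, fem = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop2("sigma must be positive")
  if (!is.numeric(rho) || rho <= 0) stop2("rho must be positive")
  if (is.null(fem)) fem <- fem_matrices(mesh)
  kappa <- sqrt(8) / rho
  tau <- 1 / (sigma * kappa * sqrt(4 * pi))
  cinv <- 1 / Matrix::diag(fem$C)
  GCG <- fem$G %*% (cinv * fem$G)
  Q <- tau^2 * (kappa^4 * fem$C + 2 * kappa^2 * fem$G + GCG)
  Q <- Matrix::forceSymmetric((Q + Matrix::t(Q)) / 2)
  ch <- tryCatch(Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) {
    ev <- tryCatch(min(eigen(as.matrix(Q), symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) NA_real_)
    stop2("assembled SPDE precision is not positive definite ",
          "(smallest eigenvalue ~ ", signif(ev, 3), ")")
  }
  structure(list(Q = Q, kappa = kappa, tau = tau, sigma = sigma,
                 rho = rho, chol = ch),
            class = "cs_spde")
}

#' Draw zero-mean samples from a sparse-precision Gaussian
#'
#' @param Q sparse SPD precision (or a `cs_spde`).
#' @param n number of draws.
#' @param chol optional pre-computed `Cholesky(Q, LDL = FALSE, perm = TRUE)`.
#' @return matrix, `nrow(Q)` x `n`.
#' @keywords internal
rgmrf <- function(Q, n = 1L, chol = NULL) {
  if (inherits(Q, "cs_spde")) {
    chol <- Q$chol
    Q <- Q$Q
  }
  if (is.null(chol)) chol <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(nrow(Q) * n), nrow(Q), n)
  x <- Matrix::solve(chol, Matrix::solve(chol, z, system = "Lt"),
                     system = "Pt")
  as.matrix(x)
}

#' Write a sparse matrix as coordinate triplets (debug format)
#'
#' Plain-text `i j x` triplets with a one-line header; readable with
#' [read_sparse_triplets()].
#'
#' @param Q sparse matrix.
#' @param path output file.
#' @export
write_sparse_triplets <- function(Q, path) {
  Tm <- as(as(Q, "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%%coordinate %d %d %d", nrow(Tm), ncol(Tm),
                     length(Tm@x)), con)
  writeLines(sprintf("%d %d %.17g", Tm@i + 1L, Tm@j + 1L, Tm@x), con)
  invisible(path)
}

#' @rdname write_sparse_triplets
#' @param path file written by [write_sparse_triplets()].
#' @export
read_sparse_triplets <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  dims <- as.integer(hdr[2:3])
  m <- matrix(scan(path, skip = 1L, quiet = TRUE), ncol = 3L, byrow = TRUE)
  Matrix::sparseMatrix(i = m[, 1], j = m[, 2], x = m[, 3], dims = dims)
}
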