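#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats dbinom optim nlminb plogis qlogis rbinom rnorm
#'   runif median dist integrate optimHess setNames quantile sd var cor
#'   binomial glm.fit rlnorm rpois pnorm
#' @importFrom utils read.csv write.csv
NULL

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

#' Derive independent per-stage random seeds from one master seed
#'
#' Simulation stages (municipality layout, latent field, covariates,
#' outcomes) each get their own stream so that adding draws to one stage
#' never shifts the draws of another.
#'
#' @param seed master integer seed.
#' @param n number of streams.
#' @return integer vector of `n` seeds, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_missing_val <- function(x) {
  is.na(x) | (is.character(x) & (x == "" | x == "NA"))
}
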