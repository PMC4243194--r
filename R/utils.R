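# Small numeric helpers shared across modules.

logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moments of a logit-normal prevalence distribution
#'
#' Computes the mean and standard deviation of `plogis(mu + sigma * Z)`,
#' `Z ~ N(0,1)`, by fixed-grid Gaussian quadrature. Used to moment-match the
#' between-cluster coefficient of variation of the synthetic generator.
#'
#' @param mu location on the logit scale.
#' @param sigma standard deviation on the logit scale (>= 0).
#' @return list with elements `mean`, `sd`, `cv`.
#' @keywords internal
logitnormal_moments <- function(mu, sigma) {
  if (sigma == 0) {
    m <- invlogit(mu)
    return(list(mean = m, sd = 0, cv = 0))
  }
  z <- seq(-8, 8, length.out = 801)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  p <- invlogit(mu + sigma * z)
  m1 <- sum(w * p)
  m2 <- sum(w * p^2)
  v <- max(m2 - m1^2, 0)
  list(mean = m1, sd = sqrt(v), cv = sqrt(v) / m1)
}

#' Calibrate a logit-normal cluster model to a target mean and CV
#'
#' Finds `(mu, sigma)` such that site prevalences drawn as
#' `plogis(mu + sigma * Z)` have mean `p_target` and coefficient of variation
#' `k`. Solved by alternating one-dimensional root finding on the quadrature
#' moments; converges in a handful of iterations for all feasible inputs.
#'
#' @param p_target target mean prevalence, in (0, 1).
#' @param k target coefficient of variation of true prevalence (>= 0).
#' @return list with `mu`, `sigma`.
#' @keywords internal
calibrate_logitnormal <- function(p_target, k) {
  stopifnot(p_target > 0, p_target < 1, k >= 0)
  if (k == 0) return(list(mu = logit(p_target), sigma = 0))
  # a bounded prevalence cannot have CV >= sqrt((1-p)/p)
  k_max <- sqrt((1 - p_target) / p_target)
  if (k >= 0.98 * k_max) {
    stop("infeasible calibration: k = ", k, " too large for mean prevalence ",
         p_target, " (upper bound ", signif(k_max, 3), ")")
  }
  mu <- logit(p_target)
  sigma <- k  # starting value; exact for small sigma near p = 0.5
  for (iter in 1:40) {
    # given mu, solve sigma for the CV
    f_cv <- function(s) logitnormal_moments(mu, s)$cv - k
    hi <- 1
    while (f_cv(hi) < 0 && hi < 30) hi <- hi * 2
    sigma_new <- stats::uniroot(f_cv, c(1e-8, hi), tol = 1e-10)$root
    # given sigma, solve mu for the mean
    f_m <- function(m) logitnormal_moments(m, sigma_new)$mean - p_target
    mu_new <- stats::uniroot(f_m, c(mu - 10, mu + 10), tol = 1e-12)$root
    done <- abs(mu_new - mu) < 1e-9 && abs(sigma_new - sigma) < 1e-9
    mu <- mu_new
    sigma <- sigma_new
    if (done) break
  }
  list(mu = mu, sigma = sigma)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  force(seed)  # a seed drawn from the RNG must be consumed before the save
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
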