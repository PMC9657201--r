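# Moment-matched truncated normal / lognormal marginals.
#
# The cohort tables report mean, SD and observed range per variable. Sampling
# from an untruncated law and clipping to the range distorts both moments
# (for the right-skewed fat-mass laws the SD shrinks by ~10%), so the
# generator solves for underlying parameters such that the *truncated*
# distribution reproduces the printed mean and SD exactly.

tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (Z <= 0) return(c(NA_real_, NA_real_))
  pa <- stats::dnorm(al); pb <- stats::dnorm(be)
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (al * pa - be * pb) / Z - ((pa - pb) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

tlnorm_moments <- function(mu, sigma, a, b) {
  la <- log(a); lb <- log(b)
  Z <- stats::pnorm((lb - mu) / sigma) - stats::pnorm((la - mu) / sigma)
  if (Z <= 0) return(c(NA_real_, NA_real_))
  mk <- function(k) {
    exp(k * mu + k^2 * sigma^2 / 2) *
      (stats::pnorm((lb - mu - k * sigma^2) / sigma) -
         stats::pnorm((la - mu - k * sigma^2) / sigma)) / Z
  }
  m1 <- mk(1); m2 <- mk(2)
  c(m1, sqrt(max(m2 - m1^2, 0)))
}

.calib_cache <- new.env(parent = emptyenv())

calibrate_marginal <- function(mean, sd, min, max, family = c("normal", "lognormal")) {
  family <- match.arg(family)
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  min <- as.numeric(min); max <- as.numeric(max)
  key <- paste(family, mean, sd, min, max, sep = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  assert_that(min < max && mean > min && mean < max && sd > 0,
              "marginal requires min < mean < max and sd > 0")
  moments <- if (family == "normal") tnorm_moments else tlnorm_moments
  start <- if (family == "normal") {
    c(mean, log(sd))
  } else {
    s2 <- log(1 + (sd / mean)^2)
    c(log(mean) - s2 / 2, log(sqrt(s2)))
  }
  obj <- function(p) {
    m <- moments(p[1], exp(p[2]), min, max)
    if (anyNA(m)) return(1e6)
    ((m[1] - mean) / sd)^2 + ((m[2] - sd) / sd)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  out <- list(family = family, mu = fit$par[1], sigma = exp(fit$par[2]),
              min = min, max = max, target = c(mean = mean, sd = sd),
              achieved = moments(fit$par[1], exp(fit$par[2]), min, max))
  .calib_cache[[key]] <- out
  out
}

# Quantile of the calibrated truncated marginal, via its Gaussian score.
# `z` is a standard-normal deviate; the copula construction feeds correlated
# scores through this map so marginals are exact by construction.
qmarginal <- function(z, cal) {
  p <- stats::pnorm(z)
  if (cal$family == "normal") {
    lo <- stats::pnorm(cal$min, cal$mu, cal$sigma)
    hi <- stats::pnorm(cal$max, cal$mu, cal$sigma)
    stats::qnorm(lo + p * (hi - lo), cal$mu, cal$sigma)
  } else {
    lo <- stats::plnorm(cal$min, cal$mu, cal$sigma)
    hi <- stats::plnorm(cal$max, cal$mu, cal$sigma)
    stats::qlnorm(lo + p * (hi - lo), cal$mu, cal$sigma)
  }
}
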