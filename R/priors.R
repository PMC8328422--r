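#' Priors for random-effect standard deviations
#'
#' Three prior families for the standard deviation of a Gaussian random
#' effect (and the residual SD), plus a degenerate `fixed` family used to
#' freeze a variance component (e.g. for exact-oracle checks):
#'
#' * `prior_pc(U, alpha)`: the penalized-complexity prior, an exponential
#'   density on the SD with rate `lambda = -log(alpha)/U`, so that
#'   `P(sigma > U) = alpha`. It shrinks toward the simpler model
#'   (`sigma = 0`) at a constant rate.
#' * `prior_half_cauchy(scale)`: half-Cauchy on the SD.
#' * `prior_inv_gamma(shape, rate)`: Gamma prior on the precision
#'   `tau = sigma^-2` (the classic "default" diffuse choice,
#'   shape 1, rate 5e-5); conjugate, so the sampler uses a Gibbs update.
#' * `prior_fixed(value)`: the SD is held at `value`.
#'
#' @param U,alpha PC-prior scaling: `P(sigma > U) = alpha`.
#' @param scale half-Cauchy scale.
#' @param shape,rate Gamma hyperparameters on the precision.
#' @param value fixed SD.
#' @return A list of class `sd_prior` with `family` and hyperparameters.
#' @name sd_priors
NULL

#' @rdname sd_priors
#' @export
prior_pc <- function(U = 1, alpha = 0.01) {
  stopifnot(U > 0, alpha > 0, alpha < 1)
  structure(list(family = "pc", U = U, alpha = alpha,
                 lambda = -log(alpha) / U), class = "sd_prior")
}

#' @rdname sd_priors
#' @export
prior_half_cauchy <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(list(family = "half_cauchy", scale = scale), class = "sd_prior")
}

#' @rdname sd_priors
#' @export
prior_inv_gamma <- function(shape = 1, rate = 5e-5) {
  stopifnot(shape > 0, rate > 0)
  structure(list(family = "inv_gamma", shape = shape, rate = rate),
            class = "sd_prior")
}

#' @rdname sd_priors
#' @export
prior_fixed <- function(value) {
  stopifnot(value > 0)
  structure(list(family = "fixed", value = value), class = "sd_prior")
}

#' Log density of the penalized-complexity prior for a standard deviation
#'
#' The PC prior for the SD of a Gaussian random effect is exponential with
#' rate `lambda = -log(alpha)/U`; by construction `P(sigma > U) = alpha`
#' and the density at the base model `sigma = 0` equals `lambda`.
#'
#' @param sigma positive SD value(s).
#' @inheritParams sd_priors
#' @return log density at `sigma`.
#' @export
pc_prior_logdensity <- function(sigma, U = 1, alpha = 0.01) {
  stopifnot(all(sigma > 0), U > 0, alpha > 0, alpha < 1)
  lambda <- -log(alpha) / U
  log(lambda) - lambda * sigma
}

# log prior density on the SD scale, any family
sd_prior_logdensity <- function(sigma, prior) {
  switch(prior$family,
    pc = pc_prior_logdensity(sigma, prior$U, prior$alpha),
    half_cauchy = log(2) - log(pi * prior$scale *
                                 (1 + (sigma / prior$scale)^2)),
    inv_gamma = {
      # Gamma(shape, rate) on tau = sigma^-2, transformed to sigma
      tau <- sigma^-2
      stats::dgamma(tau, prior$shape, rate = prior$rate, log = TRUE) +
        log(2) - 3 * log(sigma)
    },
    fixed = ifelse(sigma == prior$value, 0, -Inf),
    stop("unknown prior family: ", prior$family))
}

# one draw of sigma given sum of squares SS over k deviates; generic slice
# sampler on log(sigma), conjugate shortcut for the inverse-gamma family
draw_sigma <- function(sigma, SS, k, prior) {
  if (prior$family == "fixed") return(prior$value)
  if (prior$family == "inv_gamma") {
    tau <- stats::rgamma(1, prior$shape + k / 2, rate = prior$rate + SS / 2)
    return(1 / sqrt(tau))
  }
  logpost <- function(x) {
    s <- exp(x)
    -k * x - SS / (2 * s^2) + sd_prior_logdensity(s, prior) + x
  }
  exp(slice_sample_1d(log(sigma), logpost, w = 0.5, m = 50))
}

# univariate stepping-out slice sampler (Neal 2003); uses the current RNG
slice_sample_1d <- function(x0, logf, w = 1, m = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(m * stats::runif(1))
  k <- m - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}
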