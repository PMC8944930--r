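## Candidate dwell-time distribution models for the colocalized state:
## kinetic (truncated exponential), diffusion (Brownian first-return,
## t^(-3/2) tail) and subdiffusion (fractional-Gaussian persistence,
## t^(-(2 - B/2)) tail), with maximum-likelihood fitting and AIC ranking.
##
## The diffusion and subdiffusion densities share the inverse-gamma-type
## form f(t) proportional to t^(-p) exp(-tau/t) on [t_min, t_max]: a pure
## power-law tail with exponent -p and an exponential short-time
## regularizer controlled by the timescale tau.  p = 3/2 is the Brownian
## first-return (Levy-Smirnov) case; p = 2 - B/2 encodes the persistence
## exponent 1 - B/2 of a self-similar Gaussian process with MSD ~ t^B.

## Normalisation integral of t^(-p) exp(-tau/t) over [t_min, t_max].
pl_exp_norm <- function(p, tau, t_min, t_max = Inf) {
  s <- p - 1
  if (tau <= 0) {
    if (is.infinite(t_max)) return(t_min^(-s) / s)
    return((t_min^(-s) - t_max^(-s)) / s)
  }
  lo <- if (is.infinite(t_max)) 0 else pgamma(tau / t_max, s)
  tau^(-s) * gamma(s) * (pgamma(tau / t_min, s) - lo)
}

pl_exp_pdf <- function(t, p, tau, t_min, t_max = Inf) {
  Z <- pl_exp_norm(p, tau, t_min, t_max)
  out <- ifelse(t < t_min | t > t_max, 0, t^(-p) * exp(-tau / t) / Z)
  out
}

#' Kinetic dwell-time model (truncated exponential)
#'
#' Poisson-distributed transition times: `f(t) = rate * exp(-rate (t -
#' t_min))` on `[t_min, Inf)`.
#'
#' @param t Dwell times, s.
#' @param rate Transition rate, per s.
#' @param t_min Lower truncation (temporal resolution), s.
#' @return Density values.
#' @export
kinetic_pdf <- function(t, rate, t_min = 30) {
  stopifnot(rate > 0)
  ifelse(t < t_min, 0, rate * exp(-rate * (t - t_min)))
}

#' Diffusion dwell-time model (Brownian first-return)
#'
#' First-passage-type density with the Brownian `t^(-3/2)` tail,
#' regularised at short times by `exp(-timescale / t)` and normalised on
#' `[t_min, Inf)`.
#'
#' @param t Dwell times, s.
#' @param timescale Short-time regularisation timescale, s.
#' @param t_min Lower truncation, s.
#' @return Density values.
#' @export
diffusion_pdf <- function(t, timescale, t_min = 30) {
  stopifnot(timescale >= 0)
  pl_exp_pdf(t, 3 / 2, timescale, t_min)
}

#' Subdiffusion dwell-time model (fractional-Gaussian persistence)
#'
#' First-passage density of a self-similar Gaussian process whose MSD
#' scales as `t^B`: persistence exponent `1 - B/2`, hence density tail
#' `t^(-(2 - B/2))`, regularised at short times and normalised on
#' `[t_min, Inf)`.  `B = 1` recovers the diffusion tail `t^(-3/2)`.
#'
#' @param t Dwell times, s.
#' @param timescale Short-time regularisation timescale, s.
#' @param B MSD power-law exponent, in (0, 2).
#' @param t_min Lower truncation, s.
#' @return Density values.
#' @export
subdiffusion_pdf <- function(t, timescale, B = 0.24, t_min = 30) {
  stopifnot(timescale >= 0, B > 0, B < 2)
  pl_exp_pdf(t, 2 - B / 2, timescale, t_min)
}

#' Sample from a dwell-time model
#'
#' @param n Sample size.
#' @param model `"kinetic"`, `"diffusion"` or `"subdiffusion"`.
#' @param rate Kinetic rate, per s.
#' @param timescale Diffusion/subdiffusion timescale, s.
#' @param B Subdiffusion MSD exponent.
#' @param t_min,t_max Truncation bounds, s.
#' @return Numeric vector of dwell times.
#' @export
r_dwell <- function(n, model = c("kinetic", "diffusion", "subdiffusion"),
                    rate = 1 / 60, timescale = 30, B = 0.24, t_min = 30,
                    t_max = Inf) {
  model <- match.arg(model)
  if (model == "kinetic") {
    out <- t_min + rexp(n, rate)
    if (is.finite(t_max)) { # resample the (rare) over-long draws
      while (any(out > t_max))
        out[out > t_max] <- t_min + rexp(sum(out > t_max), rate)
    }
    return(out)
  }
  p <- if (model == "diffusion") 3 / 2 else 2 - B / 2
  s <- p - 1
  ## v = tau/t is Gamma(s) truncated to [tau/t_max, tau/t_min]
  hi <- pgamma(timescale / t_min, s)
  lo <- if (is.infinite(t_max)) 0 else pgamma(timescale / t_max, s)
  u <- runif(n, lo, hi)
  v <- qgamma(u, s)
  timescale / v
}

## Log-likelihoods on [t_min, t_max]
loglik_kinetic <- function(t, rate, t_min, t_max) {
  Z <- if (is.finite(t_max)) 1 - exp(-rate * (t_max - t_min)) else 1
  sum(log(rate) - rate * (t - t_min) - log(Z))
}

loglik_pl_exp <- function(t, p, tau, t_min, t_max) {
  sum(-p * log(t) - tau / t) - length(t) * log(pl_exp_norm(p, tau, t_min, t_max))
}

#' Fit and rank the three dwell-time models
#'
#' Maximum-likelihood fits of the kinetic, diffusion and subdiffusion models
#' on `[t_min, t_max]` (right truncation at the movie length is handled by
#' truncating the likelihood), ranked by AIC.
#'
#' @param dwells A `dwell_sample` data.frame (uncensored colocalized dwells
#'   are used) or a numeric vector of dwell times, s.
#' @param t_min Lower truncation, s.
#' @param t_max Upper truncation (movie length), s; `Inf` to disable.
#' @param min_n Minimum number of dwells required.
#' @return A data.frame of class `dwell_model_fits` with columns `model`,
#'   `rate`, `timescale`, `B`, `loglik`, `AIC`, `delta_AIC`, sorted best
#'   first.
#' @export
fit_dwell_models <- function(dwells, t_min = 30, t_max = Inf, min_n = 20) {
  t <- if (is.data.frame(dwells)) {
    d <- dwells[dwells$state == "colocalized" & !dwells$censored, , drop = FALSE]
    d$duration
  } else as.numeric(dwells)
  t <- t[t >= t_min & t <= t_max]
  if (length(t) < min_n)
    stop("need at least ", min_n, " uncensored dwells in [t_min, t_max]; got ",
         length(t))
  ## kinetic
  ok <- optimize(function(lr) -loglik_kinetic(t, exp(lr), t_min, t_max),
                 c(log(1e-6), log(1)))
  k_rate <- exp(ok$minimum); k_ll <- -ok$objective
  ## diffusion
  od <- optimize(function(ltau) -loglik_pl_exp(t, 3 / 2, exp(ltau), t_min, t_max),
                 c(log(1e-4), log(1e6)))
  d_tau <- exp(od$minimum); d_ll <- -od$objective
  ## subdiffusion (timescale and B)
  os <- optim(c(log(median(t)), 0.24),
              function(par) {
                B <- par[2]
                if (B <= 0.01 || B >= 1.99) return(1e10)
                -loglik_pl_exp(t, 2 - B / 2, exp(par[1]), t_min, t_max)
              },
              method = "Nelder-Mead",
              control = list(reltol = 1e-10, maxit = 1000))
  s_tau <- exp(os$par[1]); s_B <- os$par[2]; s_ll <- -os$value
  out <- data.frame(
    model = c("kinetic", "diffusion", "subdiffusion"),
    rate = c(k_rate, NA, NA),
    timescale = c(NA, d_tau, s_tau),
    B = c(NA, NA, s_B),
    loglik = c(k_ll, d_ll, s_ll),
    AIC = c(2 * 1 - 2 * k_ll, 2 * 1 - 2 * d_ll, 2 * 2 - 2 * s_ll),
    stringsAsFactors = FALSE)
  out <- out[order(out$AIC), ]
  out$delta_AIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  class(out) <- c("dwell_model_fits", "data.frame")
  out
}
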