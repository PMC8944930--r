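## Calibration chain: Kuhn length from the T0 (Rabl) plateau, Rabl exit rate
## from recombination-null plateaus, confinement radius, stage-wise linkage
## numbers with common-random-number bisection, and subdiffusion
## coefficients.

## Bisection on a (noisy but common-random-number) monotone map.
bisect_map <- function(f, target, lower, upper, tol, increasing = TRUE,
                       max_iter = 40L) {
  flo <- f(lower); fhi <- f(upper)
  if (!increasing) { tmp <- flo; flo <- fhi; fhi <- tmp }
  if (target < flo - 1e-12 || target > fhi + 1e-12)
    stop(sprintf("target %.4g outside achievable bracket [%.4g, %.4g]",
                 target, flo, fhi))
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    if (upper - lower < tol) break
    fm <- f(mid)
    up <- if (increasing) fm < target else fm > target
    if (up) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Fit the Kuhn length from the T0 (Rabl) MSCD plateau
#'
#' Inverts the monotone map Kuhn length -> confined Rabl plateau
#' ([plateau_confined()] with `"rabl"` tethering) by bisection, using a
#' common random seed for every candidate so the map is deterministic and
#' monotone during the search.
#'
#' @param t0_plateau Observed plateau at T0, um^2.
#' @param chrom A [chromosome_spec()] (the locus should be near the
#'   centromere for the Rabl model to dominate).
#' @param params A [polymer_params()]; its `kuhn_length_b` is ignored.
#' @param bracket Search bracket for b, nm.
#' @param tol Bisection tolerance, nm.
#' @param n_anchor,n_per Monte-Carlo settings per evaluation.
#' @param seed Common-random-number seed (drawn from the current stream when
#'   missing).
#' @return Fitted Kuhn length, nm.
#' @export
fit_kuhn_length <- function(t0_plateau, chrom, params, bracket = c(80, 600),
                            tol = 1, n_anchor = 50, n_per = 60, seed = NULL) {
  if (is.null(seed)) seed <- draw_seed()
  f <- function(b) {
    p <- params; p$kuhn_length_b <- b
    with_seed(seed, confined_locus_stats(chrom, p, "rabl",
                                         n_anchor, n_per)$plateau)
  }
  bisect_map(f, t0_plateau, bracket[1], bracket[2], tol, increasing = TRUE)
}

#' Fit the Rabl exit rate from per-stage MSCD plateaus
#'
#' Nonlinear least squares of the two-state relaxation
#' `MSCD_inf(t) = MSCD_T0 exp(-k t) + MSCD_inf (1 - exp(-k t))` over
#' `(k_rabl, MSCD_inf)`, with `MSCD_T0` fixed to the plateau observed at
#' t = 0.
#'
#' @param t_hours Stage times, hours (at least 3, including 0).
#' @param plateaus Observed MSCD plateaus, um^2.
#' @return An object of class `rabl_fit`: list with `k_rabl`, `mscd_T0`,
#'   `mscd_inf`, `residual` (RMS), `fitted`.
#' @export
fit_rabl_rate <- function(t_hours, plateaus) {
  stopifnot(length(t_hours) == length(plateaus), length(t_hours) >= 3)
  o <- order(t_hours)
  t_hours <- t_hours[o]; plateaus <- plateaus[o]
  if (t_hours[1] != 0) stop("a t = 0 stage is required to pin MSCD_T0")
  m0 <- plateaus[1]
  if (sd(plateaus) < 1e-10 * max(abs(plateaus), 1)) {
    warning("flat plateau series: k_rabl not identifiable, returning 0")
    fit <- list(k_rabl = 0, mscd_T0 = m0, mscd_inf = mean(plateaus),
                residual = 0, fitted = plateaus)
    class(fit) <- "rabl_fit"
    return(fit)
  }
  obj <- function(par) {
    k <- exp(par[1]); minf <- par[2]
    sum((rabl_decay(t_hours, m0, minf, k) - plateaus)^2)
  }
  best <- optim(c(log(0.5), plateaus[length(plateaus)]), obj,
                method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = 2000))
  k <- exp(best$par[1]); minf <- best$par[2]
  fit <- list(k_rabl = k, mscd_T0 = m0, mscd_inf = minf,
              residual = sqrt(best$value / length(plateaus)),
              fitted = rabl_decay(t_hours, m0, minf, k))
  class(fit) <- "rabl_fit"
  fit
}

#' @export
print.rabl_fit <- function(x, ...) {
  cat(sprintf("<rabl_fit> k_rabl=%.4g /h (mean detachment %.3g h), MSCD_T0=%.3g, MSCD_inf=%.3g um^2\n",
              x$k_rabl, 1 / x$k_rabl, x$mscd_T0, x$mscd_inf))
  invisible(x)
}

#' Fit the confinement radius from the post-Rabl plateau
#'
#' Inverts the monotone map sphere radius -> unlinked confined plateau
#' ([plateau_confined()] with `"telomeres_only"` tethering) by
#' common-random-number bisection.
#'
#' @param mscd_inf Observed plateau after complete centromere detachment,
#'   um^2.
#' @param chrom A [chromosome_spec()].
#' @param params A [polymer_params()]; its `sphere_radius_a` is ignored.
#' @param bracket Search bracket for a, um.
#' @param tol Bisection tolerance, um.
#' @inheritParams fit_kuhn_length
#' @return Fitted sphere radius, um.
#' @export
fit_confinement_radius <- function(mscd_inf, chrom, params,
                                   bracket = c(0.6, 4), tol = 0.01,
                                   n_anchor = 50, n_per = 60, seed = NULL) {
  if (is.null(seed)) seed <- draw_seed()
  f <- function(a) {
    p <- params; p$sphere_radius_a <- a
    with_seed(seed, confined_locus_stats(chrom, p, "telomeres_only",
                                         n_anchor, n_per)$plateau)
  }
  bisect_map(f, mscd_inf, bracket[1], bracket[2], tol, increasing = TRUE)
}

#' Fit the mean linkage number from a stage MSCD plateau
#'
#' Inverts the antitone map mu -> censored ensemble MSCD plateau by
#' bisection.  A single bank of cell realizations is drawn at the top of the
#' bracket and thinned (each linkage kept with probability `mu / mu_max`
#' against pre-drawn uniforms) for every candidate mu, so the map is
#' deterministic and monotone given the seed.  The plateau of each candidate
#' ensemble curve is extracted with [fit_powerlaw_plateau()], mirroring how
#' the observed plateau is measured.
#'
#' Two ways of computing the candidate ensembles are available.  `method =
#' "theory"` censors the exact per-cell theory curves at the floor (cheap;
#' appropriate when the target plateau is itself a theoretical quantity,
#' e.g. for the censoring-bias comparison).  `method = "simulate"` realises
#' each candidate ensemble as simulated movies and measures them exactly
#' like the data (time-averaged MSCD over resolved frames, per-cell value
#' censoring, cell-weighted average): the estimator biases induced by
#' detection masking and finite movies then cancel between the data and the
#' candidate ensembles, which matters because censoring flattens the
#' mu -> plateau map.  Use `"simulate"` when the target plateau was measured
#' from trajectory data.
#'
#' @param target_plateau Observed ensemble plateau, um^2.
#' @param chrom A [chromosome_spec()].
#' @param params A [polymer_params()] (with the stage's `D0`).
#' @param p_rabl Rabl probability at the stage (usually ~0 by linkage
#'   onset).
#' @param censor Exclude per-cell MSCD values below `params$mscd_floor`?
#' @param n_cells Size of the realization bank.
#' @param bracket Search bracket for mu.
#' @param tol Bisection tolerance on mu.
#' @param lag_times Lag grid on which ensemble curves are evaluated
#'   (defaults to the 50-frame, 30-s movie grid).
#' @param confined Optional precomputed confinement statistics: a list with
#'   elements `telomeres_only` and `rabl`, either plateau numbers
#'   (`method = "theory"`) or full [confined_locus_stats()] results
#'   (`method = "simulate"`, which needs `offset_msq`).
#' @param method `"theory"` or `"simulate"` (see Details).
#' @param seed Common-random-number seed.
#' @return Fitted mean linkage number (0, with a warning, when the target
#'   plateau is at or above the unlinked level).
#' @export
fit_linkage_number <- function(target_plateau, chrom, params, p_rabl = 0,
                               censor = TRUE, n_cells = 3000,
                               bracket = c(0, 12), tol = 0.02,
                               lag_times = seq(0, by = 30, length.out = 50),
                               confined = NULL,
                               method = c("theory", "simulate"),
                               seed = NULL) {
  method <- match.arg(method)
  if (is.null(seed)) seed <- draw_seed()
  if (method == "simulate") {
    need <- is.null(confined) || is.null(confined$telomeres_only$offset_msq)
    if (need)
      confined <- list(
        telomeres_only = confined_locus_stats(chrom, params, "telomeres_only",
                                              40, 60),
        rabl = confined_locus_stats(chrom, params, "rabl", 40, 60))
  } else {
    confined <- resolve_confined(chrom, params, p_rabl, confined)
  }
  mu_max <- bracket[2]
  n_kuhn <- bp_to_kuhn(chrom$length_bp, params)
  locus <- bp_to_kuhn(chrom$locus_bp, params)
  bank <- with_seed(seed, {
    counts <- rpois(n_cells, mu_max)
    list(counts = counts,
         pos = lapply(counts, function(k) runif(k, 0, n_kuhn)),
         thin = lapply(counts, function(k) runif(k)),
         rabl = runif(n_cells) < p_rabl)
  })
  noise_seed <- with_seed(seed + 1L, draw_seed())
  b_um <- params$kuhn_length_b / 1000
  conf_plat <- function(rabl) {
    x <- if (rabl) confined$rabl else confined$telomeres_only
    if (is.list(x)) x$plateau else as.numeric(x)
  }
  cell_plateaus <- function(mu) {
    keep_p <- mu / mu_max
    vapply(seq_len(n_cells), function(i) {
      pos <- bank$pos[[i]][bank$thin[[i]] < keep_p]
      topo <- classify_topology(pos, locus)
      tether <- switch(topo$topology,
                       unlinked = Inf,
                       linear = plateau_linear(topo$segments[["nL"]], b_um),
                       ring = plateau_ring(topo$segments[["n1"]],
                                           topo$segments[["n2"]], b_um))
      min(tether, conf_plat(bank$rabl[i]))
    }, numeric(1))
  }
  off_msq <- function(rabl) {
    x <- if (rabl) confined$rabl else confined$telomeres_only
    if (is.list(x)) x$offset_msq else 0
  }
  plateau_of <- function(mu) {
    keep_p <- mu / mu_max
    plats <- cell_plateaus(mu)
    if (method == "theory") {
      V <- mscd_theory_values(plats, params$D0, params$alpha, lag_times)
      avg <- vapply(seq_along(lag_times), function(j) {
        vals <- V[, j]
        if (censor && lag_times[j] > 0) vals <- vals[vals >= params$mscd_floor]
        if (length(vals)) mean(vals) else NA_real_
      }, numeric(1))
      return(fit_powerlaw_plateau(mscd_curve(lag_times, avg))$C)
    }
    ## simulate: same noise bank for every candidate (stream realigned)
    unlinked <- vapply(seq_len(n_cells), function(i)
      !any(bank$thin[[i]] < keep_p), TRUE)
    res_um <- params$resolution / 1000
    nf <- length(lag_times)
    nlag <- nf - 1L
    sums <- numeric(nlag); cnts <- numeric(nlag)
    with_seed(noise_seed, {
      for (i in seq_len(n_cells)) {
        dr <- gp_sample_3d(lag_times, plats[i], 6 * params$D0, params$alpha)
        osd <- if (unlinked[i]) sqrt(max(off_msq(bank$rabl[i]), 0) / 3) else 0
        dr <- dr + matrix(rnorm(3) * osd, nf, 3, byrow = TRUE)
        dr[sqrt(rowSums(dr^2)) < res_um, ] <- NA_real_
        s <- msq_increment_sums(dr, nlag)
        v <- ifelse(s$counts > 0, s$sums / pmax(s$counts, 1L), NA_real_)
        use <- s$counts > 0
        if (censor) use <- use & v >= params$mscd_floor
        sums[use] <- sums[use] + v[use]
        cnts[use] <- cnts[use] + 1
      }
    })
    avg <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
    fit_powerlaw_plateau(mscd_curve(lag_times[-1], avg))$C
  }
  if (target_plateau >= plateau_of(0)) {
    warning("target plateau at or above the unlinked level: mu = 0")
    return(0)
  }
  bisect_map(plateau_of, target_plateau, bracket[1], bracket[2], tol,
             increasing = FALSE)
}

#' Fit the subdiffusion coefficient from an ensemble MSCD curve
#'
#' Least-squares scaling of the theoretical crossover family in `D0` on the
#' pre-plateau regime of the curve (points below `frac * C`, with `C` from
#' [fit_powerlaw_plateau()] unless a plateau is supplied).
#'
#' @param curve An [mscd_curve()].
#' @param params A [polymer_params()] (supplies `alpha`; its `D0` is
#'   ignored).
#' @param plateau Optional plateau `C`, um^2.
#' @param frac Pre-plateau cutoff as a fraction of `C`.
#' @param form Crossover family (see [mscd_theory_curve()]); must match the
#'   family that produced the curve.
#' @return Fitted `D0`, um^2/s^(alpha/2).
#' @export
fit_subdiffusion_coefficient <- function(curve, params, plateau = NULL,
                                         frac = 0.8,
                                         form = c("modesum", "exponential")) {
  stopifnot(inherits(curve, "mscd_curve"))
  form <- match.arg(form)
  C <- if (is.null(plateau)) fit_powerlaw_plateau(curve)$C else plateau
  keep <- curve$lag > 0 & !is.na(curve$value) & curve$value > 0 &
    curve$value < frac * C
  if (!any(keep)) stop("no pre-plateau points below ", frac, " * C")
  t <- curve$lag[keep]; v <- curve$value[keep]
  obj <- function(ld0) {
    d0 <- exp(ld0)
    sum((mscd_theory_values(C, d0, params$alpha, t, form) - v)^2)
  }
  exp(optimize(obj, c(log(1e-6), log(10)))$minimum)
}

#' Maximum relative deviation between biased and unbiased linkage estimates
#'
#' `max over stages of |mu_b - mu_u| / mu_b`; stages with both estimates 0
#' contribute 0; a zero biased estimate paired with a nonzero unbiased one
#' is flagged infinite.
#'
#' @param mu_biased,mu_unbiased Equal-length nonnegative vectors.
#' @return Maximum relative deviation (fraction).
#' @export
bias_comparison <- function(mu_biased, mu_unbiased) {
  stopifnot(length(mu_biased) == length(mu_unbiased))
  if (any(mu_biased < 0) || any(mu_unbiased < 0))
    stop("linkage estimates must be nonnegative")
  dev <- ifelse(mu_biased == 0,
                ifelse(mu_unbiased == 0, 0, Inf),
                abs(mu_biased - mu_unbiased) / mu_biased)
  if (any(is.infinite(dev)))
    warning("zero biased estimate paired with nonzero unbiased estimate")
  max(dev)
}
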