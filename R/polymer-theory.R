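## Analytical MSCD theory for tagged loci on linked, confined, viscoelastic
## Rouse chains: tether plateaus, confinement plateaus by Monte Carlo, smooth
## crossover curves, and censoring-aware ensemble averages.

#' MSCD curve container
#'
#' A lag-time -> MSCD table with per-lag sample counts.
#'
#' @param lag_times Lag times, s, strictly increasing and nonnegative.
#' @param values MSCD values, um^2 (NA allowed where no samples exist).
#' @param n_samples Optional per-lag sample counts.
#' @return An object of class `mscd_curve`.
#' @export
mscd_curve <- function(lag_times, values, n_samples = NULL) {
  stopifnot(length(lag_times) == length(values))
  if (any(diff(lag_times) <= 0)) stop("lag_times must be strictly increasing")
  if (any(lag_times < 0)) stop("lag_times must be nonnegative")
  if (any(values < 0, na.rm = TRUE)) stop("MSCD values must be nonnegative")
  if (length(lag_times) && lag_times[1] == 0 && !is.na(values[1]) &&
      values[1] != 0)
    stop("MSCD at lag 0 must be 0")
  if (is.null(n_samples)) n_samples <- rep(NA_integer_, length(values))
  structure(list(lag = as.numeric(lag_times), value = as.numeric(values),
                 n = n_samples),
            class = "mscd_curve")
}

#' @export
print.mscd_curve <- function(x, ...) {
  cat(sprintf("<mscd_curve> %d lags, %g..%g s, max MSCD %.4g um^2\n",
              length(x$lag), min(x$lag), max(x$lag), max(x$value, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.mscd_curve <- function(x, ...) {
  data.frame(lag_s = x$lag, mscd_um2 = x$value, n = x$n)
}

#' @export
plot.mscd_curve <- function(x, ..., log = "xy") {
  keep <- x$lag > 0 & !is.na(x$value) & x$value > 0
  graphics::plot(x$lag[keep], x$value[keep], log = log, xlab = "lag (s)",
                 ylab = expression(MSCD ~ (mu * m^2)), type = "b", ...)
}

#' Unconfined MSCD plateau of a linear tether
#'
#' Long-time MSCD plateau of two homologous loci joined by an ideal-chain
#' tether of `nL` Kuhn segments: twice the mean squared end-to-end distance
#' of the tether, `2 * b^2 * nL`.
#'
#' @param nL Tether length, Kuhn segments (nonnegative).
#' @param b Kuhn length, um.
#' @return Plateau MSCD, um^2.
#' @examples
#' plateau_linear(12, 0.25)
#' @export
plateau_linear <- function(nL, b) {
  if (any(nL < 0)) stop("nL must be nonnegative")
  2 * b^2 * nL
}

#' Unconfined MSCD plateau of a ring tether
#'
#' Loci isolated inside an effective ring with arms of `n1` and `n2` Kuhn
#' segments.  The two arms act as parallel Gaussian tethers, so the plateau
#' composes harmonically: `2 * b^2 * n1 * n2 / (n1 + n2)`.
#'
#' @param n1,n2 Ring arm lengths, Kuhn segments (nonnegative).
#' @param b Kuhn length, um.
#' @return Plateau MSCD, um^2 (0 when both arms are 0, by continuity).
#' @examples
#' plateau_ring(12, 6, 0.25)
#' @export
plateau_ring <- function(n1, n2, b) {
  if (any(n1 < 0) || any(n2 < 0)) stop("arm lengths must be nonnegative")
  s <- n1 + n2
  out <- ifelse(s == 0, 0, 2 * b^2 * n1 * n2 / ifelse(s == 0, 1, s))
  out
}

## Uniform point on the surface of a sphere of radius a.
runif_sphere <- function(a) {
  v <- rnorm(3)
  a * v / sqrt(sum(v^2))
}

#' Equilibrium locus statistics of confined, surface-anchored chains
#'
#' Monte-Carlo samples equilibrium configurations of the two homologous
#' chromosomes as Gaussian chains confined to a sphere of radius `a` with
#' their telomeres pinned at independent uniform points on the surface (and,
#' under `"rabl"` tethering, both centromeres co-anchored at one shared
#' surface point).  Chains are rejection-sampled as Brownian bridges between
#' pins, discarding any configuration with a bead outside the sphere.
#'
#' The MSCD plateau is the quenched (fixed-anchor) value
#' `2 * E_anchors[ Var(dr | anchors) ]`: within one movie the anchor points
#' are static, so the time-averaged MSCD saturates at twice the conditional
#' variance of the separation vector, which is then averaged over cells.
#'
#' @param chrom A [chromosome_spec()].
#' @param params A [polymer_params()].
#' @param tethering `"telomeres_only"` or `"rabl"`.
#' @param n_anchor Number of anchor placements (cells) sampled.
#' @param n_per Accepted chain configurations per anchor placement and chain.
#' @param max_attempts Attempt cap per anchor placement and chain.
#' @return A list: `plateau` (um^2), `sem` (Monte-Carlo standard error),
#'   `offset_msq` (mean squared anchor-induced separation offset
#'   `E|E[dr|anchors]|^2`, um^2, bias-corrected), `acceptance` (overall
#'   rejection-sampling acceptance rate), `n_anchor_used`.
#' @export
confined_locus_stats <- function(chrom, params,
                                 tethering = c("telomeres_only", "rabl"),
                                 n_anchor = 100, n_per = 100,
                                 max_attempts = 200000) {
  tethering <- match.arg(tethering)
  stopifnot(inherits(chrom, "chromosome_spec"), inherits(params, "polymer_params"))
  a <- params$sphere_radius_a
  if (a <= 0) stop("sphere_radius_a must be positive")
  b_um <- params$kuhn_length_b / 1000
  n_kuhn <- bp_to_kuhn(chrom$length_bp, params)
  s_loc <- bp_to_kuhn(chrom$locus_bp, params)
  s_cen <- bp_to_kuhn(chrom$centromere_bp, params)

  if (tethering == "rabl" && chrom$locus_bp == chrom$centromere_bp)
    return(list(plateau = 0, sem = 0, offset_msq = 0, acceptance = 1,
                n_anchor_used = n_anchor))

  pts <- c(0, n_kuhn, s_loc, if (tethering == "rabl") s_cen)
  grid <- sort(unique(c(seq(0, n_kuhn, by = 1), pts)))
  iloc <- which(abs(grid - s_loc) < 1e-12)[1] - 1L
  pin_coords <- sort(unique(c(0, n_kuhn, if (tethering == "rabl") s_cen)))
  pins <- vapply(pin_coords,
                 function(s) which(abs(grid - s) < 1e-12)[1], 1L) - 1L
  icen <- if (tethering == "rabl") match(s_cen, pin_coords) else NA_integer_
  sig2 <- b_um^2 / 3

  plats <- offs <- numeric(n_anchor)
  used <- 0L; tot_att <- 0; tot_acc <- 0; hard_fail <- 0L
  for (k in seq_len(n_anchor)) {
    if (hard_fail >= 3L && used == 0L) break  # hopeless: go harmonic
    cen_point <- if (tethering == "rabl") runif_sphere(a) else NULL
    draw_pins <- function() {
      pp <- vapply(seq_along(pin_coords), function(j) {
        if (!is.na(icen) && j == icen) cen_point else runif_sphere(a)
      }, numeric(3))
      pp
    }
    r1 <- sample_confined_chain(grid, pins, draw_pins(), sig2, a, iloc,
                                as.integer(n_per), as.integer(max_attempts))
    r2 <- sample_confined_chain(grid, pins, draw_pins(), sig2, a, iloc,
                                as.integer(n_per), as.integer(max_attempts))
    tot_att <- tot_att + r1$attempts + r2$attempts
    tot_acc <- tot_acc + r1$n_acc + r2$n_acc
    if (r1$n_acc < 2 || r2$n_acc < 2) { hard_fail <- hard_fail + 1L; next }
    l1 <- r1$loc[seq_len(r1$n_acc), , drop = FALSE]
    l2 <- r2$loc[seq_len(r2$n_acc), , drop = FALSE]
    v1 <- sum(apply(l1, 2, var)); v2 <- sum(apply(l2, 2, var))
    m <- colMeans(l1) - colMeans(l2)
    used <- used + 1L
    plats[used] <- 2 * (v1 + v2)
    ## subtract the sampling variance of the two means (unbiased |offset|^2)
    offs[used] <- sum(m^2) - v1 / r1$n_acc - v2 / r2$n_acc
  }
  if (used < 2) {
    warning("rejection sampling acceptance too low (",
            signif(tot_acc / max(tot_att, 1), 3),
            "); using the harmonic-confinement approximation")
    return(confined_stats_harmonic(grid, pins, iloc + 1L, icen, sig2, a))
  }
  if (used < n_anchor / 2)
    warning("more than half of the anchor placements were under-sampled")
  plats <- plats[seq_len(used)]; offs <- offs[seq_len(used)]
  list(plateau = mean(plats), sem = sd(plats) / sqrt(used),
       offset_msq = max(mean(offs), 0), acceptance = tot_acc / tot_att,
       n_anchor_used = used, method = "rejection")
}

## Deterministic strong-confinement fallback: replace the hard sphere by a
## per-monomer harmonic well calibrated so a free monomer's radial variance
## matches the uniform-sphere value 3 a^2 / 5.  The chain-plus-well system
## is jointly Gaussian, so the locus variance and the anchor weights follow
## from one tridiagonal solve per chain; anchors enter only the mean.
## Over-confines long chains relative to the hard wall, but is only used
## where rejection sampling cannot reach (very small spheres), keeping
## radius/Kuhn-length bisections bracketed.
confined_stats_harmonic <- function(grid, pins, iloc, icen, sig2, a) {
  nb <- length(grid)
  free <- setdiff(seq_len(nb), pins + 1L)
  if (!(iloc %in% free))  # locus pinned: separation frozen at the anchors
    return(list(plateau = 0, sem = 0, offset_msq = 0, acceptance = NA,
                n_anchor_used = 0L, method = "harmonic"))
  ds <- diff(grid)
  kappa <- 5 / a^2
  Q <- matrix(0, nb, nb)
  for (i in seq_len(nb - 1)) {
    ks <- 1 / (sig2 * ds[i])
    Q[i, i] <- Q[i, i] + ks
    Q[i + 1, i + 1] <- Q[i + 1, i + 1] + ks
    Q[i, i + 1] <- Q[i, i + 1] - ks
    Q[i + 1, i] <- Q[i + 1, i] - ks
  }
  w <- c(ds[1] / 2, (ds[-1] + ds[-length(ds)]) / 2, ds[length(ds)] / 2)
  diag(Q) <- diag(Q) + kappa * w
  Qf <- Q[free, free, drop = FALSE]
  B <- -Q[free, pins + 1L, drop = FALSE]  # coupling to the pinned beads
  S <- solve(Qf)
  il <- match(iloc, free)
  v <- S[il, il]                       # per-axis locus variance (one chain)
  wts <- (S %*% B)[il, ]               # locus mean weights per pin
  ## pins are independent uniform surface points between the two homologs,
  ## except a shared centromere pin under Rabl tethering
  indep <- if (is.na(icen)) rep(TRUE, length(wts))
           else seq_along(wts) != icen
  offset_msq <- 2 * a^2 * sum(wts[indep]^2)
  list(plateau = 12 * v, sem = 0, offset_msq = offset_msq, acceptance = NA,
       n_anchor_used = 0L, method = "harmonic")
}

#' Confinement-dominated MSCD plateau
#'
#' Long-time MSCD plateau of the two unlinked homologous loci under spherical
#' confinement, computed by [confined_locus_stats()].
#'
#' @inheritParams confined_locus_stats
#' @return Plateau MSCD in um^2, with attributes `sem`, `offset_msq` and
#'   `acceptance`.
#' @examples
#' \donttest{
#' set.seed(1)
#' plateau_confined(lookup_chromosome("URA3"), polymer_params(),
#'                  n_anchor = 20, n_per = 50)
#' }
#' @export
plateau_confined <- function(chrom, params,
                             tethering = c("telomeres_only", "rabl"),
                             n_anchor = 100, n_per = 100,
                             max_attempts = 200000) {
  st <- confined_locus_stats(chrom, params, tethering, n_anchor, n_per,
                             max_attempts)
  structure(st$plateau, sem = st$sem, offset_msq = st$offset_msq,
            acceptance = st$acceptance)
}

#' Theoretical MSCD crossover curve
#'
#' Crossover between the early-time viscoelastic Rouse power law
#' `A * t^(alpha/2)` with `A = 6 * D0` and the long-time plateau `C`.  The
#' default `"modesum"` form superposes the Rouse relaxation modes of the
#' effective tether (amplitudes `1/p^2` over odd modes, stretched-exponential
#' relaxation `exp(-(t/tau_p)^alpha)` with `tau_p = tau_1 * p^(-2/alpha)`),
#' which reproduces the `t^(alpha/2)` regime as an emergent superposition and
#' keeps the local log-slope near `alpha/2` until close to the crossover.
#' The `"exponential"` form is the single-exponential shortcut
#' `C * (1 - exp(-A * t^(alpha/2) / C))`, whose gradual bend depresses
#' apparent power-law slopes well before the plateau.
#'
#' @param plateau Plateau MSCD `C`, um^2 (0 gives the identically-zero
#'   curve of pinned loci).
#' @param params A [polymer_params()] (uses `D0` and `alpha`).
#' @param lag_times Lag times, s.
#' @param form Crossover family, `"modesum"` (default) or `"exponential"`.
#' @return An [mscd_curve()] with attribute `plateau`.
#' @examples
#' mscd_theory_curve(1.74, polymer_params(), c(0, 30, 60, 300, 1500))
#' @export
mscd_theory_curve <- function(plateau, params, lag_times,
                              form = c("modesum", "exponential")) {
  if (plateau < 0) stop("plateau must be nonnegative")
  v <- mscd_theory_values(plateau, params$D0, params$alpha, lag_times,
                          match.arg(form))
  structure(mscd_curve(lag_times, v), plateau = plateau)
}

## Odd Rouse modes used by the "modesum" crossover and the sampler kernel.
cross_modes <- local({
  p <- seq(1, 199, by = 2)
  w <- 1 / p^2
  list(p2 = p^2, w = w / sum(w))
})
## 4/pi^(3/2): continuum small-u prefactor of the mode sum, used to
## calibrate tau_1 so the early asymptote is exactly 6 * D0 * t^(alpha/2).
CROSS_CG <- 4 / pi^1.5

## Saturation profile G(u) = 1 - sum_p w_p exp(-u p^2), u = (t/tau_1)^alpha.
cross_G <- function(u) {
  out <- numeric(length(u))
  for (k in seq_along(cross_modes$w))
    out <- out + cross_modes$w[k] * exp(-u * cross_modes$p2[k])
  pmax(1 - out, 0)  # clamp the ~1e-16 float residue at u = 0
}

## Vectorised curve evaluation shared by the theory and ensemble code.
## `plateau` may be a vector (cells); returns length(plateau) x length(t).
mscd_theory_values <- function(plateau, D0, alpha, t,
                               form = c("modesum", "exponential")) {
  form <- match.arg(form)
  A <- 6 * D0
  P <- matrix(plateau, nrow = length(plateau), ncol = length(t))
  if (form == "exponential") {
    g <- A * outer(rep(1, length(plateau)), t^(alpha / 2))
    out <- ifelse(P > 0, P * (1 - exp(-g / pmax(P, .Machine$double.xmin))), 0)
  } else {
    ## u_ij = t_j^alpha * (A / (CG * P_i))^2, from tau_1 = (CG*P/A)^(2/alpha)
    u <- outer((A / (CROSS_CG * pmax(plateau, .Machine$double.xmin)))^2,
               t^alpha)
    out <- ifelse(P > 0, P * matrix(cross_G(u), nrow = nrow(P)), 0)
  }
  if (length(plateau) == 1L) out <- drop(out)
  out
}

#' Per-cell MSCD curve under the minimum-plateau rule
#'
#' Combines the cell's tether plateau (from its linkage topology) with the
#' nuclear-confinement plateau by taking the smaller of the two: nuclear
#' confinement dictates the plateau when the nearest linkage is distant,
#' while a close linkage overrides confinement.
#'
#' @param cell A [sample_cell()] realization.
#' @param chrom A [chromosome_spec()].
#' @param params A [polymer_params()].
#' @param lag_times Lag times, s.
#' @param confined_plateau Optional precomputed confinement plateau (um^2)
#'   for the cell's tethering state; computed (at modest Monte-Carlo
#'   settings) when missing.
#' @return An [mscd_curve()] with attribute `plateau`.
#' @export
cell_mscd_curve <- function(cell, chrom, params, lag_times,
                            confined_plateau = NULL) {
  stopifnot(inherits(cell, "cell_realization"))
  if (is.null(confined_plateau)) {
    confined_plateau <- plateau_confined(
      chrom, params, if (cell$rabl) "rabl" else "telomeres_only",
      n_anchor = 40, n_per = 60)
  }
  P <- min(cell_tether_plateau(cell, params), as.numeric(confined_plateau))
  mscd_theory_curve(P, params, lag_times)
}

## Tether plateau of one cell from its topology (Inf when unlinked).
cell_tether_plateau <- function(cell, params) {
  b_um <- params$kuhn_length_b / 1000
  switch(cell$topology,
         unlinked = Inf,
         linear = plateau_linear(cell$segments[["nL"]], b_um),
         ring = plateau_ring(cell$segments[["n1"]], cell$segments[["n2"]], b_um))
}

#' Ensemble-averaged theoretical MSCD
#'
#' Averages [cell_mscd_curve()] over `n_cells` sampled cell realizations at
#' linkage mean `mu` and Rabl probability `p_rabl`.  With `censor = TRUE`,
#' per-cell MSCD values below `params$mscd_floor` are excluded from the
#' average at each lag, emulating the two-focus detection limit.
#'
#' @inheritParams cell_mscd_curve
#' @param mu Mean linkage number.
#' @param p_rabl Rabl probability.
#' @param n_cells Number of cell realizations.
#' @param censor Exclude sub-resolution MSCD values?
#' @param confined Optional list with elements `telomeres_only` and `rabl`,
#'   each a [confined_locus_stats()] result (or plateau), to avoid
#'   recomputation.
#' @return An [mscd_curve()]; attribute `plateaus` carries the per-cell
#'   plateau values.
#' @export
ensemble_mscd <- function(chrom, params, mu, p_rabl, n_cells, lag_times,
                          censor = FALSE, confined = NULL) {
  stopifnot(n_cells >= 1)
  plats <- sample_cell_plateaus(chrom, params, mu, p_rabl, n_cells, confined)
  V <- mscd_theory_values(plats, params$D0, params$alpha, lag_times)
  if (n_cells == 1L) V <- matrix(V, nrow = 1L)
  avg <- numeric(length(lag_times)); n <- integer(length(lag_times))
  for (j in seq_along(lag_times)) {
    vals <- V[, j]
    if (censor && lag_times[j] > 0) vals <- vals[vals >= params$mscd_floor]
    n[j] <- length(vals)
    avg[j] <- if (length(vals)) mean(vals) else NA_real_
  }
  structure(mscd_curve(lag_times, avg, n), plateaus = plats)
}

## Sample n_cells per-cell plateaus (min rule), reusing confinement stats.
sample_cell_plateaus <- function(chrom, params, mu, p_rabl, n_cells,
                                 confined = NULL) {
  confined <- resolve_confined(chrom, params, p_rabl, confined)
  vapply(seq_len(n_cells), function(i) {
    cell <- sample_cell(chrom, params, mu, p_rabl)
    pc <- if (cell$rabl) confined$rabl else confined$telomeres_only
    min(cell_tether_plateau(cell, params), pc)
  }, numeric(1))
}

## Ensure both confinement plateaus needed for a Rabl mixture are available.
## Accepts NULL, a list of confined_locus_stats results, or a list of plain
## plateau numbers; returns list(telomeres_only=, rabl=) of numbers.
resolve_confined <- function(chrom, params, p_rabl, confined,
                             n_anchor = 40, n_per = 60) {
  get_plat <- function(x) if (is.list(x)) x$plateau else as.numeric(x)
  out <- list(telomeres_only = NULL, rabl = NULL)
  if (!is.null(confined)) {
    if (!is.null(confined$telomeres_only))
      out$telomeres_only <- get_plat(confined$telomeres_only)
    if (!is.null(confined$rabl)) out$rabl <- get_plat(confined$rabl)
  }
  if (is.null(out$telomeres_only) && (is.null(p_rabl) || any(p_rabl < 1)))
    out$telomeres_only <- confined_locus_stats(chrom, params, "telomeres_only",
                                               n_anchor, n_per)$plateau
  if (is.null(out$rabl) && (is.null(p_rabl) || any(p_rabl > 0)))
    out$rabl <- confined_locus_stats(chrom, params, "rabl",
                                     n_anchor, n_per)$plateau
  out
}

#' Two-state relaxation of the MSCD plateau out of the Rabl configuration
#'
#' `MSCD_inf(t) = MSCD_T0 * exp(-k_rabl t) + MSCD_inf * (1 - exp(-k_rabl t))`.
#'
#' @param t_hours Time in sporulation media, hours.
#' @param mscd_T0 Plateau at t = 0 (Rabl-dominated), um^2.
#' @param mscd_inf Plateau after complete centromere detachment, um^2.
#' @param k_rabl Detachment rate, per hour (nonnegative).
#' @return Plateau MSCD at `t_hours`, um^2.
#' @examples
#' rabl_decay(1.6529, 1.0, 1.74, 0.605)
#' @export
rabl_decay <- function(t_hours, mscd_T0, mscd_inf, k_rabl) {
  if (any(k_rabl < 0)) stop("k_rabl must be nonnegative")
  e <- exp(-k_rabl * t_hours)
  mscd_T0 * e + mscd_inf * (1 - e)
}
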