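## Trajectory statistics: colocalization states and classes, dwell times,
## fraction of time colocalized, time-averaged and ensemble MSCD/MSD
## estimators, and the min(A t^B, C) power-law/plateau fit.

#' Split a dataset into per-cell trajectories
#'
#' @param dataset A dataset data.frame (see [read_dataset()]).
#' @return A named list of per-cell data.frames, frame-ordered.
#' @export
split_trajectories <- function(dataset) {
  out <- split(dataset, dataset$cell_id)
  lapply(out, function(d) d[order(d$t_s), , drop = FALSE])
}

#' Colocalization state series of a trajectory
#'
#' A frame is colocalized when the two foci are not resolved (merged point
#' spread functions) or when the measured separation is below the resolution
#' limit (strict `<`).
#'
#' @param traj One trajectory data.frame.
#' @param params A [polymer_params()].
#' @return Logical vector, `TRUE` = colocalized.
#' @export
states_from_separation <- function(traj, params) {
  res_um <- params$resolution / 1000
  sep <- sqrt(traj$dx_um^2 + traj$dy_um^2 + traj$dz_um^2)
  !traj$resolved | (!is.na(sep) & sep < res_um)
}

#' Classify a trajectory by its state series
#'
#' @param states Logical colocalization series (at least one frame).
#' @return `"colocalized"` (always together), `"separated"` (never), or
#'   `"mixed"` (at least one transition observed).
#' @export
classify_trajectory <- function(states) {
  stopifnot(length(states) >= 1)
  if (all(states)) "colocalized"
  else if (!any(states)) "separated"
  else "mixed"
}

#' Dwell times from a state series
#'
#' Run-length encodes the colocalization series into dwell durations
#' (`run length * dt`).  The first and last runs of a movie are censored
#' (their true duration extends beyond the observation window) and are
#' excluded from distribution fitting by default.
#'
#' @param states Logical colocalization series.
#' @param dt Frame interval, s.
#' @return A data.frame of class `dwell_sample` with columns `duration`
#'   (s), `state` (`"colocalized"`/`"separated"`) and `censored`.
#' @export
dwell_times <- function(states, dt) {
  stopifnot(dt > 0, length(states) >= 1)
  r <- rle(as.logical(states))
  n <- length(r$lengths)
  cens <- rep(FALSE, n)
  cens[c(1L, n)] <- TRUE
  structure(data.frame(duration = r$lengths * dt,
                       state = ifelse(r$values, "colocalized", "separated"),
                       censored = cens, stringsAsFactors = FALSE),
            class = c("dwell_sample", "data.frame"))
}

#' Pool dwell times over a dataset
#'
#' @param dataset A dataset data.frame.
#' @param params A [polymer_params()].
#' @param mixed_only Restrict to cells classified `"mixed"` (the transition
#'   analysis is defined on cells observed to switch states)?
#' @return A `dwell_sample` data.frame with an extra `cell_id` column.
#' @export
dwell_times_dataset <- function(dataset, params, mixed_only = TRUE) {
  trajs <- split_trajectories(dataset)
  dt <- stats_dt(dataset)
  out <- lapply(names(trajs), function(id) {
    st <- states_from_separation(trajs[[id]], params)
    if (mixed_only && classify_trajectory(st) != "mixed") return(NULL)
    cbind(cell_id = id, dwell_times(st, dt))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell_id = character(), duration = numeric(),
                      state = character(), censored = logical())
  class(res) <- c("dwell_sample", "data.frame")
  res
}

stats_dt <- function(dataset) {
  ts <- dataset$t_s[dataset$cell_id == dataset$cell_id[1]]
  d <- diff(sort(ts))
  d[1]
}

#' Fraction of time colocalized, by stage
#'
#' Per-trajectory colocalized fractions are averaged within each stage; the
#' error is the SEM with the sample count set to the number of trajectories.
#'
#' @param dataset A dataset data.frame.
#' @param params A [polymer_params()].
#' @return A data.frame with `stage`, `fraction`, `sem`, `n_cells`.
#' @export
fraction_time_colocalized <- function(dataset, params) {
  if (nrow(dataset) == 0) stop("empty dataset")
  trajs <- split_trajectories(dataset)
  frac <- vapply(trajs, function(tr)
    mean(states_from_separation(tr, params)), numeric(1))
  stage <- vapply(trajs, function(tr) as.character(tr$stage[1]), character(1))
  stages <- unique(dataset$stage)
  out <- lapply(stages, function(s) {
    f <- frac[stage == s]
    if (length(f) == 0) stop("empty stage group: ", s)
    sem <- if (length(f) > 1) sd(f) / sqrt(length(f)) else {
      warning("single trajectory in stage ", s, ": SEM set to 0")
      0
    }
    data.frame(stage = s, fraction = mean(f), sem = sem,
               n_cells = length(f), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of short colocalized dwells
#'
#' Probability that an (uncensored, by default) colocalized dwell lasts no
#' longer than `cutoff` -- i.e. a single frame at 30-s sampling.
#'
#' @param dwells A `dwell_sample` data.frame.
#' @param cutoff Duration cutoff, s.
#' @param include_censored Also count censored dwells?
#' @return A probability, or `NA` (with a warning) when no qualifying dwells
#'   exist.
#' @export
fraction_short_dwell <- function(dwells, cutoff = 30, include_censored = FALSE) {
  d <- dwells[dwells$state == "colocalized", , drop = FALSE]
  if (!include_censored) d <- d[!d$censored, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no qualifying colocalized dwells; returning NA")
    return(NA_real_)
  }
  mean(d$duration <= cutoff)
}

## Separation matrix (frames x 3) with NA rows on unresolved frames.
sep_matrix <- function(traj) {
  m <- cbind(traj$dx_um, traj$dy_um, traj$dz_um)
  m[!traj$resolved, ] <- NA_real_
  m
}

## Core pair-averaged mean-square increment estimator on a regular frame
## grid.  X: frames x 3 matrix with NA rows for missing observations.
## Returns per-lag sums and counts over all ordered frame pairs.
msq_increment_sums <- function(X, nlag) {
  nf <- nrow(X)
  ok <- complete.cases(X)
  sums <- numeric(nlag); cnts <- integer(nlag)
  for (k in seq_len(nlag)) {
    i <- seq_len(nf - k)
    use <- ok[i] & ok[i + k]
    if (any(use)) {
      d <- X[i + k, , drop = FALSE][use, , drop = FALSE] -
        X[i, , drop = FALSE][use, , drop = FALSE]
      sums[k] <- sum(d * d)
      cnts[k] <- sum(use)
    }
  }
  list(sums = sums, counts = cnts)
}

#' Time-averaged MSCD of one trajectory
#'
#' For each lag `t`, averages the squared separation increment over all
#' ordered frame pairs `(tau, tau + t)` in the movie (overlapping windows
#' included).  Frames where the foci could not be resolved are omitted: a
#' pair contributes only when both frames are resolved.
#'
#' @param traj One trajectory data.frame (regular frame grid).
#' @return An [mscd_curve()] (lag 0 included with value 0); lags with no
#'   valid pair carry `NA` and count 0.  Fewer than 2 resolved frames give
#'   an empty curve with a warning.
#' @export
mscd_time_avg <- function(traj) {
  X <- sep_matrix(traj)
  dtv <- diff(traj$t_s)
  if (length(unique(round(dtv, 9))) > 1)
    stop("mscd_time_avg requires a regular frame grid")
  if (sum(complete.cases(X)) < 2) {
    warning("fewer than 2 resolved frames: empty MSCD curve")
    return(mscd_curve(0, 0, 0L))
  }
  dt <- dtv[1]
  nlag <- nrow(X) - 1L
  s <- msq_increment_sums(X, nlag)
  vals <- ifelse(s$counts > 0, s$sums / pmax(s$counts, 1L), NA_real_)
  mscd_curve(c(0, dt * seq_len(nlag)), c(0, vals),
             c(sum(complete.cases(X)), s$counts))
}

#' Ensemble-averaged MSCD of a dataset
#'
#' With `weighting = "pair"` (the default), pools squared separation
#' increments over all cells and all frame pairs; each valid pair is
#' weighted equally (the `j, tau` average), per stage.  With `weighting =
#' "cell"`, each cell's time-averaged MSCD contributes one value per lag and
#' cells are weighted equally.  `censor_floor` additionally drops per-cell
#' MSCD values below the detection floor (um^2) before averaging, mirroring
#' the exclusion of sub-resolution MSCD values from experimental analyses.
#'
#' @param dataset A dataset data.frame.
#' @param by_stage Return one curve per stage (`TRUE`) or pool all cells?
#' @param weighting `"pair"` or `"cell"`.
#' @param censor_floor Optional censoring threshold, um^2.
#' @return An [mscd_curve()] (single stage or `by_stage = FALSE`) or a named
#'   list of curves.
#' @export
mscd_ensemble <- function(dataset, by_stage = TRUE,
                          weighting = c("pair", "cell"),
                          censor_floor = NULL) {
  weighting <- match.arg(weighting)
  if (nrow(dataset) == 0) stop("empty dataset")
  groups <- if (by_stage) split(dataset, dataset$stage) else list(all = dataset)
  curves <- lapply(groups, function(d) {
    trajs <- split_trajectories(d)
    dt <- stats_dt(d)
    nlag <- max(vapply(trajs, nrow, 1L)) - 1L
    sums <- numeric(nlag); cnts <- numeric(nlag); n0 <- 0L
    for (tr in trajs) {
      X <- sep_matrix(tr)
      s <- msq_increment_sums(X, min(nlag, nrow(X) - 1L))
      k <- seq_along(s$sums)
      v <- ifelse(s$counts > 0, s$sums / pmax(s$counts, 1L), NA_real_)
      use <- s$counts > 0
      if (!is.null(censor_floor)) use <- use & v >= censor_floor
      if (weighting == "pair") {
        sums[k[use]] <- sums[k[use]] + s$sums[use]
        cnts[k[use]] <- cnts[k[use]] + s$counts[use]
      } else {
        sums[k[use]] <- sums[k[use]] + v[use]
        cnts[k[use]] <- cnts[k[use]] + 1L
      }
      n0 <- n0 + sum(complete.cases(X))
    }
    vals <- ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_)
    mscd_curve(c(0, dt * seq_len(nlag)), c(0, vals), c(n0, cnts))
  })
  if (length(curves) == 1L) curves[[1]] else curves
}

#' Time-averaged MSD of a single locus
#'
#' The pair-averaged estimator of [mscd_time_avg()] applied to one locus's
#' 3D position track (columns `x1_um`..`z1_um` or `x2_um`..`z2_um`; the
#' trajectory must have been simulated with `include_positions = TRUE`).
#'
#' @param traj One trajectory data.frame with position columns.
#' @param locus 1 or 2.
#' @return An [mscd_curve()]-shaped MSD curve.
#' @export
msd_time_avg <- function(traj, locus = 1) {
  cols <- paste0(c("x", "y", "z"), locus, "_um")
  if (!all(cols %in% names(traj)))
    stop("per-locus positions absent; simulate with include_positions = TRUE")
  X <- as.matrix(traj[, cols])
  dt <- diff(traj$t_s)[1]
  nlag <- nrow(X) - 1L
  s <- msq_increment_sums(X, nlag)
  vals <- ifelse(s$counts > 0, s$sums / pmax(s$counts, 1L), NA_real_)
  mscd_curve(c(0, dt * seq_len(nlag)), c(0, vals),
             c(sum(complete.cases(X)), s$counts))
}

#' Fit a single-cell MSCD with min(A t^B, C)
#'
#' Least squares in log-log space over breakpoint candidates: for each
#' candidate crossover index the points before it are fit by a power law
#' `A t^B` (linear regression of log value on log lag) and the points from
#' it onward by a constant plateau `C` (their geometric mean); the
#' breakpoint minimising the total squared log-residual wins, ties broken
#' toward the earliest breakpoint (longest plateau).  A curve that never
#' flattens selects the end breakpoint (`C` = last level, flag
#' `"no_plateau"`); an all-equal curve returns the degenerate `B = 0` fit.
#'
#' @param curve An [mscd_curve()] (lag 0 and empty lags are dropped; at
#'   least 4 positive points required).
#' @return An object of class `powerlaw_fit`: list with `A`, `B`, `C`,
#'   `n_powerlaw_points`, `breakpoint_index`, `rss` and `flags`.
#' @export
fit_powerlaw_plateau <- function(curve) {
  stopifnot(inherits(curve, "mscd_curve"))
  keep <- curve$lag > 0 & !is.na(curve$value) & curve$value > 0
  t <- curve$lag[keep]; v <- curve$value[keep]
  if (length(t) < 4) stop("need at least 4 positive points to fit")
  lt <- log(t); lv <- log(v)
  if (diff(range(lv)) < 1e-12) {
    fit <- list(A = mean(v), B = 0, C = mean(v), n_powerlaw_points = 0L,
                breakpoint_index = 1L, rss = 0, flags = "degenerate")
    class(fit) <- "powerlaw_fit"
    return(fit)
  }
  m <- length(t)
  best <- NULL
  ## breakpoint j = first plateau point (a plateau needs at least 2 points);
  ## j = m + 1 means no plateau within the window
  for (j in c(3:(m - 1L), m + 1L)) {
    ipl <- seq_len(j - 1L)
    co <- coef(lm.fit(cbind(1, lt[ipl]), lv[ipl]))
    rss_pow <- sum((lv[ipl] - co[1] - co[2] * lt[ipl])^2)
    if (j <= m) {
      lC <- mean(lv[j:m])
      rss_pla <- sum((lv[j:m] - lC)^2)
    } else {
      lC <- lv[m]
      rss_pla <- 0
    }
    rss <- rss_pow + rss_pla
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(j = j, logA = co[1], B = co[2], logC = lC, rss = rss)
    }
  }
  flags <- character(0)
  if (best$j == m + 1L) flags <- c(flags, "no_plateau")
  B <- unname(best$B); A <- exp(unname(best$logA))
  if (B < 0) {
    flags <- c(flags, "nonincreasing")
    B <- 0
    A <- exp(mean(lv[seq_len(best$j - 1L)]))
  }
  fit <- list(A = A, B = B, C = exp(best$logC),
              n_powerlaw_points = best$j - 1L,
              breakpoint_index = min(best$j, m), rss = best$rss,
              flags = if (length(flags)) flags else "ok")
  class(fit) <- "powerlaw_fit"
  fit
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> A=%.4g, B=%.3f, C=%.4g (n_powerlaw=%d, %s)\n",
              x$A, x$B, x$C, x$n_powerlaw_points,
              paste(x$flags, collapse = ",")))
  invisible(x)
}

#' Distribution of single-cell power-law exponents B
#'
#' Fits every trajectory's time-averaged MSCD with [fit_powerlaw_plateau()]
#' and summarises the exponents of trajectories with at least `min_points`
#' data points in the power-law regime.
#'
#' @param dataset A dataset data.frame (or a list of precomputed
#'   `powerlaw_fit` objects).
#' @param min_points Minimum number of power-law-regime points to include a
#'   fit.
#' @return A list: `B_values`, `mean_B`, `n_total`, `n_kept`, `fits`.
#' @export
exponent_distribution <- function(dataset, min_points = 10) {
  fits <- if (is.data.frame(dataset)) {
    lapply(split_trajectories(dataset), function(tr) {
      cur <- suppressWarnings(mscd_time_avg(tr))
      if (sum(!is.na(cur$value) & cur$value > 0) < 4) return(NULL)
      fit_powerlaw_plateau(cur)
    })
  } else dataset
  fits <- Filter(Negate(is.null), fits)
  keep <- vapply(fits, function(f)
    f$n_powerlaw_points >= min_points && !"degenerate" %in% f$flags, TRUE)
  B <- vapply(fits[keep], function(f) f$B, numeric(1))
  list(B_values = unname(B), mean_B = if (length(B)) mean(B) else NA_real_,
       n_total = length(fits), n_kept = sum(keep), fits = fits)
}
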