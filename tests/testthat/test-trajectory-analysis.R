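test_that("colocalization states use the strict 250-nm rule", {
  pp <- polymer_params()
  tr <- make_traj(rbind(c(1, 0, 0), c(0.25, 0, 0), c(0.2, 0, 0)),
                  resolved = c(TRUE, TRUE, FALSE))
  st <- states_from_separation(tr, pp)
  expect_equal(st, c(FALSE, FALSE, TRUE))  # exactly 0.25 um is separated
  expect_equal(classify_trajectory(rep(TRUE, 5)), "colocalized")
  expect_equal(classify_trajectory(rep(FALSE, 5)), "separated")
  expect_equal(classify_trajectory(c(TRUE, TRUE, FALSE, TRUE)), "mixed")
})

test_that("trajectory classes partition every dataset", {
  sch <- default_stage_schedule()[c(1, 6), ]
  cfg <- study_config(schedule = sch, n_cells = 12, frames = 15, seed = 2,
                      mc_anchor = 10, mc_per = 20)
  s <- suppressWarnings(generate_study(cfg))
  pp <- polymer_params()
  cls <- vapply(split_trajectories(s$data), function(tr)
    classify_trajectory(states_from_separation(tr, pp)), character(1))
  expect_true(all(cls %in% c("colocalized", "separated", "mixed")))
  expect_equal(length(cls), 24)
})

test_that("dwell times are run lengths with censored boundary runs", {
  d <- dwell_times(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE), 30)
  expect_equal(d$duration, c(60, 90, 30))
  expect_equal(d$state, c("colocalized", "separated", "colocalized"))
  expect_equal(d$censored, c(TRUE, FALSE, TRUE))
  d2 <- dwell_times(c(FALSE, TRUE, FALSE), 30)
  expect_equal(d2$duration[!d2$censored], 30)
  expect_equal(d2$state[!d2$censored], "colocalized")
  ## constant series: a single, fully censored run
  d3 <- dwell_times(rep(TRUE, 7), 30)
  expect_equal(nrow(d3), 1)
  expect_true(all(d3$censored))
  ## durations (censored included) always sum to the movie length
  set.seed(4)
  for (i in 1:20) {
    st <- runif(50) < 0.4
    expect_equal(sum(dwell_times(st, 30)$duration), 50 * 30)
  }
})

test_that("fraction of time colocalized averages per-trajectory fractions", {
  pp <- polymer_params()
  ## two cells with fractions 0.2 and 0.6 -> 0.4 +- 0.2
  mk <- function(id, ncoloc) {
    sep <- matrix(1, 5, 3)
    sep[seq_len(ncoloc), ] <- 0.05
    make_traj(sep, cell_id = id)
  }
  d <- rbind(apply_detection(mk("a", 1), pp), apply_detection(mk("b", 3), pp))
  f <- fraction_time_colocalized(d, pp)
  expect_equal(f$fraction, 0.4)
  expect_equal(f$sem, 0.2)
  ## single trajectory: SEM 0 with a warning
  expect_warning(f1 <- fraction_time_colocalized(mk("a", 2), pp), "SEM")
  expect_equal(f1$fraction, 0.4)
  expect_equal(f1$sem, 0)
  ## all-colocalized dataset
  d2 <- apply_detection(make_traj(matrix(0.01, 4, 3)), pp)
  expect_warning(f2 <- fraction_time_colocalized(d2, pp))
  expect_equal(f2$fraction, 1)
})

test_that("short-dwell fraction counts single-frame colocalized dwells", {
  dw <- data.frame(duration = c(30, 90, 30, 60), censored = FALSE,
                   state = c("colocalized", "colocalized", "colocalized",
                             "separated"))
  expect_equal(fraction_short_dwell(dw), 2 / 3)
  dw2 <- data.frame(duration = c(60, 90), censored = FALSE,
                    state = "colocalized")
  expect_equal(fraction_short_dwell(dw2), 0)
  dw3 <- data.frame(duration = c(30, 30), censored = FALSE,
                    state = "colocalized")
  expect_equal(fraction_short_dwell(dw3), 1)
  expect_warning(out <- fraction_short_dwell(dw[dw$state == "separated", ]),
                 "no qualifying")
  expect_true(is.na(out))
})

test_that("time-averaged MSCD matches hand enumeration and omits masked frames", {
  ## 1D-embedded toy: dr = 0, 1, 1, 2 along x, dt = 1
  tr <- make_traj(cbind(c(0, 1, 1, 2), 0, 0), dt = 1)
  cur <- mscd_time_avg(tr)
  expect_equal(cur$lag, 0:3)
  expect_equal(cur$value, c(0, 2 / 3, 1, 4))
  expect_equal(cur$n, c(4, 3, 2, 1))
  ## constant separation
  expect_equal(mscd_time_avg(make_traj(matrix(1, 5, 3)))$value, rep(0, 5))
  ## masked middle frame: pairs touching it are omitted
  tr2 <- make_traj(cbind(c(0, 1, 9, 2, 4), 0, 0), dt = 1,
                   resolved = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  cur2 <- mscd_time_avg(tr2)
  expect_equal(cur2$n[-1], c(2, 1, 2, 1))      # lag 1: (1,2) and (4,5)
  expect_equal(cur2$value[2], ((1 - 0)^2 + (4 - 2)^2) / 2)
  expect_equal(cur2$value[3], (2 - 1)^2)       # lag 2: only (2,4) survives
  expect_equal(cur2$value[4], ((2 - 0)^2 + (4 - 1)^2) / 2)
  ## fewer than 2 resolved frames: empty curve with warning
  tr3 <- make_traj(matrix(1, 4, 3), resolved = c(TRUE, FALSE, FALSE, FALSE))
  expect_warning(e <- mscd_time_avg(tr3), "fewer than 2")
  expect_equal(length(e$value), 1)
})

test_that("fast MSCD estimator equals the brute-force pair loop", {
  set.seed(21)
  for (i in 1:15) {
    nf <- sample(4:10, 1)
    sep <- matrix(rnorm(nf * 3), nf, 3)
    resolved <- runif(nf) > 0.25
    if (sum(resolved) < 2) resolved[1:2] <- TRUE
    tr <- make_traj(sep, resolved = resolved)
    cur <- suppressWarnings(mscd_time_avg(tr))
    X <- sep; X[!resolved, ] <- NA
    or <- oracle_msq(X, 30)
    expect_equal(cur$value[-1], or$value)
    expect_equal(cur$n[-1], or$n)
  }
})

test_that("ensemble MSCD pools pairs and honours weighting options", {
  ## a dataset of one cell equals that cell's time average
  set.seed(22)
  tr <- make_traj(matrix(rnorm(18), 6, 3))
  expect_equal(mscd_ensemble(tr)$value, mscd_time_avg(tr)$value)
  ## identical copies of one trajectory leave the average unchanged
  tr2 <- tr; tr2$cell_id <- "c2"
  both <- rbind(tr, tr2)
  expect_equal(mscd_ensemble(both)$value, mscd_time_avg(tr)$value)
  ## two different cells: pooled pair-weighted mean from the oracle
  trb <- make_traj(matrix(rnorm(12), 4, 3), cell_id = "b")
  d <- rbind(tr, trb)
  oa <- oracle_msq(as.matrix(tr[, c("dx_um", "dy_um", "dz_um")]), 30)
  ob <- oracle_msq(as.matrix(trb[, c("dx_um", "dy_um", "dz_um")]), 30)
  pooled <- mscd_ensemble(d)
  for (k in 1:3) {
    expect_equal(pooled$value[k + 1],
                 (oa$value[k] * oa$n[k] + ob$value[k] * ob$n[k]) /
                   (oa$n[k] + ob$n[k]))
  }
  ## cell weighting averages the two time-averaged values instead
  cellw <- mscd_ensemble(d, weighting = "cell")
  expect_equal(cellw$value[2], (oa$value[1] + ob$value[1]) / 2)
  ## value censoring drops sub-floor per-cell values
  lowcell <- make_traj(matrix(rnorm(18, sd = 1e-3), 6, 3), cell_id = "lo")
  cen <- mscd_ensemble(rbind(tr, lowcell), weighting = "cell",
                       censor_floor = 0.0625)
  expect_equal(cen$value[2], mscd_time_avg(tr)$value[2])
})

test_that("single-locus MSD mirrors the estimator and flags linkage", {
  ## static locus
  tr <- make_traj(matrix(1, 5, 3))
  tr$x1_um <- 1; tr$y1_um <- 2; tr$z1_um <- 3
  expect_equal(msd_time_avg(tr)$value, rep(0, 5))
  expect_error(msd_time_avg(make_traj(matrix(1, 4, 3))), "positions")
  ## hand-enumerated 4-frame walk
  tr2 <- make_traj(matrix(0, 4, 3), dt = 1)
  tr2$x1_um <- c(0, 1, 3, 3); tr2$y1_um <- 0; tr2$z1_um <- 0
  expect_equal(msd_time_avg(tr2)$value[-1],
               c((1 + 4 + 0) / 3, (9 + 4) / 2, 9))
  ## simulated linked cell: MSCD plateaus below the MSD
  ch <- lookup_chromosome("URA3")
  pp <- polymer_params()
  ring <- structure(list(topology = "ring", segments = c(n1 = 1.5, n2 = 1.5),
                         rabl = FALSE, pinned = FALSE, linkage_positions = 1),
                    class = "cell_realization")
  set.seed(30)
  tr3 <- simulate_trajectory(ring, ch, pp, seq(0, 1470, 30),
                             confined = list(plateau = 1.8, offset_msq = 0),
                             include_positions = TRUE)
  mscd_max <- max(mscd_time_avg(tr3)$value, na.rm = TRUE)
  msd_max <- max(msd_time_avg(tr3)$value, na.rm = TRUE)
  expect_lt(mscd_max, msd_max)
})

test_that("min(A t^B, C) fitting recovers exact curves and flags edge cases", {
  lt <- seq(0, by = 30, length.out = 50)
  ## exact two-regime curve on the movie grid
  v <- pmin(0.1 * lt^0.24, 0.5); v[1] <- 0
  fit <- fit_powerlaw_plateau(mscd_curve(lt, v))
  expect_lt(abs(fit$A - 0.1) / 0.1, 0.01)
  expect_lt(abs(fit$B - 0.24), 0.01 * 0.24)
  expect_lt(abs(fit$C - 0.5) / 0.5, 0.01)
  expect_gte(fit$n_powerlaw_points, 10)
  ## degenerate constant curve
  flat <- fit_powerlaw_plateau(mscd_curve(lt[-1], rep(2, 49)))
  expect_equal(flat$B, 0)
  expect_equal(flat$C, 2)
  expect_equal(flat$flags, "degenerate")
  ## pure power law: no plateau within the window
  pw <- fit_powerlaw_plateau(mscd_curve(lt[-1], 0.01 * lt[-1]^0.3))
  expect_true("no_plateau" %in% pw$flags)
  expect_equal(pw$n_powerlaw_points, 49)
  expect_equal(pw$C, 0.01 * lt[50]^0.3, tolerance = 1e-6)
  expect_error(fit_powerlaw_plateau(mscd_curve(c(30, 60), c(1, 2))), "4")
})

test_that("exponent distribution filters by power-law points", {
  lt <- seq(30, by = 30, length.out = 49)
  fits <- list(
    fit_powerlaw_plateau(mscd_curve(lt, 0.01 * lt^0.3)),     # 49 points
    fit_powerlaw_plateau(mscd_curve(lt, pmin(0.3 * lt^0.24, 0.75))),
    fit_powerlaw_plateau(mscd_curve(lt, rep(1, 49))))        # degenerate
  e <- exponent_distribution(fits, min_points = 10)
  expect_equal(e$n_total, 3)
  expect_lte(e$n_kept, 2)
  expect_true(all(e$B_values > 0))
})
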