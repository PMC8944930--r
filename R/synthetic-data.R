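## Synthetic stand-in for the live-imaging experiment: exact-covariance
## Gaussian sampling of separation trajectories, detection-limit masking, and
## a staged (T0..Tn) study generator with seed-deterministic substreams.

#' Default stage schedule of a sporulation time course
#'
#' One row per hourly stage T0, T1, ...: mean linkage number `mu`, Rabl
#' probability `p_rabl = exp(-k_rabl * t)`, and stage subdiffusion
#' coefficient `D0`.  Linkage onset follows the wild-type calibration for
#' the chosen locus (URA3: mu = 0.08, 1.27, 3.36 at T3..T5; LYS2: mu = 1.27,
#' 2.06 at T5..T6, zero earlier); `spo11` switches to the recombination-null
#' control with mu = 0 throughout.  Stage diffusivities increase through
#' prophase (an observed trend; values are model defaults, um^2/s^(alpha/2)).
#'
#' @param chromosome `"URA3"` or `"LYS2"` (tagged-locus name).
#' @param k_rabl Rabl exit rate, per hour.
#' @param spo11 Use the recombination-null (mu = 0) schedule?
#' @return A data.frame with columns `stage`, `t_hours`, `mu`, `p_rabl`, `D0`.
#' @export
default_stage_schedule <- function(chromosome = "URA3", k_rabl = 0.605,
                                   spo11 = FALSE) {
  mu <- switch(chromosome,
               URA3 = c(0, 0, 0, 0.08, 1.27, 3.36),
               LYS2 = c(0, 0, 0, 0, 0, 1.27, 2.06),
               stop("unknown chromosome schedule: ", chromosome))
  if (spo11) mu[] <- 0
  t <- seq_along(mu) - 1
  data.frame(stage = paste0("T", t), t_hours = t, mu = mu,
             p_rabl = exp(-k_rabl * t),
             D0 = 0.015 + 0.005 * t, stringsAsFactors = FALSE)
}

#' Study configuration
#'
#' Bundles everything [generate_study()] needs: the chromosome, the per-stage
#' schedule, movie geometry and the master seed.
#'
#' @param chromosome Tagged-locus or chromosome name (resolved through
#'   [lookup_chromosome()]).
#' @param schedule Stage schedule data.frame (see
#'   [default_stage_schedule()]); must have columns `stage`, `t_hours`,
#'   `mu`, `p_rabl`, `D0`.
#' @param n_cells Cells per stage (scalar, recycled, or one per stage).
#' @param frames Frames per movie.
#' @param dt Frame interval, s.
#' @param seed Master seed (integer).
#' @param localization_sd Optional isotropic localization noise added to each
#'   separation component, um (default 0: the imaging noise is not modelled).
#' @param include_positions Also emit per-locus 3D positions (columns
#'   `x1_um`..`z2_um`) for MSD analysis?
#' @param mc_anchor,mc_per Monte-Carlo settings forwarded to
#'   [confined_locus_stats()].
#' @return An object of class `study_config` (a list).
#' @export
study_config <- function(chromosome = "URA3",
                         schedule = default_stage_schedule(chromosome),
                         n_cells = 100, frames = 50, dt = 30, seed = 1,
                         localization_sd = 0, include_positions = FALSE,
                         mc_anchor = 60, mc_per = 80) {
  cfg <- structure(list(chromosome = chromosome, schedule = schedule,
                        n_cells = n_cells, frames = frames, dt = dt,
                        seed = seed, localization_sd = localization_sd,
                        include_positions = include_positions,
                        mc_anchor = mc_anchor, mc_per = mc_per),
                   class = "study_config")
  errs <- config_errors(cfg)
  if (length(errs)) stop(paste(errs, collapse = "\n  "))
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %s, %d stage(s), %s cells/stage, %d x %gs frames, seed %d\n",
              x$chromosome, nrow(x$schedule),
              paste(unique(x$n_cells), collapse = "/"),
              x$frames, x$dt, x$seed))
  invisible(x)
}

#' Simulate one cell's separation trajectory
#'
#' Samples the separation vector of the tagged locus pair as a stationary,
#' isotropic Gaussian process whose implied MSCD equals the cell's
#' theoretical curve: per-axis covariance `K(t) = P/6 - MSCD(t)/6` with `P`
#' the cell plateau, sampled exactly on the frame grid by Cholesky
#' factorisation of the frame-by-frame covariance.  Unlinked cells
#' additionally receive a static anchor-induced mean separation drawn from
#' the confinement ensemble.  Detection masking ([apply_detection()]) is
#' applied before returning.
#'
#' @param cell A [sample_cell()] realization.
#' @param chrom A [chromosome_spec()].
#' @param params A [polymer_params()].
#' @param frame_times Frame times, s (at least 2).
#' @param confined A [confined_locus_stats()] result for the cell's tethering
#'   state (computed at modest settings when missing).
#' @param include_positions Also emit per-locus positions (common-mode
#'   nuclear motion plus/minus half the separation)?
#' @param localization_sd Isotropic localization noise per axis, um.
#' @return A data.frame of class `trajectory` with columns `frame`, `t_s`,
#'   `dx_um`, `dy_um`, `dz_um`, `resolved` (and optionally `x1_um`..`z2_um`),
#'   plus attributes `cell` and `plateau`.
#' @export
simulate_trajectory <- function(cell, chrom, params,
                                frame_times = seq(0, by = 30, length.out = 50),
                                confined = NULL, include_positions = FALSE,
                                localization_sd = 0) {
  stopifnot(inherits(cell, "cell_realization"), length(frame_times) >= 2)
  if (is.null(confined))
    confined <- confined_locus_stats(
      chrom, params, if (cell$rabl) "rabl" else "telomeres_only",
      n_anchor = 40, n_per = 60)
  P <- min(cell_tether_plateau(cell, params), confined$plateau)
  nf <- length(frame_times)
  dr <- gp_sample_3d(frame_times, P, 6 * params$D0, params$alpha)
  ## the anchor-induced offset draw always consumes 3 normals so that the
  ## random stream stays aligned across cells with different topologies
  ## (needed by common-random-number inversions)
  off_sd <- if (cell$topology == "unlinked")
    sqrt(max(confined$offset_msq, 0) / 3) else 0
  dr <- dr + matrix(rnorm(3, 0, 1) * off_sd, nf, 3, byrow = TRUE)
  if (localization_sd > 0)
    dr <- dr + matrix(rnorm(3 * nf, 0, localization_sd), nf, 3)
  out <- data.frame(frame = seq_len(nf), t_s = frame_times,
                    dx_um = dr[, 1], dy_um = dr[, 2], dz_um = dr[, 3],
                    resolved = TRUE)
  if (include_positions) {
    ## common-mode nuclear motion: same kernel family, quarter amplitude
    R <- gp_sample_3d(frame_times, confined$plateau / 4, 1.5 * params$D0,
                      params$alpha)
    out$x1_um <- R[, 1] + dr[, 1] / 2; out$y1_um <- R[, 2] + dr[, 2] / 2
    out$z1_um <- R[, 3] + dr[, 3] / 2
    out$x2_um <- R[, 1] - dr[, 1] / 2; out$y2_um <- R[, 2] - dr[, 2] / 2
    out$z2_um <- R[, 3] - dr[, 3] / 2
  }
  out <- apply_detection(out, params)
  attr(out, "cell") <- cell
  attr(out, "plateau") <- P
  class(out) <- c("trajectory", "data.frame")
  out
}

## Sample a zero-mean stationary 3D Gaussian process on `times` whose
## summed-over-axes MSCD is the theoretical crossover curve with plateau C
## and early asymptote A t^(alpha/2): per-axis covariance K(t) = C/6 -
## MSCD(t)/6.  The default mode-sum kernel is a positive mixture of
## stretched exponentials exp(-(t/tau_p)^alpha), hence positive definite.
## C = 0 gives a frozen process.
gp_sample_3d <- function(times, C, A, alpha, form = "modesum") {
  nf <- length(times)
  if (C <= 0) return(matrix(0, nf, 3))
  lagmat <- abs(outer(times, times, "-"))
  ulag <- sort(unique(as.numeric(lagmat)))  # regular grids: nf unique lags
  Mu <- mscd_theory_values(C, A / 6, alpha, ulag, form)
  M <- matrix(Mu[match(as.numeric(lagmat), ulag)], nf, nf)
  K <- (C - M) / 6
  L <- NULL
  jitter <- 0
  for (k in 0:6) {
    L <- tryCatch(chol(K + diag(jitter, nf)), error = function(e) NULL)
    if (!is.null(L)) break
    jitter <- max(jitter * 10, 1e-12)
  }
  if (is.null(L)) stop("covariance factorisation failed even with jitter")
  if (jitter > 0)
    message("covariance regularised with jitter ", signif(jitter, 2))
  t(L) %*% matrix(rnorm(3 * nf), nf, 3)
}

#' Apply the two-focus detection limit
#'
#' Frames whose separation falls below the resolution limit are flagged
#' `resolved = FALSE` and their separation components are masked (`NA`):
#' such frames appear as a single focus, are treated as colocalized in state
#' analyses, and are omitted from MSCD estimation.  Idempotent.
#'
#' @param traj A trajectory data.frame with `dx_um`, `dy_um`, `dz_um`.
#' @param params A [polymer_params()] (uses `resolution`, nm).
#' @return The trajectory with updated `resolved` flags and masked
#'   separations.
#' @export
apply_detection <- function(traj, params) {
  res_um <- params$resolution / 1000
  sep <- sqrt(traj$dx_um^2 + traj$dy_um^2 + traj$dz_um^2)
  resolved <- !is.na(sep) & sep >= res_um
  traj$resolved <- resolved
  traj$dx_um[!resolved] <- NA_real_
  traj$dy_um[!resolved] <- NA_real_
  traj$dz_um[!resolved] <- NA_real_
  traj
}

#' Generate a full multi-stage synthetic study
#'
#' For each stage of the configured schedule, samples cell realizations
#' ([sample_cell()] at the stage's `mu` and `p_rabl`), simulates their
#' trajectories at the stage diffusivity, applies the detection limit, and
#' (optionally) writes one CSV per stage plus a JSON manifest.  Fully
#' reproducible from the master seed: confinement statistics and each stage
#' use independent sub-seeds derived from it, so stages are independent.
#'
#' @param config A [study_config()].
#' @param params A [polymer_params()]; the stage schedule's `D0` overrides
#'   `params$D0` stage by stage.
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @return A list of class `study`: `data` (the combined dataset
#'   data.frame), `config`, `params`, `confined` (confinement statistics) and
#'   `manifest`.
#' @export
generate_study <- function(config, params = polymer_params(), outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  chrom <- lookup_chromosome(config$chromosome)
  sch <- config$schedule
  n_stage <- nrow(sch)
  ncells <- rep_len(config$n_cells, n_stage)
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, n_stage + 1L))
  confined <- with_seed(seeds[1L], list(
    telomeres_only = confined_locus_stats(chrom, params, "telomeres_only",
                                          config$mc_anchor, config$mc_per),
    rabl = confined_locus_stats(chrom, params, "rabl",
                                config$mc_anchor, config$mc_per)))
  frame_times <- seq(0, by = config$dt, length.out = config$frames)
  pieces <- vector("list", n_stage)
  for (i in seq_len(n_stage)) {
    p_st <- params
    p_st$D0 <- sch$D0[i]
    pieces[[i]] <- with_seed(seeds[i + 1L], {
      rows <- lapply(seq_len(ncells[i]), function(j) {
        cell <- sample_cell(chrom, p_st, sch$mu[i], sch$p_rabl[i])
        tr <- simulate_trajectory(
          cell, chrom, p_st, frame_times,
          confined = if (cell$rabl) confined$rabl else confined$telomeres_only,
          include_positions = config$include_positions,
          localization_sd = config$localization_sd)
        cbind(cell_id = sprintf("%s_c%04d", sch$stage[i], j),
              stage = sch$stage[i], as.data.frame(tr))
      })
      do.call(rbind, rows)
    })
  }
  data <- do.call(rbind, pieces)
  rownames(data) <- NULL
  manifest <- list(package = "homolink",
                   version = as.character(utils::packageVersion("homolink")),
                   seed = config$seed,
                   chromosome = config$chromosome,
                   stages = sch,
                   n_cells = ncells, frames = config$frames, dt = config$dt,
                   localization_sd = config$localization_sd,
                   confined = list(
                     telomeres_only = confined$telomeres_only[c("plateau", "sem", "offset_msq")],
                     rabl = confined$rabl[c("plateau", "sem", "offset_msq")]))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(n_stage)
    for (i in seq_len(n_stage)) {
      files[i] <- file.path(outdir, paste0("stage_", sch$stage[i], ".csv"))
      write_dataset(data[data$stage == sch$stage[i], , drop = FALSE], files[i])
    }
    manifest$files <- basename(files)
    manifest$checksums <- unname(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(data = data, config = config, params = params,
                 confined = confined, manifest = manifest), class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study> %s: %d trajectories, %d frames each, seed %d\n",
              x$config$chromosome, length(unique(x$data$cell_id)),
              x$config$frames, x$config$seed))
  invisible(x)
}

dataset_columns <- c("cell_id", "stage", "frame", "t_s",
                     "dx_um", "dy_um", "dz_um", "resolved")

#' Write a trajectory dataset to CSV
#'
#' Headered CSV with columns `cell_id, stage, frame, t_s, dx_um, dy_um,
#' dz_um, resolved` (plus optional position columns).  Masked separations
#' (unresolved frames) are written as empty fields.
#'
#' @param dataset A dataset data.frame (e.g. `generate_study(...)$data`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  miss <- setdiff(dataset_columns, names(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  out <- dataset
  num <- vapply(out, is.numeric, TRUE) & !(names(out) %in% c("frame"))
  for (j in which(num))
    out[[j]] <- ifelse(is.na(out[[j]]), "",
                       formatC(out[[j]], digits = 9, format = "g"))
  out$resolved <- ifelse(dataset$resolved, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory dataset from CSV
#'
#' Inverse of [write_dataset()]: restores types, re-masks empty separation
#' fields as `NA`, and validates the file (required columns, per-cell
#' strictly increasing frame times, masked separations only on unresolved
#' frames).  Malformed rows raise an error naming the row and field.
#'
#' @param path CSV file path (or several, concatenated).
#' @return A dataset data.frame.
#' @export
read_dataset <- function(path) {
  tabs <- lapply(path, read.csv, stringsAsFactors = FALSE)
  tab <- do.call(rbind, tabs)
  miss <- setdiff(dataset_columns, names(tab))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  tab$resolved <- as.logical(tab$resolved)
  if (any(is.na(tab$resolved)))
    stop("invalid 'resolved' value at row ",
         which(is.na(tab$resolved))[1])
  for (id in unique(tab$cell_id)) {
    ts <- tab$t_s[tab$cell_id == id]
    bad <- which(diff(ts) <= 0)
    if (length(bad))
      stop("non-monotone 't_s' for cell ", id, " at frame row ", bad[1] + 1)
  }
  sep_na <- is.na(tab$dx_um) | is.na(tab$dy_um) | is.na(tab$dz_um)
  bad <- which(sep_na & tab$resolved)
  if (length(bad))
    stop("missing separation on resolved frame at row ", bad[1],
         " (fields dx_um/dy_um/dz_um)")
  tab
}
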