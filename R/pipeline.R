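## Orchestration: configuration validation, seeded end-to-end runs
## (simulate -> analyse -> fit -> report), manifests and logging.

## Collect human-readable validation errors for a study_config-shaped list.
config_errors <- function(cfg) {
  errs <- character(0)
  say <- function(...) errs <<- c(errs, sprintf(...))
  if (is.null(cfg$chromosome) || !is.character(cfg$chromosome))
    say("missing or invalid 'chromosome'")
  sch <- cfg$schedule
  if (is.null(sch) || !is.data.frame(sch)) {
    say("missing 'schedule' table")
  } else {
    need <- c("stage", "t_hours", "mu", "p_rabl", "D0")
    miss <- setdiff(need, names(sch))
    if (length(miss)) say("schedule lacks columns: %s",
                          paste(miss, collapse = ", "))
    else {
      if (is.unsorted(sch$t_hours, strictly = TRUE))
        say("schedule stages must have strictly increasing t_hours")
      for (i in seq_len(nrow(sch))) {
        if (!is.finite(sch$mu[i]) || sch$mu[i] < 0)
          say("stage %s: negative or invalid mu", sch$stage[i])
        if (!is.finite(sch$p_rabl[i]) || sch$p_rabl[i] < 0 || sch$p_rabl[i] > 1)
          say("stage %s: p_rabl outside [0, 1]", sch$stage[i])
        if (!is.finite(sch$D0[i]) || sch$D0[i] <= 0)
          say("stage %s: nonpositive D0", sch$stage[i])
      }
    }
  }
  num_ok <- function(x) is.numeric(x) && length(x) >= 1 && all(is.finite(x))
  if (!num_ok(cfg$n_cells) || any(cfg$n_cells < 1))
    say("'n_cells' must be a positive count")
  if (!num_ok(cfg$frames) || cfg$frames[1] < 2) say("'frames' must be >= 2")
  if (!num_ok(cfg$dt) || cfg$dt[1] <= 0) say("'dt' must be positive")
  if (!num_ok(cfg$seed)) say("'seed' must be an integer")
  if (!is.null(cfg$localization_sd) &&
      (!num_ok(cfg$localization_sd) || cfg$localization_sd < 0))
    say("'localization_sd' must be nonnegative")
  errs
}

#' Validate a study configuration
#'
#' Type- and range-checks every field of a configuration, either an
#' in-memory [study_config()]-shaped list or a JSON file (fields of
#' [study_config()]; `schedule` as an array of stage records).
#'
#' @param config A list or a path to a JSON configuration file.
#' @return `TRUE` invisibly if valid; otherwise raises an error aggregating
#'   every problem found.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  errs <- config_errors(cfg)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

#' Read a study configuration from JSON
#'
#' @param path JSON file (see `inst/config/default_study.json` for the
#'   layout).
#' @return A [study_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- if (!is.null(raw$schedule)) as.data.frame(raw$schedule)
         else default_stage_schedule(raw$chromosome %||% "URA3")
  study_config(
    chromosome = raw$chromosome %||% "URA3",
    schedule = sch,
    n_cells = raw$n_cells %||% 100,
    frames = raw$frames %||% 50,
    dt = raw$dt %||% 30,
    seed = raw$seed %||% 1,
    localization_sd = raw$localization_sd %||% 0,
    include_positions = isTRUE(raw$include_positions),
    mc_anchor = raw$mc_anchor %||% 60,
    mc_per = raw$mc_per %||% 80)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(logfile, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full pipeline: simulate, analyse, fit, report
#'
#' Executes [generate_study()] and the downstream analysis chain -- per-stage
#' colocalized fractions, dwell collection and [fit_dwell_models()],
#' per-cell power-law fits and the exponent distribution, ensemble MSCD
#' curves with plateau extraction, [fit_rabl_rate()] on the stage plateaus,
#' per-stage [fit_subdiffusion_coefficient()], and (optionally)
#' [fit_linkage_number()] per stage -- writing TSV tables, a plain-text
#' report and a JSON manifest with checksums.  Deterministic per seed.
#'
#' @param config A [study_config()], a config list, or a path to a JSON
#'   config.
#' @param outdir Output directory.
#' @param params A [polymer_params()].
#' @param seed Optional master-seed override.
#' @param fit_mu Invert the linkage number per stage (the slowest step)?
#' @param mu_cells Bank size for [fit_linkage_number()].
#' @return The manifest list, invisibly; all outputs are under `outdir`.
#' @export
run_pipeline <- function(config, outdir, params = polymer_params(),
                         seed = NULL, fit_mu = TRUE, mu_cells = 2000) {
  cfg <- if (is.character(config)) read_config(config) else config
  validate_config(cfg)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  log_line(logfile, "simulate: %s, %d stage(s), seed %d",
           cfg$chromosome, nrow(cfg$schedule), cfg$seed)

  study <- generate_study(cfg, params, outdir = file.path(outdir, "dataset"))
  data <- study$data
  chrom <- lookup_chromosome(cfg$chromosome)
  sch <- cfg$schedule
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  files <- character(0)

  log_line(logfile, "analyse: colocalization and dwell statistics")
  frac <- fraction_time_colocalized(data, params)
  files <- c(files, wtsv(frac, "fraction_colocalized.tsv"))
  dwells <- dwell_times_dataset(data, params)
  files <- c(files, wtsv(dwells, "dwell_times.tsv"))
  dwell_fits <- tryCatch(fit_dwell_models(dwells,
                                          t_max = cfg$frames * cfg$dt),
                         error = function(e) NULL)
  if (!is.null(dwell_fits))
    files <- c(files, wtsv(dwell_fits, "dwell_model_fits.tsv"))
  short <- vapply(split(dwells, factor(sub("_c.*", "", dwells$cell_id),
                                       levels = sch$stage)),
                  function(d) if (nrow(d)) suppressWarnings(
                    fraction_short_dwell(d)) else NA_real_, numeric(1))
  files <- c(files, wtsv(data.frame(stage = sch$stage, frac_short = short),
                         "fraction_short_dwell.tsv"))

  log_line(logfile, "analyse: MSCD curves and power-law fits")
  curves <- mscd_ensemble(data)
  if (inherits(curves, "mscd_curve")) curves <- setNames(list(curves), sch$stage[1])
  curve_tab <- do.call(rbind, lapply(names(curves), function(s)
    cbind(stage = s, as.data.frame(curves[[s]]))))
  files <- c(files, wtsv(curve_tab, "mscd_ensemble.tsv"))
  expo <- exponent_distribution(data)
  files <- c(files, wtsv(data.frame(B = expo$B_values), "exponent_B.tsv"))

  log_line(logfile, "fit: stage plateaus, Rabl rate, D0%s",
           if (fit_mu) ", linkage numbers" else "")
  ## fits run on the censored, cell-weighted ensemble (the estimator the
  ## calibration chain and the linkage inversion are defined on)
  curves_c <- mscd_ensemble(data, weighting = "cell",
                            censor_floor = params$mscd_floor)
  if (inherits(curves_c, "mscd_curve"))
    curves_c <- setNames(list(curves_c), sch$stage[1])
  plate <- vapply(sch$stage, function(s)
    fit_powerlaw_plateau(curves_c[[s]])$C, numeric(1))
  rabl <- if (nrow(sch) >= 3) fit_rabl_rate(sch$t_hours, plate) else NULL
  d0 <- vapply(seq_len(nrow(sch)), function(i) {
    p <- params; p$D0 <- sch$D0[i]
    tryCatch(fit_subdiffusion_coefficient(curves_c[[sch$stage[i]]], p,
                                          plateau = plate[i]),
             error = function(e) NA_real_)
  }, numeric(1))
  mu_hat <- rep(NA_real_, nrow(sch))
  if (fit_mu) {
    mu_seed <- with_seed(cfg$seed, draw_seed())
    for (i in seq_len(nrow(sch))) {
      if (sch$mu[i] == 0 && sch$p_rabl[i] > 0.5) next  # Rabl-dominated stage
      p <- params; p$D0 <- sch$D0[i]
      mu_hat[i] <- tryCatch(suppressWarnings(fit_linkage_number(
        plate[i], chrom, p, p_rabl = sch$p_rabl[i], censor = TRUE,
        n_cells = mu_cells, confined = study$confined,
        method = "simulate", seed = mu_seed)),
        error = function(e) NA_real_)
    }
  }
  stage_fits <- data.frame(stage = sch$stage, t_hours = sch$t_hours,
                           plateau_um2 = plate, D0_hat = d0, mu_hat = mu_hat,
                           mu_true = sch$mu, D0_true = sch$D0)
  files <- c(files, wtsv(stage_fits, "stage_fits.tsv"))

  report <- file.path(outdir, "report.txt")
  con <- file(report, "w")
  writeLines(c(
    sprintf("homolink pipeline report (seed %d)", cfg$seed),
    sprintf("chromosome: %s; %d stages; %s cells/stage; %d x %gs frames",
            cfg$chromosome, nrow(sch),
            paste(unique(rep_len(cfg$n_cells, nrow(sch))), collapse = "/"),
            cfg$frames, cfg$dt),
    "",
    "fraction of time colocalized by stage:",
    sprintf("  %s: %.3f +- %.3f (n=%d)", frac$stage, frac$fraction,
            frac$sem, frac$n_cells),
    "",
    sprintf("mean single-cell exponent B: %.3f (%d of %d fits kept)",
            expo$mean_B, expo$n_kept, expo$n_total),
    if (!is.null(dwell_fits))
      sprintf("best dwell model: %s (delta AIC to next: %.1f)",
              dwell_fits$model[1], dwell_fits$delta_AIC[2]) else
      "dwell model fits: skipped (too few dwells)",
    if (!is.null(rabl))
      sprintf("Rabl fit: k_rabl=%.3g /h, MSCD_inf=%.3g um^2",
              rabl$k_rabl, rabl$mscd_inf) else "Rabl fit: skipped",
    "",
    "stage fits (plateau, D0_hat, mu_hat):",
    sprintf("  %s: C=%.3g um^2, D0=%.3g, mu=%s", sch$stage, plate, d0,
            ifelse(is.na(mu_hat), "-", sprintf("%.2f", mu_hat)))),
    con)
  close(con)
  files <- c(files, report)

  manifest <- study$manifest
  manifest$outputs <- basename(files)
  manifest$output_checksums <- unname(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(logfile, "done: %d output files", length(files))
  invisible(manifest)
}
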