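#' Run configuration for the full pipeline
#'
#' Bundles the input source (a track file or a [sim_config()]), the
#' interval scheme and the analysis parameters into one serializable
#' object, so that a run is reproducible from its resolved config and seed
#' alone.
#'
#' @param simulation a [sim_config()], or NULL to read `tracks_file`.
#' @param tracks_file path to a track table (used when `simulation` is
#'   NULL).
#' @param scheme an [interval_scheme()].
#' @param max_lag largest MSD lag (min).
#' @param lag_range_pre,lag_range_post MSD fit windows (min) for the
#'   pre-split and post-split intervals (the 10-min windows cap usable
#'   lags).
#' @param bin_width,min_count drift-profile binning parameters.
#' @param threshold_sd Gaussian-excess tail cut.
#' @param n_boot bootstrap replicates for fit standard errors.
#' @param seed master RNG seed.
#' @param out_dir directory for TSV/JSON outputs, or NULL for none.
#' @return a `run_config`.
#' @export
run_config <- function(simulation = sim_config(), tracks_file = NULL,
                       scheme = interval_scheme(), max_lag = 10,
                       lag_range_pre = c(1, 20), lag_range_post = c(1, 10),
                       bin_width = 0.05, min_count = 25,
                       threshold_sd = 2.5, n_boot = 200, seed = 1,
                       out_dir = NULL) {
  structure(list(simulation = simulation, tracks_file = tracks_file,
                 scheme = scheme, max_lag = max_lag,
                 lag_range_pre = lag_range_pre,
                 lag_range_post = lag_range_post,
                 bin_width = bin_width, min_count = min_count,
                 threshold_sd = threshold_sd, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full segregation-dynamics analysis
#'
#' Orchestrates simulate/load -> synchronize -> orient -> label foci ->
#' occupancy map -> per-interval MSD fits, step summaries and drift
#' profiles -> equilibria and relaxation time -> force profile, and
#' returns one report aggregating every estimate.  Re-running the same
#' config and seed reproduces the report exactly.
#'
#' @param config a [run_config()].
#' @return a `run_report` list with elements `config_seed`, `ensemble_info`,
#'   `occupancy`, `msd` (per interval), `steps` (per interval), `drift`
#'   (per interval, with equilibria), `relaxation`, `force`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ens <- if (!is.null(config$simulation)) {
    simulate_split_cycle(config$simulation)
  } else {
    load_tracks(config$tracks_file, quiet = TRUE)
  }
  ens <- synchronize(ens)
  has_fid <- "fid" %in% ens$obs$channel
  if (has_fid) ens <- orient(ens)
  ens <- label_foci(ens)

  intervals <- config$scheme$name
  occ <- occupancy_map(ens)

  msd_out <- list(); step_out <- list(); drift_out <- list()
  for (iv in intervals) {
    pre_split <- interval_window(iv, config$scheme)[2] <= 0
    lag_range <- if (pre_split) config$lag_range_pre else config$lag_range_post
    curve <- compute_msd(ens, iv, max_lag = max(lag_range),
                         scheme = config$scheme)
    fit <- tryCatch(fit_power_law(curve, lag_range, n_boot = config$n_boot,
                                  seed = config$seed),
                    error = function(e) NULL)
    msd_out[[iv]] <- list(curve = as.data.frame(curve), fit = fit)

    st <- compute_steps(ens, iv, selection = if (pre_split) "all" else "right",
                        scheme = config$scheme)
    step_out[[iv]] <- if (nrow(st) >= 2) {
      s <- summarize_steps(st, threshold_sd = config$threshold_sd)
      s$excess_ci <- gaussian_excess(st, config$threshold_sd,
                                     n_boot = config$n_boot,
                                     seed = config$seed)$ci
      s
    } else NULL

    dp <- tryCatch(
      compute_drift_profile(ens, iv, bin_width = config$bin_width,
                            min_count = config$min_count,
                            selection = "all", scheme = config$scheme),
      error = function(e) NULL)
    drift_out[[iv]] <- if (!is.null(dp)) {
      list(profile = as.data.frame(dp), equilibria = find_equilibria(dp))
    } else NULL
  }

  # relaxation time from the pre-split profile around mid-cell
  relax <- NULL
  if (!is.null(drift_out[["pre"]])) {
    dp_pre <- compute_drift_profile(ens, "pre", bin_width = config$bin_width,
                                    min_count = config$min_count,
                                    scheme = config$scheme)
    relax <- tryCatch(fit_relaxation_time(dp_pre, around = 0),
                      error = function(e) NULL)
  }

  # force profile for the post-segregation interval (right focus, mirrored
  # pooling for power)
  force <- NULL
  post_summary <- step_out[["post"]]
  if (!is.null(drift_out[["post"]]) && !is.null(post_summary) &&
      post_summary$D_eff > 0) {
    L <- mean(ens$obs$cell_length_um, na.rm = TRUE)
    ctx <- physical_context(cell_length_um = if (is.finite(L)) L else 2.5,
                            delta_t = ens$delta_t)
    dp_post <- compute_drift_profile(ens, "post", bin_width = config$bin_width,
                                     min_count = config$min_count,
                                     selection = "mirror",
                                     scheme = config$scheme)
    force <- force_profile(dp_post, post_summary$D_eff, ctx)
  }

  report <- structure(list(
    config_seed = config$seed,
    ensemble_info = list(n_cells = n_cells(ens), n_obs = nrow(ens$obs),
                         delta_t = ens$delta_t,
                         n_excluded = nrow(ens$exclusions)),
    occupancy = occ, msd = msd_out, steps = step_out, drift = drift_out,
    relaxation = relax, force = force
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Serialize a run report: JSON summary plus per-interval TSV tables.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    seed = report$config_seed,
    ensemble = report$ensemble_info,
    msd_fits = lapply(report$msd, function(m) {
      if (is.null(m$fit)) NULL else
        m$fit[c("alpha", "D_gen", "stderr_alpha", "lag_range")]
    }),
    step_summaries = lapply(report$steps, function(s) {
      if (is.null(s)) NULL else
        s[c("v", "se_v", "D_eff", "se_D_eff", "n", "excess_tail", "acf1")]
    }),
    equilibria = lapply(report$drift, function(d) {
      if (is.null(d)) NULL else d$equilibria
    }),
    relaxation = report$relaxation,
    force = if (is.null(report$force)) NULL else
      report$force[c("gamma_kg_s", "peak_F_N", "annotation")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (iv in names(report$msd)) {
    write.table(report$msd[[iv]]$curve,
                file.path(out_dir, paste0("msd_", iv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$drift[[iv]])) {
      write.table(report$drift[[iv]]$profile,
                  file.path(out_dir, paste0("drift_", iv, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out_dir)
}
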