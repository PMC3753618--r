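#' Spatially binned drift-velocity profile
#'
#' The central object of the analysis: the mean step per unit time as a
#' function of where the step started, v(x) = <dx | x(t) in bin>/dt,
#' computed per cell-cycle interval.  A restoring (spring-like) profile is
#' a line of negative slope crossing zero at the equilibrium position;
#' before the split the equilibrium sits at mid-cell, after it at the
#' quarter-cell positions.  Steps are binned by their start position,
#' consistent with the conditional-mean convention of the
#' Ornstein-Uhlenbeck oracle used to test this function.
#'
#' @param ensemble a [track_ensemble()].
#' @param interval interval label or NULL (all frames).
#' @param bin_width position bin width (relative units).
#' @param min_count bins with fewer steps are flagged unpopulated (absent,
#'   not zero).
#' @param selection post-split focus rule (see [compute_steps()]); the
#'   default `"all"` keeps both foci so the post-split profile shows both
#'   quarter-cell equilibria.
#' @param lag step length in frames.
#' @param scheme,channel,post_split_start as in [compute_steps()].
#' @return a `drift_profile`: data.frame with columns `x` (bin centre),
#'   `x_mean` (mean start position of the steps in the bin, the abscissa
#'   used for slope fits), `v` (rel/min), `se`, `n`, `populated`.
#' @export
compute_drift_profile <- function(ensemble, interval = NULL,
                                  bin_width = 0.05, min_count = 25,
                                  selection = "all", lag = 1,
                                  scheme = interval_scheme(),
                                  channel = "ori", post_split_start = 1) {
  steps <- compute_steps(ensemble, interval, lag = lag,
                         selection = selection, scheme = scheme,
                         channel = channel,
                         post_split_start = post_split_start)
  if (nrow(steps) == 0L) stop("no steps available for drift profile")
  dt <- attr(steps, "step_dt")
  bin <- floor(steps$x0 / bin_width)
  agg <- split(data.frame(dx = steps$dx, x0 = steps$x0), bin)
  bins <- as.integer(names(agg))
  o <- order(bins)
  bins <- bins[o]; agg <- agg[o]
  n <- vapply(agg, nrow, integer(1))
  v <- vapply(agg, function(z) mean(z$dx), numeric(1)) / dt
  se <- vapply(agg, function(z) if (nrow(z) > 1) sd(z$dx) / sqrt(nrow(z)) else NA_real_,
               numeric(1)) / dt
  # x_mean: occupancy-weighted mean start position per bin; the honest
  # abscissa for conditional-mean comparisons and slope fits (the bin
  # centre is biased wherever occupancy varies across the bin)
  out <- data.frame(x = (bins + 0.5) * bin_width,
                    x_mean = vapply(agg, function(z) mean(z$x0), numeric(1)),
                    v = v, se = se, n = n,
                    populated = n >= min_count)
  rownames(out) <- NULL
  if (!any(out$populated)) stop("insufficient occupancy: all bins under min_count")
  structure(out, class = c("drift_profile", "data.frame"),
            step_dt = dt, interval = interval, bin_width = bin_width,
            min_count = min_count, selection = selection)
}

#' Locate drift-field equilibria
#'
#' Finds zero crossings of v(x) between adjacent populated bins (linear
#' interpolation), estimates the local slope by a weighted linear fit
#' around each crossing, and classifies stability: a negative slope is a
#' restoring (stable) equilibrium, for which the spring relaxation time
#' tau = -delta_t / log(1 + slope * delta_t) is also reported (the
#' finite-sampling inversion of slope = -(1 - e^(-delta_t/tau))/delta_t).
#' No sign change is a valid result: an empty set.
#'
#' @param profile a `drift_profile`.
#' @param slope_window half-width (relative units) of the window used for
#'   the local slope fit; defaults to 3 bin widths.
#' @return data.frame with columns `x_eq`, `slope`, `slope_se`, `stable`,
#'   `tau` (min; NA for unstable equilibria).
#' @export
find_equilibria <- function(profile, slope_window = NULL) {
  p <- profile[profile$populated, , drop = FALSE]
  p$xm <- if ("x_mean" %in% names(p)) p$x_mean else p$x
  bw <- attr(profile, "bin_width")
  dt <- attr(profile, "step_dt")
  if (is.null(slope_window)) slope_window <- 3 * bw
  out <- data.frame(x_eq = numeric(), slope = numeric(),
                    slope_se = numeric(), stable = logical(),
                    tau = numeric())
  if (nrow(p) < 2L) return(out)
  for (i in seq_len(nrow(p) - 1L)) {
    adjacent <- abs(p$x[i + 1L] - p$x[i] - bw) < 1e-9
    if (!adjacent) next
    if (p$v[i] == 0 || sign(p$v[i]) == sign(p$v[i + 1L])) next
    x_star <- p$xm[i] + (p$xm[i + 1L] - p$xm[i]) * p$v[i] /
      (p$v[i] - p$v[i + 1L])
    w <- p[abs(p$x - x_star) <= slope_window + 1e-9, , drop = FALSE]
    slope <- NA_real_; slope_se <- NA_real_
    if (nrow(w) >= 2L) {
      wt <- ifelse(is.finite(w$se) & w$se > 0, 1 / w$se^2, 0)
      if (all(wt == 0)) wt <- rep(1, nrow(w))
      fit <- lm(v ~ xm, data = w, weights = wt)
      slope <- unname(coef(fit)[2])
      slope_se <- summary(fit)$coefficients[2, 2]
    }
    stable <- is.finite(slope) && slope < 0
    tau <- if (stable && 1 + slope * dt > 0) -dt / log1p(slope * dt) else NA_real_
    out <- rbind(out, data.frame(x_eq = x_star, slope = slope,
                                 slope_se = slope_se, stable = stable,
                                 tau = tau))
  }
  rownames(out) <- NULL
  out
}

#' Fit the spring relaxation time from a drift profile
#'
#' Weighted linear fit of v(x) in a window around a stable equilibrium.
#' The discrete-sampling drift of a spring with relaxation time tau is
#' v(x) = -(x - x_eq)(1 - e^(-delta_t/tau))/delta_t, so the fitted slope s
#' is inverted as tau = -delta_t / log(1 + s * delta_t) rather than the
#' naive -1/s (which overestimates the spring stiffness when delta_t is
#' not small against tau).  The SE of tau is propagated from the slope SE
#' by the delta method.
#'
#' @param profile a `drift_profile`.
#' @param around equilibrium position (relative units) to fit about.
#' @param window half-width of the fit window (relative units).
#' @return list with `tau`, `se_tau`, `slope`, `slope_se`, `n_bins`,
#'   `x_eq`.
#' @export
fit_relaxation_time <- function(profile, around = 0, window = 0.15) {
  p <- profile[profile$populated &
                 abs(profile$x - around) <= window + 1e-9, , drop = FALSE]
  if (nrow(p) < 3L) stop("fewer than 3 populated bins in the fit window")
  p$xm <- if ("x_mean" %in% names(p)) p$x_mean else p$x
  wt <- ifelse(is.finite(p$se) & p$se > 0, 1 / p$se^2, 0)
  if (all(wt == 0)) wt <- rep(1, nrow(p))
  fit <- lm(v ~ xm, data = p, weights = wt)
  s <- unname(coef(fit)[2])
  s_se <- summary(fit)$coefficients[2, 2]
  dt <- attr(profile, "step_dt")
  if (s >= 0) stop("not a restoring profile: non-negative slope")
  if (1 + s * dt <= 0) stop("slope too steep for the finite-sampling inversion")
  tau <- -dt / log1p(s * dt)
  dtau_ds <- dt^2 / ((1 + s * dt) * log1p(s * dt)^2)
  list(tau = tau, se_tau = abs(dtau_ds) * s_se, slope = s, slope_se = s_se,
       n_bins = nrow(p), x_eq = around)
}

#' Spatiotemporal occupancy map
#'
#' Per-time-bin histograms of locus position (each populated row normalized
#' to sum to 1), the mean trajectory, and a per-focus mode count as a
#' unimodality diagnostic: a single segregation pathway shows one mode per
#' focus at every time point.
#'
#' @param ensemble a synchronized [track_ensemble()].
#' @param time_bin time bin width (min).
#' @param pos_bin position bin width (relative units).
#' @param channel locus channel.
#' @param prominence a local maximum only counts as a separate mode if the
#'   valley between it and a higher mode drops below this fraction of its
#'   height.
#' @return an `occupancy_map`: list with `time` (bin centres), `pos` (bin
#'   centres), `occupancy` (time x position matrix), `mean_traj`, `n`
#'   (points per time bin) and `modes` (data.frame time, focus_id,
#'   n_modes).
#' @export
occupancy_map <- function(ensemble, time_bin = 5, pos_bin = 0.05,
                          channel = "ori", prominence = 0.5) {
  if (!ensemble$synchronized) stop("occupancy_map requires a synchronized ensemble")
  obs <- ensemble$obs[ensemble$obs$channel == channel, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observations in channel")
  tb <- floor(obs$t_min / time_bin)
  pb_breaks <- seq(-0.5, 0.5, by = pos_bin)
  pos_centers <- head(pb_breaks, -1L) + pos_bin / 2
  tbs <- sort(unique(tb))
  occ <- matrix(NA_real_, length(tbs), length(pos_centers))
  mean_traj <- numeric(length(tbs))
  n_row <- integer(length(tbs))
  modes <- data.frame(time = numeric(), focus_id = integer(),
                      n_modes = integer())
  for (i in seq_along(tbs)) {
    d <- obs[tb == tbs[i], , drop = FALSE]
    n_row[i] <- nrow(d)
    if (nrow(d) == 0L) next
    h <- hist_counts(d$x_rel, pb_breaks)
    occ[i, ] <- h / sum(h)
    mean_traj[i] <- mean(d$x_rel)
    for (f in sort(unique(d$focus_id))) {
      hf <- hist_counts(d$x_rel[d$focus_id == f], pb_breaks)
      modes <- rbind(modes, data.frame(
        time = (tbs[i] + 0.5) * time_bin, focus_id = f,
        n_modes = count_modes(hf, prominence)))
    }
  }
  structure(list(time = (tbs + 0.5) * time_bin, pos = pos_centers,
                 occupancy = occ, mean_traj = mean_traj, n = n_row,
                 modes = modes),
            class = "occupancy_map")
}

hist_counts <- function(x, breaks) {
  x <- x[x >= breaks[1] & x <= breaks[length(breaks)]]
  if (length(x) == 0L) return(integer(length(breaks) - 1L))
  tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                length(breaks) - 1L),
           nbins = length(breaks) - 1L)
}

# Count prominent modes in a histogram: smooth lightly, take local maxima,
# and merge a maximum into a higher neighbouring mode unless the valley
# between them drops below `prominence` times its height.
count_modes <- function(counts, prominence = 0.5) {
  if (sum(counts) == 0L) return(0L)
  v <- as.numeric(stats::filter(c(counts[1], counts, counts[length(counts)]),
                                c(1, 2, 1) / 4, sides = 2))
  v <- v[2:(length(v) - 1L)]
  n <- length(v)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) v[i - 1L] else -Inf
    right <- if (i < n) v[i + 1L] else -Inf
    v[i] > left && v[i] >= right && v[i] > 0
  }, logical(1))
  peaks <- which(is_max)
  if (length(peaks) <= 1L) return(length(peaks))
  o <- peaks[order(v[peaks], decreasing = TRUE)]
  kept <- o[1]
  for (p in o[-1]) {
    distinct <- TRUE
    for (q in kept) {
      valley <- min(v[seq(min(p, q), max(p, q))])
      if (valley > prominence * v[p]) { distinct <- FALSE; break }
    }
    if (distinct) kept <- c(kept, p)
  }
  length(kept)
}
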