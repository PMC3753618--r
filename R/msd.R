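#' Ensemble mean-squared displacement
#'
#' Computes the MSD curve of an ensemble within one cell-cycle interval,
#' using the combined time-and-ensemble average: for each lag, the mean of
#' (x(t + lag) - x(t))^2 over every track and every start time with both
#' endpoints inside the interval window.  Post-split windows that open at
#' t = 0 start at t = 1 min, the first frame at which two distinct foci can
#' be resolved.  Both daughter foci contribute; the MSD uses displacements,
#' so no mirroring is needed.
#'
#' @param ensemble a [track_ensemble()] (synchronized when `interval` is
#'   given; `interval = NULL` uses all frames).
#' @param interval interval label from `scheme`, or NULL.
#' @param max_lag largest lag, in minutes.
#' @param scheme an [interval_scheme()].
#' @param channel locus channel.
#' @param post_split_start first usable time (min) for windows opening at
#'   t = 0.
#' @return an `msd_curve`: data.frame with columns `lag` (min), `msd`
#'   ((relative units)^2) and `n_pairs`, carrying per-track sufficient
#'   statistics for trajectory bootstraps.
#' @export
compute_msd <- function(ensemble, interval = NULL, max_lag = 10,
                        scheme = interval_scheme(), channel = "ori",
                        post_split_start = 1) {
  series <- series_list(ensemble, interval, scheme, channel,
                        post_split_start)
  max_lag_fr <- as.integer(round(max_lag / ensemble$delta_t))
  stopifnot(max_lag_fr >= 1)
  n_s <- length(series)
  if (n_s == 0L || all(vapply(series, function(s) length(s$x), 1L) < 2L)) {
    warning("interval holds fewer than 2 frames per track; empty MSD curve")
    out <- data.frame(lag = numeric(), msd = numeric(), n_pairs = integer())
    return(structure(out, class = c("msd_curve", "data.frame"),
                     interval = interval, delta_t = ensemble$delta_t))
  }
  ss <- matrix(0, max_lag_fr, n_s)      # per-track sum of squared displ.
  np <- matrix(0L, max_lag_fr, n_s)
  for (j in seq_len(n_s)) {
    s <- series[[j]]
    for (l in seq_len(max_lag_fr)) {
      i2 <- match(s$idx + l, s$idx)
      ok <- !is.na(i2)
      if (!any(ok)) next
      d <- s$x[i2[ok]] - s$x[ok]
      ss[l, j] <- sum(d^2)
      np[l, j] <- sum(ok)
    }
  }
  n_pairs <- rowSums(np)
  msd <- ifelse(n_pairs > 0, rowSums(ss) / n_pairs, NA_real_)
  out <- data.frame(
    lag = c(0, seq_len(max_lag_fr) * ensemble$delta_t),
    msd = c(0, msd),
    n_pairs = c(sum(vapply(series, function(s) length(s$x), 1L)), n_pairs)
  )
  structure(out, class = c("msd_curve", "data.frame"),
            interval = interval, delta_t = ensemble$delta_t,
            track_ss = ss, track_n = np,
            track_cell = vapply(series, function(s) s$cell_id, character(1)))
}

#' Fit a power law to an MSD curve
#'
#' Least-squares line on log(msd) vs log(lag) over the fit range:
#' MSD(lag) = D_gen * lag^alpha, slope = alpha, intercept = log(D_gen).
#' alpha ~ 2 indicates processive motion, ~ 1 diffusive, < 1 sub-diffusive.
#' The standard error of alpha is estimated by a seeded bootstrap that
#' resamples whole trajectories (displacement pairs within a track are
#' dependent, so pair-level resampling would be anticonservative).
#'
#' @param curve an `msd_curve` from [compute_msd()].
#' @param lag_range numeric length-2: inclusive lag window (min) to fit.
#' @param n_boot trajectory-bootstrap replicates for `stderr_alpha`
#'   (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return a `power_law_fit`: list with `alpha`, `D_gen`, `stderr_alpha`,
#'   `lag_range`, `n_lags`.
#' @export
fit_power_law <- function(curve, lag_range = c(1, 10), n_boot = 1000,
                          seed = 1) {
  sel <- which(curve$lag >= lag_range[1] & curve$lag <= lag_range[2] &
                 curve$lag > 0 & is.finite(curve$msd) & curve$msd > 0 &
                 curve$n_pairs > 0)
  if (length(sel) < 3L) {
    stop("fewer than 3 positive-MSD lags in the fit range")
  }
  fit <- lm(log(curve$msd[sel]) ~ log(curve$lag[sel]))
  alpha <- unname(coef(fit)[2])
  d_gen <- unname(exp(coef(fit)[1]))

  stderr_alpha <- NA_real_
  ss <- attr(curve, "track_ss"); np <- attr(curve, "track_n")
  if (n_boot > 0 && !is.null(ss)) {
    # lag rows of the per-track matrices corresponding to `sel` (sel indexes
    # the curve including its lag-0 row)
    rows <- as.integer(round(curve$lag[sel] / attr(curve, "delta_t")))
    n_tr <- ncol(ss)
    set.seed(as.integer(seed))
    ab <- numeric(n_boot)
    log_lag <- log(curve$lag[sel])
    for (b in seq_len(n_boot)) {
      pick <- sample.int(n_tr, n_tr, replace = TRUE)
      m <- rowSums(ss[rows, pick, drop = FALSE]) /
        pmax(rowSums(np[rows, pick, drop = FALSE]), 1L)
      ok <- m > 0
      ab[b] <- if (sum(ok) >= 2L) {
        unname(coef(lm(log(m[ok]) ~ log_lag[ok]))[2])
      } else NA_real_
    }
    stderr_alpha <- sd(ab, na.rm = TRUE)
  }
  structure(list(alpha = alpha, D_gen = d_gen, stderr_alpha = stderr_alpha,
                 lag_range = lag_range, n_lags = length(sel)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.4f (se %.4f), D_gen = %.4g, lags %g-%g min\n",
              x$alpha, x$stderr_alpha, x$D_gen,
              x$lag_range[1], x$lag_range[2]))
  invisible(x)
}
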