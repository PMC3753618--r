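#' Frame-to-frame step ensemble
#'
#' Collects displacements dx = x(t + lag*delta_t) - x(t) for every start
#' time with both endpoints inside the interval window.  After the split,
#' the default selection keeps only the right-destined focus (so the
#' segregation bias has a definite sign); `"mirror"` pools the left focus
#' with negated positions (doubling n under left-right symmetry), `"all"`
#' keeps both foci as-is.
#'
#' @param ensemble a [track_ensemble()] (synchronized when `interval` is
#'   given; `interval = NULL` uses all frames).
#' @param interval interval label or NULL.
#' @param lag step length in frames (>= 1).
#' @param selection post-split focus rule: `"right"`, `"mirror"` or `"all"`.
#' @param scheme an [interval_scheme()].
#' @param channel locus channel.
#' @param post_split_start first usable time (min) for windows opening at 0.
#' @return a `step_ensemble`: data.frame with columns `cell_id`,
#'   `focus_id`, `t`, `x0` (start position) and `dx`; attributes record
#'   `step_dt` (min), interval and selection.
#' @export
compute_steps <- function(ensemble, interval = NULL, lag = 1,
                          selection = c("right", "mirror", "all"),
                          scheme = interval_scheme(), channel = "ori",
                          post_split_start = 1) {
  selection <- match.arg(selection)
  stopifnot(lag >= 1)
  series <- series_list(ensemble, interval, scheme, channel,
                        post_split_start)
  series <- apply_selection(series, selection,
                            split_cells = ensemble$splits$cell_id)
  parts <- lapply(series, function(s) {
    i2 <- match(s$idx + as.integer(lag), s$idx)
    ok <- !is.na(i2)
    if (!any(ok)) return(NULL)
    data.frame(cell_id = s$cell_id, focus_id = s$focus_id,
               t = s$t[ok], x0 = s$x[ok], dx = s$x[i2[ok]] - s$x[ok])
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- if (length(parts) > 0L) do.call(rbind, parts) else
    data.frame(cell_id = character(), focus_id = integer(),
               t = numeric(), x0 = numeric(), dx = numeric())
  if (nrow(out) == 0L) warning("step selection is empty")
  rownames(out) <- NULL
  structure(out, class = c("step_ensemble", "data.frame"),
            step_dt = lag * ensemble$delta_t, lag = as.integer(lag),
            interval = interval, selection = selection)
}

#' Summarize a step ensemble
#'
#' The two headline statistics of locus motion on the frame timescale: the
#' drift velocity v = <dx>/dt (mean step per unit time) and the effective
#' diffusion constant D_eff = var(dx)/(2 dt), plus the excess-tail fraction
#' relative to a moment-matched Gaussian and the lag-1 autocorrelation of
#' successive steps (viscoelastic memory; negative for sub-diffusive
#' motion).
#'
#' @param steps a `step_ensemble` from [compute_steps()].
#' @param threshold_sd tail cut (in s.d. units) passed to
#'   [gaussian_excess()]; the excess is NA when the sample is degenerate.
#' @return a `step_summary`: list with `v`, `se_v`, `D_eff`, `se_D_eff`,
#'   `n`, `excess_tail`, `acf1`, `step_dt`.
#' @export
summarize_steps <- function(steps, threshold_sd = 2.5) {
  n <- nrow(steps)
  if (n < 2L) stop("need at least 2 steps to summarize")
  dt <- attr(steps, "step_dt")
  v <- mean(steps$dx) / dt
  s2 <- var(steps$dx)
  d_eff <- s2 / (2 * dt)
  se_v <- sd(steps$dx) / sqrt(n) / dt
  se_d <- s2 * sqrt(2 / (n - 1)) / (2 * dt)   # normal-theory SE of variance
  excess <- if (s2 > 0) {
    suppressWarnings(
      gaussian_excess(steps, threshold_sd = threshold_sd, n_boot = 0)$excess)
  } else NA_real_
  acf1 <- step_acf1(steps, dt)
  structure(list(v = v, se_v = se_v, D_eff = d_eff, se_D_eff = se_d,
                 n = n, excess_tail = excess, acf1 = acf1, step_dt = dt),
            class = "step_summary")
}

#' @export
print.step_summary <- function(x, ...) {
  cat(sprintf(
    "<step_summary> n = %d, v = %.4g (se %.2g) rel/min, D_eff = %.4g rel^2/min, acf1 = %.3f\n",
    x$n, x$v, x$se_v, x$D_eff, if (is.na(x$acf1)) NA else x$acf1))
  invisible(x)
}

# lag-1 autocorrelation of successive steps within tracks: mean pair
# product over mean squared step (pair-count normalization, so edge steps
# that enter no pair do not attenuate the estimate)
step_acf1 <- function(steps, dt) {
  num <- 0; n_pairs <- 0L; den <- 0; n_steps <- 0L
  mu <- mean(steps$dx)
  for (d in split(steps, paste(steps$cell_id, steps$focus_id, sep = "\r"))) {
    d <- d[order(d$t), , drop = FALSE]
    s <- d$dx - mu
    den <- den + sum(s^2); n_steps <- n_steps + length(s)
    if (nrow(d) < 2L) next
    consec <- which(abs(diff(d$t) - dt) < 1e-9)
    if (length(consec) == 0L) next
    num <- num + sum(s[consec] * s[consec + 1L])
    n_pairs <- n_pairs + length(consec)
  }
  if (den > 0 && n_pairs > 0L) (num / n_pairs) / (den / n_steps) else NA_real_
}

#' Excess large-step fraction over the Gaussian null
#'
#' Compares the empirical fraction of steps beyond `threshold_sd` standard
#' deviations from the mean with the tail mass of a Gaussian having the
#' same mean and variance (the step-size distribution of a pure diffusion
#' model).  A positive excess means more large steps than diffusion
#' predicts.  Because no single cut is canonical, the maximum excess over
#' the 2, 2.5 and 3 s.d. cuts is also reported.
#'
#' @param steps a `step_ensemble` (or numeric vector of steps).
#' @param threshold_sd tail cut in s.d. units.
#' @param n_boot bootstrap replicates for a percentile confidence interval
#'   (0 disables).
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `excess`, `ci` (or NULL), `threshold_sd`,
#'   `excess_max_grid` (max over the 2/2.5/3 sd cuts), `n`.
#' @export
gaussian_excess <- function(steps, threshold_sd = 2.5, n_boot = 200,
                            conf = 0.95, seed = 1) {
  dx <- if (is.data.frame(steps)) steps$dx else as.numeric(steps)
  n <- length(dx)
  if (n < 200L) warning("fewer than 200 steps; tail bins are sparse")
  mu <- mean(dx); sigma <- sd(dx)
  if (!is.finite(sigma) || sigma == 0) stop("zero step variance")
  one_excess <- function(x, k) {
    mean(abs(x - mean(x)) > k * sd(x)) - 2 * pnorm(-k)
  }
  excess <- one_excess(dx, threshold_sd)
  grid <- vapply(c(2, 2.5, 3), function(k) one_excess(dx, k), numeric(1))
  ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    bs <- vapply(seq_len(n_boot), function(b) {
      one_excess(dx[sample.int(n, n, replace = TRUE)], threshold_sd)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(bs, c(a, 1 - a)))
  }
  list(excess = excess, ci = ci, threshold_sd = threshold_sd,
       excess_max_grid = max(grid), n = n)
}

#' Step autocorrelation function
#'
#' Normalized autocorrelation of within-track step sequences, pooled across
#' tracks: negative lag-1 values indicate anti-correlated (sub-diffusive,
#' viscoelastic) motion; for fractional Gaussian noise of exponent alpha
#' the lag-1 value is 2^(alpha-1) - 1.
#'
#' @param ensemble a [track_ensemble()].
#' @param interval interval label or NULL.
#' @param max_lag largest step lag (in steps) to report.
#' @param scheme,channel,post_split_start as in [compute_steps()].
#' @param selection post-split focus rule.
#' @return data.frame with columns `lag` (steps) and `acf` (lag 0 = 1).
#' @export
step_autocorrelation <- function(ensemble, interval = NULL, max_lag = 5,
                                 selection = "all",
                                 scheme = interval_scheme(),
                                 channel = "ori", post_split_start = 1) {
  steps <- compute_steps(ensemble, interval, lag = 1, selection = selection,
                         scheme = scheme, channel = channel,
                         post_split_start = post_split_start)
  if (nrow(steps) == 0L) stop("no steps in interval")
  dt <- attr(steps, "step_dt")
  mu <- mean(steps$dx)
  num <- numeric(max_lag); n_pairs <- integer(max_lag)
  den <- 0; n_steps <- 0L
  for (d in split(steps, paste(steps$cell_id, steps$focus_id, sep = "\r"))) {
    d <- d[order(d$t), , drop = FALSE]
    s <- d$dx - mu
    idx <- as.integer(round(d$t / dt))
    den <- den + sum(s^2); n_steps <- n_steps + length(s)
    for (h in seq_len(max_lag)) {
      j <- match(idx + h, idx)
      ok <- !is.na(j)
      if (any(ok)) {
        num[h] <- num[h] + sum(s[ok] * s[j[ok]])
        n_pairs[h] <- n_pairs[h] + sum(ok)
      }
    }
  }
  if (n_pairs[1] == 0L) stop("all tracks shorter than lag + 1 steps")
  # pair-count normalization against the mean squared step
  acf <- ifelse(n_pairs > 0L, (num / pmax(n_pairs, 1L)) / (den / n_steps),
                NA_real_)
  data.frame(lag = 0:max_lag, acf = c(1, acf))
}
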