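# Synthetic trajectory generators.  Three modes cover the statistical
# structure the analysis assumes: a white-noise Ornstein-Uhlenbeck spring
# (drift/relaxation-time ground truth), pure fractional Gaussian noise
# (MSD-exponent ground truth), and a full split-cycle model whose spring
# equilibrium jumps from mid-cell to the quarter-cell positions at the
# split.  A single white-noise process cannot reproduce both the restoring
# drift and the sub-diffusive MSD at once, hence the separate modes.

#' Simulation configuration for the split-cycle generator
#'
#' Parameters of the synthetic full-cell-cycle model.  Defaults emulate the
#' study conditions of a slow-growing bacterial population imaged once per
#' minute: ~120-min generation time, spring relaxation time 10 min,
#' equilibrium at mid-cell before the split and at the quarter-cell
#' positions (+/-0.25) after, split near mid-cycle.
#'
#' @param n_cells number of simulated cell cycles.
#' @param delta_t sampling interval (min).
#' @param generation_time cell-cycle duration (min).
#' @param t_split_mean,t_split_sd Gaussian split-time draw (min), truncated
#'   to the cell cycle.
#' @param tau spring relaxation time (min), > 0.
#' @param x_eq_post magnitude of the post-split equilibrium positions
#'   (relative units; 0.25 = quarter cell).
#' @param D diffusion constant of the fluctuating force, (relative
#'   units)^2/min.
#' @param d_epoch_factor multiplicative factor applied to D for steps whose
#'   time lies in \[-10, 10) min relative to the split (elevated
#'   fluctuations around replication/segregation); 1 = time-homogeneous.
#' @param noise `"white"` (memoryless) or `"fractional"` (fractional
#'   Gaussian noise of exponent `alpha` driving the spring update).
#' @param alpha MSD scaling exponent of the fractional noise (0 < alpha <= 2).
#' @param sigma_loc localization-noise s.d. added to reported positions
#'   (relative units); does not feed back into the dynamics.
#' @param include_fiducial also emit a fiducial-channel track (an
#'   independent spring centred at +0.2) so orientation is testable.
#' @param L0 birth length (um); lengths grow as L0 * 2^(t/generation_time).
#' @param seed integer RNG seed; identical configs give identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 400, delta_t = 1, generation_time = 120,
                       t_split_mean = 60, t_split_sd = 10,
                       tau = 10, x_eq_post = 0.25, D = 2.5e-4,
                       d_epoch_factor = 1,
                       noise = c("white", "fractional"), alpha = 0.74,
                       sigma_loc = 0.005, include_fiducial = TRUE,
                       L0 = 2.5, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(tau > 0, D >= 0, delta_t > 0, alpha > 0, alpha <= 2,
            n_cells >= 1, generation_time > 2 * delta_t, sigma_loc >= 0,
            d_epoch_factor > 0)
  structure(list(n_cells = n_cells, delta_t = delta_t,
                 generation_time = generation_time,
                 t_split_mean = t_split_mean, t_split_sd = t_split_sd,
                 tau = tau, x_eq_post = x_eq_post, D = D,
                 d_epoch_factor = d_epoch_factor, noise = noise,
                 alpha = alpha, sigma_loc = sigma_loc,
                 include_fiducial = include_fiducial, L0 = L0,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Fractional Gaussian noise: `n_tracks` columns of `n_steps` unit-variance
# increments of fractional Brownian motion with Hurst index H = alpha/2,
# sampled by Davies-Harte circulant embedding (falls back to a Cholesky
# factorization of the Toeplitz covariance when the embedding is not
# non-negative definite).  Returns a matrix with attribute "sampler".
fgn_matrix <- function(n_steps, n_tracks, alpha) {
  stopifnot(alpha > 0, alpha <= 2, n_steps >= 1)
  H <- alpha / 2
  k <- 0:n_steps
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  if (n_steps == 1L) {
    out <- matrix(rnorm(n_tracks), 1L, n_tracks)
    attr(out, "sampler") <- "direct"
    return(out)
  }
  m <- 2L * n_steps
  c_vec <- c(g[1:(n_steps + 1L)], g[n_steps:2])
  lambda <- Re(stats::fft(c_vec))
  if (min(lambda) < -1e-8 * max(abs(lambda))) {
    # embedding failed: exact Cholesky sampling
    Sigma <- g[abs(outer(seq_len(n_steps), seq_len(n_steps), "-")) + 1L]
    dim(Sigma) <- c(n_steps, n_steps)
    L <- chol(Sigma)
    out <- crossprod(L, matrix(rnorm(n_steps * n_tracks), n_steps, n_tracks))
    attr(out, "sampler") <- "cholesky"
    return(out)
  }
  lambda[lambda < 0] <- 0
  half <- n_steps                      # index m/2
  a <- matrix(0 + 0i, m, n_tracks)
  a[1, ] <- sqrt(lambda[1] / m) * rnorm(n_tracks)
  a[half + 1L, ] <- sqrt(lambda[half + 1L] / m) * rnorm(n_tracks)
  idx <- 2:half
  scale <- sqrt(lambda[idx] / (2 * m))
  re <- matrix(rnorm(length(idx) * n_tracks), length(idx), n_tracks)
  im <- matrix(rnorm(length(idx) * n_tracks), length(idx), n_tracks)
  a[idx, ] <- scale * (re + 1i * im)
  a[m + 2L - idx, ] <- Conj(a[idx, ])
  out <- Re(mvfft(a))[1:n_steps, , drop = FALSE]
  attr(out, "sampler") <- "davies-harte"
  out
}

#' Simulate fractional-Brownian-motion tracks
#'
#' Generates trajectories whose increments are stationary fractional
#' Gaussian noise, so the ensemble MSD follows the power law
#' MSD(lag) = 2 D lag^alpha exactly in expectation.  alpha < 1 gives
#' sub-diffusive (anti-correlated) motion with lag-1 increment
#' autocorrelation 2^(alpha-1) - 1; alpha = 1 is Brownian.
#'
#' @param alpha MSD scaling exponent, 0 < alpha <= 2.
#' @param D generalized diffusion constant ((relative units)^2/min^alpha).
#' @param n_tracks,n_frames ensemble dimensions.
#' @param delta_t sampling interval (min).
#' @param seed integer RNG seed.
#' @return a [track_ensemble()]; attribute `"sampler"` names the fGn
#'   sampler that ran (`"davies-harte"` or the `"cholesky"` fallback).
#' @export
simulate_fbm_tracks <- function(alpha, D = 2.5e-4, n_tracks = 400,
                                n_frames = 120, delta_t = 1, seed = 1) {
  stopifnot(alpha > 0, alpha <= 2, D >= 0, n_frames >= 2)
  set.seed(as.integer(seed))
  inc <- fgn_matrix(n_frames - 1L, n_tracks, alpha)
  sampler <- attr(inc, "sampler")
  inc <- inc * sqrt(2 * D * delta_t^alpha)
  x <- rbind(0, apply(inc, 2L, cumsum))
  t_abs <- (seq_len(n_frames) - 1L) * delta_t
  obs <- data.frame(
    cell_id = rep(sprintf("fbm%04d", seq_len(n_tracks)), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, n_tracks),
    t_min = rep(t_abs, n_tracks),
    channel = "ori",
    focus_id = 0L,
    x_rel = as.vector(x),
    cell_length_um = NA_real_
  )
  ens <- track_ensemble(obs, delta_t = delta_t)
  attr(ens, "sampler") <- sampler
  ens
}

#' Simulate stationary Ornstein-Uhlenbeck tracks
#'
#' A damped-spring (Hookean) locus model with white fluctuating force: the
#' position relaxes toward `x_eq` with time constant `tau` and fluctuates
#' with diffusion constant `D`.  Sampling uses the exact OU transition
#' density (conditional mean `x_eq + (x - x_eq) e^(-delta_t/tau)`, noise
#' variance `D tau (1 - e^(-2 delta_t/tau))`), so the stationary variance
#' is exactly `D tau` and the binned drift obeys
#' `v(x) = -(x - x_eq)(1 - e^(-delta_t/tau))/delta_t`.
#'
#' @param n_tracks,n_frames ensemble dimensions.
#' @param tau relaxation time (min), > 0.
#' @param D diffusion constant ((relative units)^2/min), >= 0.
#' @param x_eq equilibrium position (relative units).
#' @param x0 initial position; NULL draws from the stationary distribution.
#' @param delta_t sampling interval (min).
#' @param sigma_loc localization-noise s.d. added to reported positions.
#' @param seed integer RNG seed.
#' @return a [track_ensemble()] (single focus, no split).
#' @export
simulate_ou_tracks <- function(n_tracks = 400, n_frames = 100, tau = 10,
                               D = 2.5e-4, x_eq = 0, x0 = NULL,
                               delta_t = 1, sigma_loc = 0, seed = 1) {
  if (D < 0) stop("negative diffusion constant")
  stopifnot(tau > 0, n_frames >= 2)
  if (tau <= 2 * delta_t) {
    warning("tau <= 2 * delta_t: discrete sampling poorly resolves the spring")
  }
  set.seed(as.integer(seed))
  rho <- exp(-delta_t / tau)
  s_noise <- sqrt(D * tau * (1 - rho^2))
  s_stat <- sqrt(D * tau)
  x <- matrix(NA_real_, n_frames, n_tracks)
  x[1, ] <- if (is.null(x0)) rnorm(n_tracks, x_eq, s_stat) else x0
  for (k in 2:n_frames) {
    x[k, ] <- x_eq + (x[k - 1, ] - x_eq) * rho + s_noise * rnorm(n_tracks)
  }
  x_out <- x + if (sigma_loc > 0) {
    matrix(rnorm(n_frames * n_tracks, 0, sigma_loc), n_frames, n_tracks)
  } else 0
  t_abs <- (seq_len(n_frames) - 1L) * delta_t
  obs <- data.frame(
    cell_id = rep(sprintf("ou%04d", seq_len(n_tracks)), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, n_tracks),
    t_min = rep(t_abs, n_tracks),
    channel = "ori",
    focus_id = 0L,
    x_rel = as.vector(x_out),
    cell_length_um = NA_real_
  )
  track_ensemble(obs, delta_t = delta_t)
}

#' Simulate full split-cycle ensembles
#'
#' The complete synthetic cell cycle: a single focus fluctuates around
#' mid-cell under a damped spring; at a per-cell split time the track
#' branches into two daughters whose spring equilibria are the quarter-cell
#' positions -0.25 (left, focus id 0) and +0.25 (right, focus id 1).  The
#' diffusion constant may be elevated in the window \[-10, 10) min around
#' the split (`d_epoch_factor`), the fluctuating force may be white or
#' fractional, and localization noise is added to the reported positions
#' last.  Optionally a fiducial-channel spring track (home +0.2) is emitted
#' per cell for orientation.
#'
#' @param config a [sim_config()].
#' @return an unsynchronized [track_ensemble()] in absolute time; run
#'   [synchronize()] to set t = 0 at the split.
#' @export
simulate_split_cycle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt <- config$delta_t
  n_frames <- as.integer(round(config$generation_time / dt))
  t_abs <- (seq_len(n_frames) - 1L) * dt
  rho <- exp(-dt / config$tau)
  s_stat <- sqrt(config$D * config$tau)

  # step-noise s.d. for a step starting at absolute time t (D may be
  # elevated around the split)
  step_sd <- function(t, t_split) {
    D <- config$D
    rel <- t - t_split
    D <- ifelse(rel >= -10 & rel < 10, D * config$d_epoch_factor, D)
    sqrt(D * config$tau * (1 - rho^2))
  }

  draw_split <- function() {
    for (i in 1:100) {
      ts <- round(rnorm(1, config$t_split_mean, config$t_split_sd) / dt) * dt
      if (ts >= 2 * dt && ts <= config$generation_time - 2 * dt) return(ts)
    }
    stop("could not draw a split time inside the cell cycle")
  }

  # standardized (unit-variance) noise sequence of length n for one branch
  noise_seq <- function(n) {
    if (config$noise == "white") rnorm(n) else as.vector(fgn_matrix(n, 1L, config$alpha))
  }

  rows <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    cid <- sprintf("cell%04d", i)
    ts <- draw_split()
    k_split <- as.integer(round(ts / dt)) + 1L   # frame index of the split
    pre_idx <- seq_len(k_split - 1L)

    x0 <- if (config$D > 0) rnorm(1, 0, s_stat) else 0
    eps_pre <- noise_seq(k_split - 1L)
    x_pre <- numeric(k_split - 1L)
    x_pre[1] <- x0
    if (k_split > 2L) {
      for (k in 2:(k_split - 1L)) {
        x_pre[k] <- x_pre[k - 1] * rho +
          step_sd(t_abs[k - 1L], ts) * eps_pre[k - 1L]
      }
    }

    n_post <- n_frames - k_split + 1L
    x_last <- x_pre[k_split - 1L]
    daughters <- lapply(c(-1, 1), function(sgn) {
      xeq <- sgn * config$x_eq_post
      eps <- noise_seq(n_post)
      xd <- numeric(n_post)
      prev <- x_last
      for (k in seq_len(n_post)) {
        t_start <- t_abs[k_split + k - 2L]
        xd[k] <- xeq + (prev - xeq) * rho + step_sd(t_start, ts) * eps[k]
        prev <- xd[k]
      }
      xd
    })

    loc <- function(x) x + if (config$sigma_loc > 0) {
      rnorm(length(x), 0, config$sigma_loc)
    } else 0

    frames_pre <- pre_idx - 1L
    frames_post <- seq(k_split, n_frames) - 1L
    L <- config$L0 * 2^(t_abs / config$generation_time)
    cell_rows <- rbind(
      data.frame(cell_id = cid, frame = frames_pre, t_min = t_abs[pre_idx],
                 channel = "ori", focus_id = 0L, x_rel = loc(x_pre),
                 cell_length_um = L[pre_idx]),
      data.frame(cell_id = cid, frame = frames_post,
                 t_min = t_abs[k_split:n_frames],
                 channel = "ori", focus_id = 0L, x_rel = loc(daughters[[1]]),
                 cell_length_um = L[k_split:n_frames]),
      data.frame(cell_id = cid, frame = frames_post,
                 t_min = t_abs[k_split:n_frames],
                 channel = "ori", focus_id = 1L, x_rel = loc(daughters[[2]]),
                 cell_length_um = L[k_split:n_frames])
    )
    if (config$include_fiducial) {
      eps <- noise_seq(n_frames - 1L)
      xf <- numeric(n_frames)
      xf[1] <- 0.2 + (if (config$D > 0) rnorm(1, 0, s_stat) else 0)
      s_fid <- sqrt(config$D * config$tau * (1 - rho^2))
      for (k in 2:n_frames) {
        xf[k] <- 0.2 + (xf[k - 1] - 0.2) * rho + s_fid * eps[k - 1L]
      }
      cell_rows <- rbind(cell_rows,
        data.frame(cell_id = cid, frame = t_abs / dt, t_min = t_abs,
                   channel = "fid", focus_id = 0L, x_rel = loc(xf),
                   cell_length_um = L))
    }
    rows[[i]] <- cell_rows
  }
  track_ensemble(do.call(rbind, rows), delta_t = dt)
}
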