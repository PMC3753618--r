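# construct a drift_profile by hand (for closed-form checks)
fake_profile <- function(x, v, se = 1e-4, n = 1000L, bin_width = 0.05,
                         step_dt = 1) {
  structure(data.frame(x = x, x_mean = x, v = v, se = se, n = n,
                       populated = TRUE),
            class = c("drift_profile", "data.frame"),
            step_dt = step_dt, bin_width = bin_width, min_count = 25,
            interval = NULL, selection = "all")
}

test_that("a drift-free random walk has no significant drift in any bin", {
  ens <- simulate_fbm_tracks(1, D = 2.5e-4, n_tracks = 300, n_frames = 60,
                             seed = 33)
  dp <- compute_drift_profile(ens, NULL, bin_width = 0.05, min_count = 25)
  p <- dp[dp$populated, ]
  expect_gte(mean(abs(p$v) < 2 * p$se), 0.95)
})

test_that("OU drift profile matches the exact conditional mean", {
  dp <- compute_drift_profile(ou_ens(), NULL, bin_width = 0.05,
                              min_count = 25)
  p <- dp[dp$populated, ]
  # conditional mean at the bin's mean start position: -x (1 - e^(-dt/tau))
  expected <- -p$x_mean * (1 - exp(-0.1))
  expect_gte(mean(abs(p$v - expected) <= 2 * p$se), 0.95)
  # a bin near x = 0.2 shows the hand-computed restoring drift -0.0190
  i <- which.min(abs(p$x - 0.225))
  expect_equal(p$v[i], -p$x_mean[i] * (1 - exp(-0.1)),
               tolerance = 3 * p$se[i] / abs(p$v[i]))
  # negative slope overall: restoring
  expect_lt(coef(lm(p$v ~ p$x))[2], 0)
})

test_that("equilibria are found with correct stability classification", {
  # constructed unstable profile v = +x: crossing at 0, positive slope
  x <- seq(-0.2, 0.2, by = 0.05) + 0.025
  eq_unstable <- find_equilibria(fake_profile(x, x))
  expect_equal(nrow(eq_unstable), 1)
  expect_equal(eq_unstable$x_eq, 0, tolerance = 1e-10)
  expect_false(eq_unstable$stable)
  expect_true(is.na(eq_unstable$tau))

  # stable spring profile: discrete slope of tau = 10 inverts back exactly
  s10 <- -(1 - exp(-1 / 10))
  eq_stable <- find_equilibria(fake_profile(x, s10 * (x - 0.05)))
  expect_equal(eq_stable$x_eq, 0.05, tolerance = 1e-10)
  expect_true(eq_stable$stable)
  expect_equal(eq_stable$tau, 10, tolerance = 1e-6)

  # no sign change: a valid empty set
  expect_equal(nrow(find_equilibria(fake_profile(x, x + 1))), 0)
})

test_that("relaxation-time fitting inverts the finite-sampling slope", {
  x <- seq(-0.15, 0.15, by = 0.05) + 0.025
  s10 <- -(1 - exp(-1 / 10))
  fit <- fit_relaxation_time(fake_profile(x, s10 * x), around = 0)
  expect_equal(fit$tau, 10, tolerance = 1e-6)
  expect_error(fit_relaxation_time(fake_profile(x, 0.1 * x), around = 0),
               "not a restoring profile")
})

test_that("relaxation time is recovered from OU simulation within 15%", {
  dp <- compute_drift_profile(ou_ens(), NULL, bin_width = 0.05,
                              min_count = 25)
  fit <- fit_relaxation_time(dp, around = 0)
  expect_equal(fit$tau, 10, tolerance = 0.15)
  # halving the bin width moves tau by less than its combined SE scale
  dp2 <- compute_drift_profile(ou_ens(), NULL, bin_width = 0.025,
                               min_count = 25)
  fit2 <- fit_relaxation_time(dp2, around = 0)
  expect_lt(abs(fit2$tau - fit$tau),
            3 * sqrt(fit$se_tau^2 + fit2$se_tau^2) + 0.5)
})

test_that("split-cycle drift reproduces the equilibrium switch", {
  ens <- split_ens()
  eq_pre <- find_equilibria(compute_drift_profile(ens, "pre"))
  eq_pre <- eq_pre[eq_pre$stable, ]
  expect_equal(nrow(eq_pre), 1)
  expect_equal(eq_pre$x_eq, 0, tolerance = 0.03)

  eq_post <- find_equilibria(compute_drift_profile(ens, "post"))
  eq_post <- eq_post[eq_post$stable, ]
  expect_equal(nrow(eq_post), 2)
  expect_equal(sort(eq_post$x_eq), c(-0.25, 0.25), tolerance = 0.12)
  # equilibrium positions are robust to halving the bin width
  eq_post2 <- find_equilibria(compute_drift_profile(ens, "post",
                                                    bin_width = 0.025))
  eq_post2 <- eq_post2[eq_post2$stable, ]
  for (x0 in eq_post$x_eq) {
    expect_lt(min(abs(eq_post2$x_eq - x0)), 0.025)
  }
})

test_that("post-segregation drift is temporally stationary", {
  # split the post interval in half: binwise profile difference is noise
  ens <- split_ens()
  sch <- interval_scheme(names = c("post1", "post2"),
                         t_min = c(10, 35), t_max = c(35, Inf))
  d1 <- compute_drift_profile(ens, "post1", scheme = sch)
  d2 <- compute_drift_profile(ens, "post2", scheme = sch)
  shared <- intersect(round(d1$x[d1$populated], 6),
                      round(d2$x[d2$populated], 6))
  i1 <- match(shared, round(d1$x, 6)); i2 <- match(shared, round(d2$x, 6))
  z <- abs(d1$v[i1] - d2$v[i2]) / sqrt(d1$se[i1]^2 + d2$se[i2]^2)
  expect_gte(mean(z < 2.5), 0.95)
})

test_that("occupancy maps are normalized with a consistent mean trajectory", {
  # single static track: every row is a point mass in the bin holding 0.11
  ens <- toy_ensemble(list(a = rep(0.11, 30)), synchronized = TRUE)
  occ <- occupancy_map(ens, time_bin = 5, pos_bin = 0.05)
  expect_true(all(abs(rowSums(occ$occupancy) - 1) < 1e-12))
  expect_true(all(occ$occupancy[, which(abs(occ$pos - 0.125) < 1e-9)] == 1))
  expect_equal(occ$mean_traj, rep(0.11, length(occ$time)))
  expect_true(all(occ$modes$n_modes == 1L))

  # split-cycle: rows normalized; the pooled two-focus mean settles at
  # mid-cell once both daughters sit at the symmetric quarter positions
  occ2 <- occupancy_map(split_ens(), time_bin = 10, pos_bin = 0.05)
  ok <- occ2$n > 0
  expect_true(all(abs(rowSums(occ2$occupancy[ok, , drop = FALSE]) - 1) < 1e-9))
  late <- occ2$time > 30 & occ2$time < 60
  expect_equal(mean(abs(occ2$mean_traj[late])), 0, tolerance = 0.05)
})
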