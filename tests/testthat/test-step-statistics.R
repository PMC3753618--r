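test_that("steps are frame-to-frame displacements with the expected counts", {
  ens <- toy_ensemble(list(a = c(0, 0.1, 0.2)))
  st <- compute_steps(ens, NULL)
  expect_equal(st$dx, c(0.1, 0.1), tolerance = 1e-12)
  # lag 3 on a 5-frame track: exactly 2 valid start frames
  ens5 <- toy_ensemble(list(a = c(0, 0.1, 0.15, 0.3, 0.25)))
  st3 <- compute_steps(ens5, NULL, lag = 3)
  expect_equal(nrow(st3), 2)
  expect_equal(st3$dx, c(0.3 - 0, 0.25 - 0.1), tolerance = 1e-12)
  expect_equal(attr(st3, "step_dt"), 3)
})

test_that("step summaries recover drift and effective diffusion", {
  # deterministic drift: v = step/dt, zero variance
  ens <- toy_ensemble(list(a = 0.02 * (0:10)))
  s <- summarize_steps(compute_steps(ens, NULL))
  expect_equal(s$v, 0.02, tolerance = 1e-12)
  expect_equal(s$D_eff, 0, tolerance = 1e-15)
  expect_error(summarize_steps(compute_steps(toy_ensemble(list(a = c(0, 1e-3))), NULL)),
               "at least 2")

  # Gaussian steps with known variance: D_eff = sigma^2 / (2 dt)
  set.seed(4)
  sig2 <- 5e-4
  x <- cumsum(c(0, rnorm(20000, 0, sqrt(sig2))))
  s2 <- summarize_steps(compute_steps(toy_ensemble(list(a = x)), NULL))
  expect_equal(s2$D_eff, sig2 / 2, tolerance = 0.05)
  expect_equal(s2$acf1, 0, tolerance = 0.03)
})

test_that("D_eff matches the generator on Brownian input within 5%", {
  D <- 2.5e-4
  ens <- simulate_fbm_tracks(1, D = D, n_tracks = 200, n_frames = 60,
                             seed = 17)
  s <- summarize_steps(compute_steps(ens, NULL))
  expect_gte(s$n, 1e4)
  expect_equal(s$D_eff, D, tolerance = 0.05)
})

test_that("Gaussian excess is null on Gaussian steps and exact on a mixture", {
  set.seed(8)
  x <- cumsum(c(0, rnorm(20000)))
  st <- compute_steps(toy_ensemble(list(a = x / 100)), NULL)
  g <- gaussian_excess(st, threshold_sd = 2.5, n_boot = 200, seed = 1)
  expect_lte(g$ci[1], 0)
  expect_gte(g$ci[2], 0)
  expect_lt(abs(g$excess), 0.005)

  # 95/5 mixture with the contaminant at +/-4: closed-form expected excess.
  # Mixture sd = sqrt(0.95 + 0.05 * 16); every contaminant exceeds the
  # 2.5-sd cut, the Gaussian component contributes its own tail mass.
  set.seed(9)
  n <- 5e4
  big <- runif(n) < 0.05
  dx <- ifelse(big, sample(c(-4, 4), n, TRUE), rnorm(n))
  k <- 2.5
  sd_th <- sqrt(0.95 + 0.05 * 16)
  emp_th <- 0.95 * 2 * pnorm(-k * sd_th) + 0.05
  excess_th <- emp_th - 2 * pnorm(-k)
  g2 <- gaussian_excess(dx, threshold_sd = k, n_boot = 0)
  expect_equal(g2$excess, excess_th, tolerance = 0.15)
  expect_gt(g2$excess, 0.03)    # the 5% contaminant dominates the tail
  expect_error(gaussian_excess(rep(0.1, 300)), "zero step variance")
})

test_that("the excess estimator is unbiased over Gaussian replicates", {
  set.seed(12)
  reps <- vapply(1:50, function(r) {
    gaussian_excess(rnorm(2000), 2.5, n_boot = 0)$excess
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps)), 2 * se + 1e-4)
})

test_that("step autocorrelation matches closed forms for fGn and OU", {
  # white noise: no memory
  ens_w <- simulate_fbm_tracks(1, n_tracks = 200, n_frames = 60, seed = 23)
  expect_lt(abs(step_autocorrelation(ens_w, NULL, 1)$acf[2]), 0.02)
  # fGn at alpha = 0.38: 2^(alpha-1) - 1 = -0.3487
  ens_f <- simulate_fbm_tracks(0.38, n_tracks = 200, n_frames = 60, seed = 24)
  expect_lt(abs(step_autocorrelation(ens_f, NULL, 1)$acf[2] -
                  (2^(0.38 - 1) - 1)), 0.02)
  # OU increments: lag-1 correlation -(1 - e^(-dt/tau))/2
  ens_o <- simulate_ou_tracks(300, 120, tau = 10, D = 2.5e-4, seed = 25)
  expect_lt(abs(step_autocorrelation(ens_o, NULL, 1)$acf[2] -
                  (-(1 - exp(-1 / 10)) / 2)), 0.02)
  expect_error(step_autocorrelation(toy_ensemble(list(a = c(0, 0.1))), NULL, 1),
               "shorter than")
})

test_that("mirroring negates drift and preserves even statistics", {
  ens <- split_ens()
  st <- compute_steps(ens, "rapid", selection = "right")
  stm <- compute_steps(mirror_ensemble(ens), "rapid", selection = "right")
  s <- summarize_steps(st); sm <- summarize_steps(stm)
  # mirrored ensemble: the right-destined focus is now focus 0 moving left
  expect_equal(sm$v, -s$v, tolerance = 1e-12)
  expect_equal(sm$D_eff, s$D_eff, tolerance = 1e-12)
  expect_equal(sm$excess_tail, s$excess_tail, tolerance = 1e-12)
  expect_equal(sm$acf1, s$acf1, tolerance = 1e-12)
})

test_that("mirror-pooling matches right-only for a symmetric generator", {
  ens <- split_ens()
  v_right <- summarize_steps(compute_steps(ens, "rapid", selection = "right"))
  v_mirror <- summarize_steps(compute_steps(ens, "rapid", selection = "mirror"))
  expect_equal(v_mirror$n, 2 * v_right$n)
  expect_lt(abs(v_mirror$v - v_right$v),
            3 * sqrt(v_right$se_v^2 + v_mirror$se_v^2))
})
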