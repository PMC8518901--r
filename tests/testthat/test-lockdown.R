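test_that("policy construction enforces exactly one trigger kind", {
  expect_s3_class(lockdown_policy(trigger_fraction = 0.005, duration = 130,
                                  alpha = 0.5), "lockdown_policy")
  expect_error(lockdown_policy(), "exactly one")
  expect_error(lockdown_policy(trigger_fraction = 0.005, start_day = 10),
               "exactly one")
  expect_error(lockdown_policy(start_day = 10, duration = -5))
})

test_that("trigger fires by event detection at the cumulative-incidence crossing", {
  d <- named_degree_dist("delta-like")
  m <- hmf_model(d, 0.016, 1 / 14)
  pol <- lockdown_policy(trigger_fraction = 0.005, duration = 130, alpha = 0.5)
  run <- run_with_policy(m, pol)
  expect_true(run$fired)
  t0 <- run$window[1]
  expect_false(t0 == round(t0) && isTRUE(all.equal(t0, round(t0))))
  # cumulative incidence at the trigger equals the threshold
  cum_t0 <- stats::approx(run$trajectory$time, run$trajectory$cumulative,
                          t0)$y
  expect_equal(cum_t0 / m$N, 0.005, tolerance = 1e-4)
})

test_that("an unreachable threshold is reported as a no-lockdown run", {
  d <- named_degree_dist("delta-like")
  m <- hmf_model(d, 0.016, 1 / 14)
  pol <- lockdown_policy(trigger_fraction = 0.999, duration = 130, alpha = 0.5)
  run <- run_with_policy(m, pol)
  expect_false(run$fired)
  expect_true(all(is.na(run$window)))
})

test_that("alpha = 0 gives pure exponential decay during lockdown and a second wave", {
  d <- named_degree_dist("delta-like")
  m <- hmf_model(d, 0.016, 1 / 14)
  pol <- lockdown_policy(trigger_fraction = 0.005, duration = 60, alpha = 0)
  run <- run_with_policy(m, pol)
  tw <- run$trajectory[run$trajectory$time >= run$window[1] + 1 &
                       run$trajectory$time <= run$window[2], ]
  rate <- -stats::coef(stats::lm(log(prevalence) ~ time, tw))[2]
  expect_equal(unname(rate), 1 / 14, tolerance = 1e-4)
  sw <- detect_second_wave(run, N = m$N)
  expect_true(sw$second_wave)
  expect_gt(sw$post_peak, max(tw$prevalence))
})

test_that("second-wave detection: monotone tails are negative, completed epidemics too", {
  traj <- data.frame(time = 0:100,
                     prevalence = 1000 * exp(-0.05 * (0:100)),
                     cumulative = 5000)
  expect_false(detect_second_wave(traj, t_end_lockdown = 20, N = 1e5)$second_wave)
  expect_error(detect_second_wave(traj, t_end_lockdown = 150, N = 1e5),
               "extend")
  # alpha = 1 run past the peak is never flagged
  d <- named_degree_dist("delta-like")
  m <- hmf_model(d, 0.016, 1 / 14)
  run <- run_with_policy(m, lockdown_policy(trigger_fraction = 0.005,
                                            duration = 130, alpha = 1))
  expect_false(detect_second_wave(run, N = m$N)$second_wave)
})

test_that("optimal alpha balances second waves against weak control (Fig. 3 regime)", {
  d <- named_degree_dist("delta-like")
  m <- hmf_model(d, 0.016, 1 / 14)
  pol <- lockdown_policy(trigger_fraction = 0.005, duration = 130, alpha = 1)
  res <- optimal_alpha(m, pol)
  expect_false(is.na(res$alpha_star))
  expect_true(res$alpha_star > 0 && res$alpha_star < 1)
  expect_false(res$second_wave)
  scan <- res$scan
  # aggressive alphas on the grid produce second waves; weak ones do not
  expect_true(any(scan$second_wave))
  expect_true(scan$second_wave[scan$alpha == 0])
  expect_false(scan$second_wave[scan$alpha == 1])
  # DIHI <= final size <= free final size, and the scan preserves evaluations
  free_fs <- scan$final_size[scan$alpha == 1]
  expect_true(all(scan$dihi <= scan$final_size + 1e-9, na.rm = TRUE))
  expect_true(all(scan$final_size <= free_fs + 1e-9))
  expect_lte(res$dihi, res$final_size)
  # the chosen alpha minimises final size among subcritical evaluations
  sub <- scan[!scan$second_wave, ]
  expect_equal(res$final_size, min(sub$final_size), tolerance = 1e-12)
  # near-homogeneous network: DIHI close to the classical 1 - 1/R0
  R0 <- r0_hmf(0.016, 1 / 14, d)
  expect_equal(res$dihi, 1 - 1 / R0, tolerance = 0.02)
})

test_that("optimal alpha search is reproducible", {
  d <- named_degree_dist("delta-like")
  pol <- lockdown_policy(trigger_fraction = 0.005, duration = 130, alpha = 1)
  r1 <- optimal_alpha(hmf_model(d, 0.016, 1 / 14), pol)
  r2 <- optimal_alpha(hmf_model(d, 0.016, 1 / 14), pol)
  expect_identical(r1$alpha_star, r2$alpha_star)
  expect_identical(r1$dihi, r2$dihi)
})

test_that("a pre-lockdown subcritical epidemic returns alpha* = 1 with seed-level DIHI", {
  d <- named_degree_dist("delta-like")
  m <- hmf_model(d, 0.002, 1 / 14)  # R0 ~ 0.25
  pol <- lockdown_policy(trigger_fraction = 0.005, duration = 130, alpha = 1)
  res <- optimal_alpha(m, pol)
  expect_equal(res$alpha_star, 1)
  expect_lt(res$dihi, 1e-5)
})

test_that("pairwise DIHI is smaller than HMF DIHI at matched inputs", {
  d <- named_degree_dist("normal-like")
  pol <- lockdown_policy(trigger_fraction = 0.005, duration = 130, alpha = 1)
  res_h <- optimal_alpha(hmf_model(d, 0.016, 1 / 14), pol, step = 2)
  res_p <- optimal_alpha(pairwise_model(d, 0.016, 1 / 14, phi = 0), pol,
                         step = 2)
  expect_lt(res_p$dihi, res_h$dihi)
  expect_lt(res_p$final_size, res_h$final_size)
})

test_that("scenario grid: degenerate single cell equals optimal_alpha", {
  d <- negbin_for_moments(4, 7.5)
  p <- ebcm_params(0.045, 0.015, 1 / 14, d, rho = 1e-4)
  m <- ebcm_model(p)
  pol <- lockdown_policy(start_day = 60, duration = 200, alpha = 1,
                         target = "global")
  g <- scenario_grid(m, 60, 200, pol, step = 2)
  direct <- optimal_alpha(m, pol, step = 2)
  expect_equal(g$final_size[1, 1], direct$final_size, tolerance = 1e-10)
  expect_equal(g$alpha_star[1, 1], direct$alpha_star, tolerance = 1e-10)
  expect_true(g$constrained[1, 1])
})
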