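test_that("phase normalization divides by the phase maximum", {
  expect_equal(normalize_phase(c(40, 50, 45, 35, 30, 25)),
               c(0.8, 1.0, 0.9, 0.7, 0.6, 0.5))
  expect_equal(normalize_phase(c(7, 7, 7)), c(1, 1, 1))
  set.seed(3)
  x <- runif(6, 10, 90)
  nx <- normalize_phase(x)
  expect_equal(sum(nx == 1), 1)  # unique max here
  expect_true(all(nx > 0 & nx <= 1))
  expect_error(normalize_phase(c(40, -1, 30)), "positive")
  expect_error(normalize_phase(55), "at least 2")
})

test_that("subject curve is the per-stop mean of the five phase curves", {
  one <- c(1, 0.5); two <- c(1, 0.7); rest <- c(1, 0.6)
  expect_equal(subject_curve(list(one, two, rest, rest, rest)), c(1, 0.6))
  same <- c(0.9, 1, 0.8)
  expect_equal(subject_curve(list(same, same, same, same, same)), same)
  expect_error(subject_curve(list(c(1, 0.5), c(1, 0.5, 0.2))), "mismatched")
  expect_lte(max(subject_curve(list(c(1, .5), c(.5, 1), c(1, .5),
                                    c(.5, 1), c(1, .5)))), 1)
})

test_that("representative scale recovers exact proportionality", {
  cv <- c(0.8, 1, 0.9, 0.7, 0.6, 0.5)
  fit <- representative_scale(cv, 55 * cv)
  expect_equal(fit$scale, 55)
  expect_equal(fit$ssr, 0, tolerance = 1e-20)
  # lexicographic tie-break on the all-equal case: subset size 4 for n = 6
  expect_equal(fit$subset, 1:4)
  fit5 <- representative_scale(cv[1:5], 3 * cv[1:5])
  expect_equal(length(fit5$subset), 3)  # n = 5 -> majority of 3
})

test_that("majority-subset fitting rejects corrupted stops", {
  # n = 5, majority m = 3; corrupt floor(5/2) = 2 stops so one clean
  # majority subset remains; brute-force oracle over all subsets via lm
  cv <- c(0.7, 1, 0.85, 0.6, 0.5)
  raw <- 48 * cv
  raw[c(2, 4)] <- raw[c(2, 4)] * c(0.35, 2.4)
  fit <- representative_scale(cv, raw)
  oracle <- NULL
  for (S in combn(5, 3, simplify = FALSE)) {
    f <- lm(raw[S] ~ 0 + cv[S])
    ssr <- sum(residuals(f)^2)
    if (is.null(oracle) || ssr < oracle$ssr)
      oracle <- list(scale = unname(coef(f)), ssr = ssr, subset = S)
  }
  expect_equal(fit$scale, oracle$scale, tolerance = 1e-12)
  expect_equal(fit$subset, oracle$subset)
  expect_equal(fit$scale, 48, tolerance = 1e-12)  # clean subset wins
  expect_setequal(fit$subset, c(1, 3, 5))
})

test_that("fatigue rates are consecutive normalized scale drops per minute", {
  expect_equal(fatigue_rates(c(1.0, 0.9, 0.85, 0.82, 0.80)), c(10, 5, 3, 2))
  expect_equal(fatigue_rates(rep(4.2, 5)), c(0, 0, 0, 0))
  # negative declines (gains) are preserved
  expect_equal(fatigue_rates(c(1, 0.9, 0.95, 0.9, 0.9))[2], -5)
  expect_error(fatigue_rates(c(1, 0.9)), "5 phase")
})

test_that("the pipeline recovers sampled residual capacities exactly when noiseless", {
  spec <- synthetic_spec(group_params("hip extensors"), "hip", sigma = 0)
  ses <- generate_session(spec, 60, seed = 5)
  s <- process_torque_data(ses$data)
  ext <- s[s$direction == "extension", ]
  ext <- ext[order(ext$phase), ]
  expect_lt(max(abs(ext$strength_norm - ses$truth$phase_rc$extension)), 1e-6)
})

test_that("rescaling a session rescales scales and leaves rates unchanged", {
  spec <- synthetic_spec(group_params("knee flexors"), "knee", sigma = 0.03)
  ses <- generate_session(spec, 90, seed = 12)
  s1 <- process_torque_data(ses$data)
  scaled <- ses$data
  scaled$peak_torque_Nm <- scaled$peak_torque_Nm * 3.7
  s2 <- process_torque_data(scaled)
  expect_equal(s2$scale, s1$scale * 3.7, tolerance = 1e-12)
  expect_equal(s2$strength_norm, s1$strength_norm, tolerance = 1e-12)
  r1 <- session_fatigue_rates(s1); r2 <- session_fatigue_rates(s2)
  expect_equal(r2$rate, r1$rate, tolerance = 1e-10)
  # and identical reruns return identical subsets and scales
  s1b <- process_torque_data(ses$data)
  expect_identical(s1b$subset, s1$subset)
  expect_identical(s1b$scale, s1$scale)
})

test_that("torque datasets are validated with row-level diagnostics", {
  spec <- synthetic_spec(group_params("knee flexors"), "knee", sigma = 0)
  d <- generate_session(spec, 60, seed = 2)$data
  expect_error(validate_torque_data(d[, -7]), "missing column")
  bad <- d
  bad$peak_torque_Nm[13] <- -4
  expect_error(validate_torque_data(bad, on_invalid = "error"), "13")
  expect_warning(ok <- validate_torque_data(bad, on_invalid = "exclude"),
                 "13")
  # the artifact's stop is dropped from all 5 phases of its session so the
  # session keeps a common stop set
  expect_equal(nrow(ok), nrow(d) - 5)
  expect_no_error(process_torque_data(suppressWarnings(
    validate_torque_data(bad, on_invalid = "exclude"))))
  short <- d[d$phase != 5, ]
  expect_error(validate_torque_data(short), "phases 1..5")
})

test_that("velocity regression matches the normal-equations oracle", {
  # perfect line: slope recovered with a vanishing interval and p-value
  v <- c(30, 60, 90, 120, 150)
  perfect <- data.frame(velocity_deg_s = v, mean_rate = 0.001 * v + 0.02)
  vr <- velocity_regression(perfect)
  expect_equal(vr$slope, 0.001, tolerance = 1e-10)
  expect_lt(vr$p_value, 1e-10)
  expect_lt(vr$ci[2] - vr$ci[1], 1e-8)

  flat <- data.frame(velocity_deg_s = v, mean_rate = rep(2.5, 5))
  expect_equal(velocity_regression(flat)$slope, 0, tolerance = 1e-12)

  set.seed(8)
  noisy <- data.frame(velocity_deg_s = v, mean_rate = rnorm(5, 1, 0.3))
  vr2 <- velocity_regression(noisy)
  X <- cbind(1, v)
  beta <- solve(crossprod(X), crossprod(X, noisy$mean_rate))
  expect_equal(vr2$slope, beta[2], tolerance = 1e-12)
  expect_equal(vr2$intercept, beta[1], tolerance = 1e-12)

  expect_error(velocity_regression(perfect[1:2, ]), "3 distinct")
})

test_that("group rate tables aggregate sessions across participants", {
  spec <- synthetic_spec(group_params("knee extensors"), "knee",
                         sigma = 0.02)
  st <- generate_study(list(spec), participants = 3, seed = 4)
  s <- process_torque_data(st$data)
  rates <- session_fatigue_rates(s)
  tab <- fatigue_rate_table(rates)
  expect_equal(nrow(tab), 2 * 5 * 4)  # groups x velocities x iterations
  expect_true(all(tab$n == 3))
  reg <- velocity_regression_table(tab)
  expect_equal(nrow(reg), 2 * 4)
  # strength declines grow with velocity in this model, so slopes are
  # predominantly positive
  expect_gt(mean(reg$slope > 0), 0.5)
})
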