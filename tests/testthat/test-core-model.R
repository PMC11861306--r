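test_that("controller drive activates, deactivates and settles as demanded", {
  expect_equal(controller_drive(TL = 1, MA = 0, MR = 1, L = 20), 20)
  expect_equal(controller_drive(TL = 0, MA = 0.3, MR = 0.5, L = 20), -6)
  expect_equal(controller_drive(TL = 0.5, MA = 0.5, MR = 0.2, L = 20), 0)
  # limited by the resting pool, not the demand gap
  expect_equal(controller_drive(TL = 1, MA = 0.2, MR = 0.1, L = 20), 2)
  expect_error(controller_drive(1.2, 0, 1, 20), "TL")
  expect_error(controller_drive(0.5, 0, 1, L = 0), "positive")
})

test_that("controller drive is positive only with unmet demand and reserves", {
  set.seed(11)
  for (i in 1:200) {
    TL <- runif(1); MA <- runif(1); MR <- runif(1, 0, 1 - 0)
    C <- controller_drive(TL, MA, MR, 20)
    if (C > 0) expect_true(TL > MA && MR > 0)
    if (TL <= MA) expect_lte(C, 0)
  }
})

test_that("fatigue coefficients split central/peripheral flow by velocity", {
  p <- fatigue_parameters(FC0 = 0.00912, FP0 = 0.0145, RC0 = 0.00094,
                          RP0 = 1.2e-5, r = 7.5, k = 0.0233)
  at0 <- fatigue_coefficients(0, p)
  expect_equal(at0$FP, 0)          # isometric action: all fatigue central
  expect_equal(at0$FC, p$FC0)
  big <- fatigue_coefficients(1e6, p)
  expect_equal(big$FP, p$FP0)
  expect_equal(big$FC, 0)
  # exponential half-point: k * V = log(2)
  half <- fatigue_coefficients(log(2) / 0.0233, p)
  expect_equal(half$FP, p$FP0 / 2)
  expect_equal(half$FC, p$FC0 / 2)
  expect_error(fatigue_coefficients(-5, p), "concentric")
})

test_that("FP is non-decreasing and FC non-increasing in velocity", {
  p <- fatigue_parameters(FC0 = 0.01, FP0 = 0.02, RC0 = 0.001,
                          RP0 = 1e-5, r = 2, k = 0.03)
  v <- seq(0, 300, by = 1.5)
  fc <- fatigue_coefficients(v, p)
  expect_true(all(diff(fc$FP) >= 0))
  expect_true(all(diff(fc$FC) <= 0))
  expect_true(all(fc$FP <= p$FP0 & fc$FC <= p$FC0))
  # degenerate k = 0: no peripheral pathway at any velocity
  p0 <- fatigue_parameters(FC0 = 0.01, FP0 = 0.02, RC0 = 0.001,
                           RP0 = 1e-5, r = 2, k = 0)
  expect_equal(fatigue_coefficients(v, p0)$FP, rep(0, length(v)))
})

test_that("central recovery is boosted by r at rest, peripheral is constant", {
  p <- fatigue_parameters(FC0 = 0.01, FP0 = 0.02, RC0 = 0.02,
                          RP0 = 1.2e-5, r = 7.5, k = 0.01)
  expect_equal(recovery_coefficients(0, p)$RC, 0.15)
  expect_equal(recovery_coefficients(0.4, p)$RC, 0.02)
  expect_equal(recovery_coefficients(c(0, 0.4, 1), p)$RP, rep(1.2e-5, 3))
  # sensitivity switch flips the branch the multiplier applies to
  expect_equal(recovery_coefficients(0.4, p, r_at_rest = FALSE)$RC, 0.15)
  expect_equal(recovery_coefficients(0, p, r_at_rest = FALSE)$RC, 0.02)
})

test_that("negative k input is stored as magnitude", {
  expect_message(
    p <- fatigue_parameters(FC0 = 0.01, FP0 = 0.02, RC0 = 0.001,
                            RP0 = 1e-5, r = 2, k = -0.0233),
    "using \\|k\\|")
  expect_equal(p$k, 0.0233)
  fc <- fatigue_coefficients(100, p)
  expect_gt(fc$FP, 0)
  expect_lt(fc$FC, p$FC0)
})

test_that("compartment state enforces bounds and conservation", {
  s <- compartment_state()
  expect_equal(unname(sum(s)), 1)
  expect_error(compartment_state(0.5, 0.5, 0.2, -0.2), "\\[0, 1\\]")
  expect_error(compartment_state(0.5, 0.4, 0.2, 0.1), "sum to 1")
})

test_that("compartment derivatives match hand-evaluated flows", {
  # rates engineered so that FP = 0.01, FC = 0.005, RP = 1e-5, RC = 0.02
  # and C = 20 * min(0.6 - 0.5, 0.3) = 2 at the evaluation point
  p <- fatigue_parameters(FC0 = 0.01, FP0 = 0.02, RC0 = 0.02,
                          RP0 = 1e-5, r = 7.5, k = 0.01)
  st <- compartment_state(MA = 0.5, MR = 0.3, MFP = 0.1, MFC = 0.1)
  d <- compartment_derivatives(st, TL = 0.6, V = log(2) / 0.01, p)
  expect_equal(unname(d),
               c(1.9925, -1.997999, 0.004999, 0.0005), tolerance = 1e-12)
})

test_that("fully rested pool with no demand is an equilibrium", {
  p <- fatigue_parameters(FC0 = 0.01, FP0 = 0.02, RC0 = 0.001,
                          RP0 = 1e-5, r = 2, k = 0.02)
  d <- compartment_derivatives(compartment_state(), TL = 0, V = 0, p)
  expect_equal(unname(d), rep(0, 4))
})

test_that("motor units are conserved: derivatives sum to zero", {
  set.seed(42)
  for (i in 1:1000) {
    f <- sort(runif(3))
    st <- compartment_state(f[1], f[2] - f[1], f[3] - f[2], 1 - f[3])
    p <- fatigue_parameters(FC0 = runif(1, 0, 0.05), FP0 = runif(1, 0, 0.05),
                            RC0 = runif(1, 0, 0.01), RP0 = runif(1, 0, 1e-3),
                            r = runif(1, 1, 15), k = runif(1, 0, 0.1))
    d <- compartment_derivatives(st, TL = runif(1), V = runif(1, 0, 200), p)
    expect_lt(abs(sum(d)), 1e-13)
  }
})
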