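test_that("the torque-angle bell peaks at 1 and is symmetric", {
  expect_equal(torque_angle_shape(60, 60, 40), 1)
  expect_equal(torque_angle_shape(45, 60, 40), torque_angle_shape(75, 60, 40))
  expect_error(torque_angle_shape(120, 60, 40, rom_range = c(15, 90)),
               "range of motion")
  expect_error(torque_angle_shape(60, 60, 0), "width")
  # pinned regression fixture: bell(peak 60, width 40) at the knee stops
  expect_equal(torque_angle_shape(c(90, 75, 60, 45, 30, 15), 60, 40),
               c(0.56978282473092301, 0.86881505626284317, 1,
                 0.86881505626284317, 0.56978282473092301,
                 0.28206295169381546),
               tolerance = 1e-15)
})

test_that("synthetic sessions have the dynamometer record structure", {
  spec <- synthetic_spec(group_params("hip flexors"), "hip", sigma = 0.02)
  ses <- generate_session(spec, 45, participant = "P07", seed = 9)
  d <- ses$data
  expect_equal(nrow(d), 5 * 6 * 2)  # phases x stops x directions
  expect_setequal(unique(d$direction), c("flexion", "extension"))
  expect_true(all(d$peak_torque_Nm > 0))
  expect_silent(validate_torque_data(d))
  # ground-truth strengths decline over the session
  expect_true(all(diff(ses$truth$phase_rc$flexion) < 0))
  expect_equal(ses$truth$phase_rc$flexion[1], 1)  # rested at first MVIC
})

test_that("equal seeds reproduce sessions byte for byte", {
  spec <- synthetic_spec(group_params("knee flexors"), "knee", sigma = 0.05)
  a <- generate_session(spec, 120, seed = 31)
  b <- generate_session(spec, 120, seed = 31)
  expect_identical(a$data, b$data)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(a$data, f1, row.names = FALSE)
  write.csv(b$data, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  c_ <- generate_session(spec, 120, seed = 32)
  expect_false(identical(a$data, c_$data))
})

test_that("generation does not disturb the caller's RNG stream", {
  spec <- synthetic_spec(group_params("knee flexors"), "knee", sigma = 0.05)
  set.seed(77)
  x1 <- runif(1)
  set.seed(77)
  invisible(generate_session(spec, 60, seed = 5))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("empirical measurement noise converges to sigma", {
  spec <- synthetic_spec(group_params("knee extensors"), "knee",
                         sigma = 0.05)
  noiseless <- generate_session(
    synthetic_spec(group_params("knee extensors"), "knee", sigma = 0),
    90, seed = 1)$data
  reps <- vapply(1:300, function(s)
    generate_session(spec, 90, seed = s)$data$peak_torque_Nm[17] /
      noiseless$peak_torque_Nm[17], 0)
  expect_equal(sd(reps), 0.05, tolerance = 0.15)
  expect_equal(mean(reps), 1, tolerance = 0.01)
})

test_that("the full factorial study yields 200 strength distributions", {
  mg <- muscle_group_parameters()
  fx <- baseline_fixed()
  specs <- lapply(c("shoulder", "hip", "knee"), function(j) {
    rows <- mg[grep(j, mg$muscle_group), ]
    synthetic_spec(
      list(flexion = fatigue_parameters(fx$FC0, rows$FP0[1], fx$RC0,
                                        rows$RP0[1], fx$r, rows$k[1]),
           extension = fatigue_parameters(fx$FC0, rows$FP0[2], fx$RC0,
                                          rows$RP0[2], fx$r, rows$k[2])),
      j, sigma = 0.02)
  })
  # no calibrated elbow row exists; synthetic elbow ground truth
  specs <- c(specs, list(synthetic_spec(
    fatigue_parameters(fx$FC0, 0.01, fx$RC0, 1.5e-5, fx$r, 0.02),
    "elbow", sigma = 0.02)))
  st <- generate_study(specs, participants = 1, seed = 6)
  s <- process_torque_data(st$data)
  ds <- study_design_summary(s)
  expect_equal(ds$n_groups, 8)
  expect_equal(ds$strength_distributions, 8 * 5 * 5)
  expect_equal(ds$rate_cells, 8 * 5 * 4)
})

test_that("per-stop sampling mode reflects within-phase fatigue", {
  p <- group_params("hip extensors")
  phase_mode <- generate_session(synthetic_spec(p, "hip", sigma = 0), 60,
                                 seed = 1)
  stop_mode <- generate_session(
    synthetic_spec(p, "hip", sigma = 0, strength_sampling = "stop"), 60,
    seed = 1)
  d1 <- phase_mode$data[phase_mode$data$direction == "flexion", ]
  d2 <- stop_mode$data[stop_mode$data$direction == "flexion", ]
  # within a phase, constant-strength sampling keeps the ratio to the shape
  # constant; per-stop sampling declines across the phase's MVICs
  shape <- torque_angle_shape(d1$stop_deg[d1$phase == 1],
                              (90 + 0) / 2, 90 * 0.8)
  r1 <- d1$peak_torque_Nm[d1$phase == 1] / shape
  r2 <- d2$peak_torque_Nm[d2$phase == 1] / shape
  expect_lt(diff(range(r1)), 1e-9)
  expect_gt(diff(range(r2)), 1e-3)
})
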