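test_that("steady-state calibration hits the anchors and is idempotent", {
  p <- fx_params()
  cal <- calibrate_steady(p)
  hs <- solve_steady_state(cal, "healthy")
  expect_equal(hs$state[["x0"]], 1e4, tolerance = 0.02)
  expect_equal(hs$state[["x1"]], 1e10, tolerance = 0.02)
  expect_equal(hs$state[["a"]], 700, tolerance = 0.02)
  expect_equal(hs$state[["s"]], 3.61, tolerance = 0.02 / 3.61)  # 3.61 +/- 0.02
  ## parsimony ties preserved exactly
  expect_identical(cal$A_y, cal$A_x)
  expect_identical(cal$d_y0, cal$d_x0)
  ## fixed point: re-calibrating the calibrated set changes nothing
  cal2 <- calibrate_steady(cal)
  expect_equal(unclass(cal2)[1:19], unclass(cal)[1:19], tolerance = 1e-12)
  ## the shipped defaults are (a fixed point of) this calibration
  expect_equal(unclass(calibrate_steady(fx_params()))[1:19],
               unclass(fx_params())[1:19], tolerance = 1e-9)
  ## a perturbed structure is pulled back onto the anchors
  pert <- suppressWarnings(  # r_x * 1.3 transiently removes the advantage
    do.call(mpn_parameters,
            within(unclass(p), { r_x <- r_x * 1.3; e_a <- e_a * 2 })))
  cal3 <- calibrate_steady(pert)
  hs3 <- solve_steady_state(cal3, "healthy")
  expect_equal(hs3$state[["x0"]], 1e4, tolerance = 0.02)
  expect_equal(hs3$state[["s"]], 3.61, tolerance = 0.01)
})

test_that("equilibrium identities hold at the calibrated healthy state to 1e-9", {
  cal <- calibrate_steady(fx_params())
  st <- solve_steady_state(cal, "healthy")$state
  DI <- death_influx(st, cal)
  expect_equal(st[["a"]], DI / (cal$e_a * st[["s"]]), tolerance = 1e-9)
  expect_equal(st[["s"]], (cal$r_s * st[["a"]] + cal$I_base) / cal$e_s,
               tolerance = 1e-9)
  expect_gt(cal$r_y, cal$r_x)
})

test_that("timeline calibration responds monotonically and respects a no-op", {
  p <- fx_params()
  ## zero-weight timeline: no anchors, parameters unchanged
  none <- calibration_targets(burdens = numeric(0), years = numeric(0))
  expect_identical(unclass(calibrate_timeline(p, none))[1:19],
                   unclass(p)[1:19])
  ## doubling r_y after calibration strictly decreases all crossing times
  tt0 <- mpninflam:::.timeline_times(p, calibration_targets())
  p2 <- do.call(mpn_parameters, within(unclass(p), r_y <- r_y * 2))
  tt2 <- mpninflam:::.timeline_times(p2, calibration_targets())
  expect_true(all(tt2 < tt0))
})

test_that("timeline calibration is idempotent and recovers from a detuned start", {
  p <- fx_params()
  tt0 <- mpninflam:::.timeline_times(p, calibration_targets())
  ## idempotence: refitting the shipped optimum barely moves it
  again <- suppressWarnings(calibrate_timeline(p, maxit = 40))
  expect_equal(again$r_y, p$r_y, tolerance = 5e-3)
  expect_equal(again$r_m, p$r_m, tolerance = 5e-2)
  expect_lt(max(abs(attr(again, "achieved_years") - tt0)), 0.1)
  ## a detuned start converges back to the same structural optimum
  pert <- do.call(mpn_parameters,
                  within(unclass(p), {
                    r_y <- r_x + (r_y - r_x) * 1.15
                    r_m <- r_m * 3
                  }))
  refit <- suppressWarnings(calibrate_timeline(pert, maxit = 120))
  ach <- attr(refit, "achieved_years")
  expect_lt(max(abs(ach - tt0)), 0.3)
  expect_equal(attr(refit, "achieved_insult_shift"), 1, tolerance = 0.2)
  expect_gt(refit$r_y, refit$r_x)
})

test_that("parameters are recovered exactly from a noiseless trajectory", {
  p <- fx_params()
  spec <- synthetic_spec(p, sigma = 0, grid_years = seq(0, 30, by = 0.5))
  traj <- make_trajectory(spec)
  ## start the search away from the truth
  start <- do.call(mpn_parameters,
                   within(unclass(p), {
                     r_y <- r_x + (r_y - r_x) * 1.3
                     r_m <- r_m * 2
                   }))
  rec <- recover_parameters(traj, start, free = c("r_y", "r_m"))
  truth <- c(r_y = p$r_y, r_m = p$r_m)
  expect_lt(max(abs(rec$estimates - truth) / truth), 0.01)
  expect_true(all(rec$identifiable))
})

test_that("r_y is recovered within 10% median error from 5%-noise trajectories", {
  p <- fx_params()
  start <- do.call(mpn_parameters,
                   within(unclass(p), {
                     r_y <- r_x + (r_y - r_x) * 1.2
                     r_m <- r_m * 1.5
                   }))
  errs <- vapply(1:8, function(k) {
    spec <- synthetic_spec(p, sigma = 0.05, grid_years = seq(0, 28, by = 1),
                           seed = 200L + k)
    traj <- make_trajectory(spec)
    rec <- suppressWarnings(recover_parameters(traj, start,
                                               free = c("r_y", "r_m")))
    abs(rec$estimates[["r_y"]] - p$r_y) / p$r_y
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("r_y is flagged non-identifiable when the data contain no malignant cells", {
  p0 <- do.call(mpn_parameters, within(unclass(fx_params()), r_m <- 0))
  spec <- synthetic_spec(p0, sigma = 0, grid_years = seq(0, 10, by = 0.5),
                         mode = "first-insult")
  traj <- make_trajectory(spec)
  traj$y0 <- 0; traj$y1 <- 0  # a patient sample without a malignant clone
  rec <- recover_parameters(traj, p0, free = c("r_y"))
  expect_false(rec$identifiable[["r_y"]])
})
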