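test_that("the mutation-free healthy equilibrium persists over 50 years", {
  p0 <- do.call(mpn_parameters, within(unclass(fx_params()), r_m <- 0))
  hs <- solve_steady_state(p0, "healthy")$state
  traj <- simulate_mpn(p0, hs, span_years = 50, grid_dt_years = 0.5)
  for (cn in c("x0", "x1", "a", "s"))
    expect_lt(max(abs(traj[[cn]] - hs[[cn]]) / hs[[cn]]), 1e-6)
  expect_true(all(traj$y0 == 0) && all(traj$y1 == 0))
})

test_that("first-insult state is the healthy anchor state with one malignant cell", {
  st <- first_insult_state(fx_params())
  expect_identical(st[["y0"]], 1)
  expect_identical(st[["y1"]], 0)
  expect_equal(st[["x0"]], 1e4, tolerance = 0.02)
  expect_equal(st[["x1"]], 1e10, tolerance = 0.02)
  expect_equal(st[["a"]], 700, tolerance = 0.02)
  expect_equal(st[["s"]], 3.61, tolerance = 0.02)
  ## the single malignant cell perturbs the healthy turnover only weakly:
  ## |dx0| against the healthy stem turnover scale d_x1-free bound from rhs
  p0 <- do.call(mpn_parameters, within(unclass(fx_params()), r_m <- 0))
  d <- mpn_rhs(st, p0)
  turnover <- (p0$d_x0 + p0$a_x) * st[["x0"]]
  expect_lt(abs(d[["x0"]]) / turnover, 1e-3)
  expect_lt(abs(d[["x1"]]) / (p0$d_x1 * st[["x1"]]), 1e-3)
})

test_that("allele burden is the mature-cell ratio with its edge cases", {
  tr <- fx_insult()$trajectory
  expect_true(all(tr$allele_burden >= 0 & tr$allele_burden <= 1))
  ## arithmetic check on a constructed trajectory row
  fake <- tr[1:3, ]
  fake$x1 <- 3e9; fake$y1 <- 1e9
  class(fake) <- class(tr)
  expect_equal(allele_burden(fake), rep(0.25, 3))
  fake$y1 <- 0
  expect_equal(allele_burden(fake), rep(0, 3))
  fake$x1 <- 0
  expect_error(allele_burden(fake), "zero total mature")
})

test_that("crossing times interpolate linearly and report unreached thresholds", {
  tr <- fx_reference()$trajectory
  t7 <- crossing_time(tr, 0.07)
  b <- allele_burden(tr)
  i <- which(b >= 0.07)[1]
  expect_gte(t7, tr$time_years[i - 1])
  expect_lte(t7, tr$time_years[i])
  ## hand interpolation between the bracketing grid points
  lin <- tr$time_years[i - 1] + (0.07 - b[i - 1]) / (b[i] - b[i - 1]) *
    (tr$time_years[i] - tr$time_years[i - 1])
  expect_equal(t7, lin)
  expect_true(is.na(crossing_time(tr, 0.999999)))
})

test_that("crossing times are stable under solver-tolerance refinement", {
  p <- fx_params()
  hs <- fx_healthy()$state
  tr1 <- simulate_mpn(p, hs, 40, grid_dt_years = 1 / 36,
                      mode = "continuous-mutation")
  tr2 <- simulate_mpn(p, hs, 40, rtol = 0.5e-8,
                      atol = 0.5 * c(1e-6, 1e-2, 1e-6, 1e-2, 1e-6, 1e-9),
                      grid_dt_years = 1 / 36, mode = "continuous-mutation")
  for (b in c(0.07, 0.33, 0.67))
    expect_lt(abs(crossing_time(tr1, b) - crossing_time(tr2, b)), 0.01)
})

test_that("steady-state branches solve to anchors, stability and closed forms", {
  p <- fx_params()
  hs <- fx_healthy()
  expect_equal(hs$state[["x0"]], 1e4, tolerance = 0.02)
  expect_equal(hs$state[["x1"]], 1e10, tolerance = 0.02)
  ## healthy state invadable by the malignant clone (r_y > r_x)
  expect_identical(hs$stability, "unstable")
  fm <- solve_steady_state(p, "full-MPN")
  expect_gt(fm$state[["y1"]], hs$state[["x1"]])
  expect_identical(fm$stability, "stable")
  tv <- solve_steady_state(p, "trivial")
  expect_equal(tv$state[["s"]], p$I_base / p$e_s)
  expect_identical(tv$state[["a"]], 0)
  ## under equal niche coefficients the interior equilibrium is absent
  cx <- solve_steady_state(p, "coexistence")
  expect_identical(cx$kind, "branch absent")
})

test_that("malignant clone invades iff it holds the self-renewal advantage", {
  p <- fx_params()
  tr <- fx_insult()$trajectory
  w <- tr$time_years <= 10
  expect_gt(tr$y0[max(which(w))], tr$y0[1])  # grows from one cell
  ## exponential-phase growth rate matches the linearised prediction
  g_pred <- fx_healthy()$leading_eigenvalue * 365
  w5 <- tr$time_years >= 4 & tr$time_years <= 8
  g_emp <- stats::coef(stats::lm(log(tr$y0[w5]) ~ tr$time_years[w5]))[2]
  expect_equal(unname(g_emp), g_pred, tolerance = 0.02)
  ## without the advantage the clone dies out
  pna <- fx_params_no_advantage()
  st <- first_insult_state(pna)
  p0 <- mpninflam:::mpn_parameters_unchecked(
    mpninflam:::.p_modify(pna, r_m = 0))
  tr2 <- simulate_mpn(p0, st, 30, grid_dt_years = 0.5)
  expect_lt(tr2$y0[nrow(tr2)], 0.2)
})

test_that("disease course: monotone burden, mature cells track stem cells, MPN takeover", {
  p <- fx_params()
  tr <- fx_reference()$trajectory
  b <- allele_burden(tr)
  expect_true(all(diff(b) >= -1e-12))
  ## y1/y0 approaches a_y*A_y/d_y1 in the exponential phase (within 5%)
  w <- tr$time_years >= 10 & tr$time_years <= 20
  ratio <- tr$y1[w] / tr$y0[w]
  expect_lt(max(abs(ratio - p$a_y * p$A_y / p$d_y1)) / (p$a_y * p$A_y / p$d_y1),
            0.05)
  ## late state converges to the full-MPN equilibrium; healthy clone dies out
  fm <- solve_steady_state(p, "full-MPN")$state
  last <- unlist(tr[nrow(tr), c("y0", "y1", "a", "s")])
  expect_equal(unname(last), unname(fm[c("y0", "y1", "a", "s")]),
               tolerance = 0.02)
  expect_lt(tr$x1[nrow(tr)] / tr$x1[1], 0.01)
  ## d(x1)/dt sign agrees with the production-minus-death balance exactly
  mid <- unlist(tr[500, mpninflam:::.state_names])
  d <- mpn_rhs(mid, p)
  expect_identical(sign(d[["x1"]]),
                   sign(p$a_x * p$A_x * mid[["x0"]] - p$d_x1 * mid[["x1"]]))
})

test_that("first-insult times follow the healthy-state Poisson intensity", {
  p <- fx_params()
  ## r_m = 0: no insult, ever
  p0 <- do.call(mpn_parameters, within(unclass(p), r_m <- 0))
  expect_true(all(is.na(sample_first_insult_time(p0, n = 5, seed = 1))))
  ## constant intensity: mean of many draws matches 1/lambda within 3 SE
  hs <- fx_healthy()$state
  lambda <- p$r_m * hs[["s"]] * hs[["x0"]] * 365  # per year
  n <- 1e4
  draws <- sample_first_insult_time(p, n = n, horizon_years = Inf, seed = 7)
  expect_equal(mean(draws), 1 / lambda, tolerance = 3 / sqrt(n))
  ## doubled stimulus brings insults stochastically earlier
  draws2 <- sample_first_insult_time(p, n = n, horizon_years = Inf,
                                     stimulus = 2 * p$I_base, seed = 7)
  expect_lt(mean(draws2), mean(draws))
  q <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(quantile(draws2, q) < quantile(draws, q)))
})

test_that("schedule discontinuities restart the integration cleanly", {
  p <- fx_params()
  hs <- fx_healthy()$state
  sched <- stimulus_schedule(c(2, 6), c(4, 8), c(14, 3.5), base_level = 7)
  tr <- simulate_mpn(p, hs, 10, schedule = sched, grid_dt_years = 1 / 73)
  expect_true(all(unlist(tr[mpninflam:::.state_names]) >= 0))
  ## s rises promptly after the step up at year 2, falls after year 4
  s_at <- function(t) tr$s[which.min(abs(tr$time_years - t))]
  expect_gt(s_at(2.5), 1.2 * s_at(1.9))
  expect_lt(s_at(5.9), s_at(3.9))
  expect_lt(s_at(6.5), s_at(5.9))
})
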