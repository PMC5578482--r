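test_that("stage anchors sit at the healthy state and the PV/PMF crossings", {
  tr <- fx_reference()$trajectory
  anch <- anchor_levels(tr)
  expect_equal(anch$times[["Normal"]], 0)
  expect_equal(anch$times[["PV"]], crossing_time(tr, 0.33))
  expect_equal(anch$times[["PMF"]], crossing_time(tr, 0.67))
  expect_equal(anch$s[["Normal"]], 3.61, tolerance = 0.005)
  ## inflammation rises towards the MPN level along the disease course
  expect_true(all(diff(anch$s) > 0))
  expect_equal(anch$s[["PMF"]], 3.66, tolerance = 0.01)
  expect_equal(anch$DI[["Normal"]],
               death_influx(unlist(tr[1, mpninflam:::.state_names]), fx_params()),
               tolerance = 1e-6)
  ## a trajectory that never reaches the crossings is an error
  early <- tr[tr$time_years <= 5, ]
  class(early) <- class(tr)
  expect_error(anchor_levels(early), "does not reach")
})

test_that("exactly linear tables are recovered exactly; anchors must differ", {
  anch <- list(s = c(Normal = 3.61, PV = 3.63, PMF = 3.66),
               DI = c(Normal = 1e10, PV = 1.01e10, PMF = 1.03e10))
  tab <- biomarker_table(c("A", "B", "LDH"),
                         Normal = c(2 * 3.61 + 1, 5 * 3.61 + 2, 1e-8 * 1e10 + 3),
                         PV = c(2 * 3.63 + 1, 5 * 3.63 + 2, 1e-8 * 1.01e10 + 3),
                         PMF = c(2 * 3.66 + 1, 5 * 3.66 + 2, 1e-8 * 1.03e10 + 3))
  maps <- fit_linear_map(tab, anch)
  expect_equal(maps$slope, c(2, 5, 1e-8), tolerance = 1e-9)
  expect_equal(maps$intercept, c(1, 2, 3), tolerance = 1e-9)
  expect_lt(max(maps$max_rel_residual), 1e-9)
  expect_identical(maps$predictor, c("s", "s", "DI"))
  degenerate <- list(s = c(Normal = 3.61, PV = 3.61, PMF = 3.61), DI = anch$DI)
  expect_error(fit_linear_map(tab[1, ], degenerate), "identical anchors")
})

test_that("least-squares residuals are orthogonal to the design and affine-invariant", {
  anch <- list(s = c(Normal = 3.61, PV = 3.628, PMF = 3.645),
               DI = c(Normal = 1e10, PV = 1.01e10, PMF = 1.03e10))
  tab <- biomarker_table("X", Normal = 10, PV = 14, PMF = 13)
  maps <- fit_linear_map(tab, anch)
  res <- as.numeric(maps[1, c("resid_Normal", "resid_PV", "resid_PMF")])
  expect_lt(abs(sum(res)), 1e-10 * max(abs(res)))
  expect_lt(abs(sum(res * anch$s)), 1e-10 * max(abs(res * anch$s)))
  ## unit rescaling rescales coefficients and leaves relative residuals alone
  tab2 <- biomarker_table("X", Normal = 1000, PV = 1400, PMF = 1300)
  maps2 <- fit_linear_map(tab2, anch)
  expect_equal(maps2$slope, 100 * maps$slope)
  expect_equal(maps2$intercept, 100 * maps$intercept)
  expect_equal(maps2[, c("rel_Normal", "rel_PV", "rel_PMF")],
               maps[, c("rel_Normal", "rel_PV", "rel_PMF")], tolerance = 1e-12)
})

test_that("noisy linear panels recover slopes within 10% in the median", {
  ## anchors spanning a healthy-to-advanced inflammatory range
  anch <- list(s = c(Normal = 1, PV = 2, PMF = 3), DI = NULL)
  slope <- 40; intercept <- 10
  set.seed(3)
  err <- replicate(100, {
    truth <- slope * anch$s + intercept
    obs <- truth * stats::rlnorm(3, 0, 0.05)
    tab <- biomarker_table("IL-8", obs[1], obs[2], obs[3])
    abs(fit_linear_map(tab, anch)$slope - slope) / slope
  })
  expect_lt(stats::median(err), 0.10)
})

test_that("the shipped synthetic panel singles out IL-6 as the least linear biomarker", {
  tab <- read_biomarker_table(system.file("extdata",
                                          "biomarker_medians_synthetic.tsv",
                                          package = "mpninflam"))
  expect_s3_class(tab, "biomarker_table")
  expect_setequal(tab$biomarker,
                  c("IL-1b", "IL-1RA", "IL-2R", "IL-6", "IL-8", "IL-10",
                    "IL-12", "CRP", "LDH"))
  anch <- anchor_levels(fx_reference()$trajectory)
  maps <- fit_linear_map(tab, anch)
  expect_identical(maps$biomarker[which.max(maps$max_rel_residual)], "IL-6")
  ## the panel as a whole is well predicted: nothing exceeds the 25% flag
  val <- validate_panel(maps, tab)
  expect_length(val$flagged, 0)
})

test_that("a deliberately nonlinear biomarker is flagged, and only it", {
  anch <- anchor_levels(fx_reference()$trajectory)
  spec <- synthetic_spec(fx_params(), sigma = 0)
  truth <- spec$biomarker_truth
  truth$nonlinear[truth$biomarker == "IL-6"] <- 1  # linearise IL-6
  truth$nonlinear[truth$biomarker == "IL-8"] <- 2  # bend IL-8 far off the line
  spec2 <- synthetic_spec(fx_params(), sigma = 0, biomarker_truth = truth)
  tab <- make_biomarker_table(spec2, anch)
  maps <- fit_linear_map(tab, anch)
  val <- validate_panel(maps, tab)
  expect_identical(val$flagged, "IL-8")
  ## and a perfectly linear panel yields no flags at all
  truth$nonlinear[] <- 1
  tab0 <- make_biomarker_table(synthetic_spec(fx_params(), sigma = 0,
                                              biomarker_truth = truth), anch)
  val0 <- validate_panel(fit_linear_map(tab0, anch), tab0)
  expect_length(val0$flagged, 0)
})
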