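## Shared fixtures, computed once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_params <- function() {
  if (is.null(.fx$params)) .fx$params <- default_parameters()
  .fx$params
}

fx_healthy <- function() {
  if (is.null(.fx$healthy))
    .fx$healthy <- solve_steady_state(fx_params(), "healthy")
  .fx$healthy
}

## continuous-mutation reference run from the healthy steady state
fx_reference <- function() {
  if (is.null(.fx$reference))
    .fx$reference <- run_scenario(fx_params(),
                                  stimulus_schedule(base_level = fx_params()$I_base),
                                  mode = "continuous-mutation",
                                  span_years = 60, label = "reference")
  .fx$reference
}

## first-insult run (r_m = 0, one malignant stem cell)
fx_insult <- function() {
  if (is.null(.fx$insult))
    .fx$insult <- run_scenario(fx_params(),
                               stimulus_schedule(base_level = fx_params()$I_base),
                               mode = "first-insult",
                               span_years = 60, label = "first-insult")
  .fx$insult
}

## canonical five-scenario suite (continuous-mutation mode)
fx_suite <- function() {
  if (is.null(.fx$suite)) .fx$suite <- scenario_suite(fx_params())
  .fx$suite
}

## a small counterfactual parameter set without malignant advantage
fx_params_no_advantage <- function() {
  p <- fx_params()
  suppressWarnings(mpn_parameters(
    r_x = p$r_x, r_y = p$r_x * 0.98, a_x = p$a_x, a_y = p$a_y,
    A_x = p$A_x, A_y = p$A_y, d_x0 = p$d_x0, d_y0 = p$d_y0,
    d_x1 = p$d_x1, d_y1 = p$d_y1, r_m = p$r_m,
    c_xx = p$c_xx, c_xy = p$c_xy, c_yx = p$c_yx, c_yy = p$c_yy,
    r_s = p$r_s, e_s = p$e_s, e_a = p$e_a, I_base = p$I_base))
}
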