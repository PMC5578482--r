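## Integration of the model over decadal horizons, derived series, crossing
## times, steady states and stability.

DAYS_PER_YEAR <- 365

## default solver tolerances: the system is stiff (mature-cell turnover and
## dead-cell clearance act on hour scales against a decadal horizon)
.default_rtol <- 1e-8
.default_atol <- c(1e-6, 1e-2, 1e-6, 1e-2, 1e-6, 1e-9)

## internal: build the trajectory data frame with derived series
.as_trajectory <- function(out, params, schedule, mode = "custom") {
  df <- data.frame(
    time_years = out[, 1] / DAYS_PER_YEAR,
    x0 = out[, 2], x1 = out[, 3], y0 = out[, 4],
    y1 = out[, 5], a = out[, 6], s = out[, 7]
  )
  tot <- df$x1 + df$y1
  df$allele_burden <- ifelse(tot > 0, df$y1 / tot, NA_real_)
  df$total_mature <- tot
  df$death_influx <- params$d_x0 * df$x0 + params$d_x1 * df$x1 +
    params$d_y0 * df$y0 + params$d_y1 * df$y1
  structure(df, class = c("mpn_trajectory", "data.frame"),
            params = params, schedule = schedule, mode = mode)
}

#' Integrate the inflammation-MPN model
#'
#' Stiff-capable adaptive integration (`deSolve::lsoda` with the analytic
#' Jacobian) of the six-compartment system under a piecewise-constant
#' exogenous load. Schedule discontinuities are integration restart points.
#' Tiny negative excursions (below `-1e-6` relative to the compartment
#' scale they would be an error) are clipped to zero.
#'
#' @param params an [mpn_parameters()] object.
#' @param initial numeric length-6 initial state `(x0, x1, y0, y1, a, s)`.
#' @param span_years integration horizon (years, > 0).
#' @param schedule a [stimulus_schedule()]; default: constant `I_base`.
#' @param rtol,atol relative/absolute solver tolerances; `atol` may be a
#'   length-6 vector (cells for the five cell-type compartments, pg/ml for s).
#' @param grid_dt_years output grid spacing (years); default monthly.
#' @param mode label stored on the trajectory (`"continuous-mutation"`,
#'   `"first-insult"` or `"custom"`).
#' @return An `mpn_trajectory`: a data frame with columns `time_years`,
#'   the six compartments, `allele_burden` (`y1/(x1+y1)`), `total_mature`
#'   (`x1+y1`) and `death_influx`.
#' @export
simulate_mpn <- function(params, initial, span_years,
                         schedule = stimulus_schedule(base_level = params$I_base),
                         rtol = .default_rtol, atol = .default_atol,
                         grid_dt_years = 1 / 12, mode = "custom") {
  stopifnot(span_years > 0)
  init <- .check_state(initial)
  p <- unclass(params)
  breaks <- .schedule_breaks(schedule, span_years)
  segs <- vector("list", length(breaks) - 1L)
  st <- unname(init)
  for (k in seq_len(length(breaks) - 1L)) {
    lev <- schedule_level(schedule, breaks[k])
    tt <- seq(breaks[k], breaks[k + 1L], by = grid_dt_years) * DAYS_PER_YEAR
    if (utils::tail(tt, 1L) < breaks[k + 1L] * DAYS_PER_YEAR - 1e-9)
      tt <- c(tt, breaks[k + 1L] * DAYS_PER_YEAR)
    out <- deSolve::lsoda(st, tt, .rhs_desolve, parms = list(p = p, I = lev),
                          jacfunc = .jac_desolve, jactype = "fullusr",
                          rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("solver failed to converge in [%g, %g] years; last valid time %.4f years",
                   breaks[k], breaks[k + 1L], out[nrow(out), 1] / DAYS_PER_YEAR))
    states <- out[, -1, drop = FALSE]
    scale <- pmax(abs(init), 1)
    if (any(sweep(states, 2, scale, "/") < -1e-6))
      stop("solution went significantly negative; tighten tolerances")
    states[states < 0] <- 0
    out[, -1] <- states
    st <- unname(out[nrow(out), -1])
    segs[[k]] <- if (k == 1L) out else out[-1L, , drop = FALSE]
  }
  .as_trajectory(do.call(rbind, segs), params, schedule, mode)
}

#' JAK2 allele burden of a trajectory
#'
#' The ratio of MPN mature cells to all mature cells, `y1/(x1+y1)`.
#'
#' @param traj an `mpn_trajectory`.
#' @return Numeric series in `[0, 1]`.
#' @export
allele_burden <- function(traj) {
  stopifnot(inherits(traj, "mpn_trajectory"))
  tot <- traj$x1 + traj$y1
  if (any(tot <= 0))
    stop("allele burden undefined: zero total mature cells at some grid point")
  traj$y1 / tot
}

#' First crossing time of an allele-burden threshold
#'
#' Linearly interpolated between the bracketing grid points of the solved
#' trajectory.
#'
#' @param traj an `mpn_trajectory`.
#' @param threshold allele-burden fraction in (0, 1).
#' @return Crossing time in years, or `NA_real_` if the threshold is never
#'   reached on the grid.
#' @export
crossing_time <- function(traj, threshold) {
  stopifnot(inherits(traj, "mpn_trajectory"),
            threshold > 0, threshold < 1)
  b <- allele_burden(traj)
  i <- which(b >= threshold)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(traj$time_years[1L])
  t0 <- traj$time_years[i - 1L]; t1 <- traj$time_years[i]
  b0 <- b[i - 1L]; b1 <- b[i]
  t0 + (threshold - b0) / (b1 - b0) * (t1 - t0)
}

#' Healthy steady state with one malignant stem cell (first insult)
#'
#' The initial condition of first-insult runs: the healthy steady state of
#' the mutation-free system with `y0 = 1`, `y1 = 0`. Intended for use with
#' `r_m = 0`.
#'
#' @param params an [mpn_parameters()] object.
#' @param stimulus exogenous load (pg/ml/day); default `params$I_base`.
#' @return Named numeric length-6 state vector.
#' @export
first_insult_state <- function(params, stimulus = params$I_base) {
  ss <- solve_steady_state(params, branch = "healthy", stimulus = stimulus)
  if (is.null(ss$state)) stop("no healthy steady state exists for these parameters")
  st <- ss$state
  st[["y0"]] <- 1
  st[["y1"]] <- 0
  st
}

## ---- steady states ----------------------------------------------------

## internal: healthy (y = 0) or full-MPN (x = 0) equilibrium by 1-D
## reduction to a root problem in s. With the clone's stem cells z0 and
## D = d0 + a0 the nullclines give
##   1 + c*z0 = r*s/D  (mutation-free clone equation)
##   z1 = a0*A*z0/d1;  a = DI/(e_a*s);  e_s*s = r_s*a + I
## which collapse to a single increasing/decreasing balance in s.
.branch_equilibrium <- function(params, stimulus, clone = c("x", "y")) {
  clone <- match.arg(clone)
  p <- unclass(params)
  if (clone == "x") {
    r <- p$r_x; D <- p$d_x0 + p$a_x; cc <- p$c_xx
    a0 <- p$a_x; A <- p$A_x; d0 <- p$d_x0; d1 <- p$d_x1
  } else {
    r <- p$r_y; D <- p$d_y0 + p$a_y; cc <- p$c_yy
    a0 <- p$a_y; A <- p$A_y; d0 <- p$d_y0; d1 <- p$d_y1
  }
  z0_of_s <- function(s) (r * s / D - 1) / cc
  resid <- function(s) {
    z0 <- max(z0_of_s(s), 0)
    DI <- (d0 + a0 * A) * z0
    a <- DI / (p$e_a * s)
    p$r_s * a + stimulus - p$e_s * s
  }
  s_min <- D / r * (1 + 1e-12)      # smallest s with z0 > 0
  s_triv <- stimulus / p$e_s        # s of the empty-marrow state
  if (s_min >= s_triv * 50) return(NULL)  # no positive branch anywhere sensible
  lo <- max(s_min, 1e-12)
  hi <- max(s_triv * 50, lo * 10)
  if (resid(lo) <= 0) return(NULL)  # even at onset the balance cannot close
  root <- tryCatch(stats::uniroot(resid, c(lo, hi), tol = 1e-14)$root,
                   error = function(e) NULL)
  if (is.null(root)) return(NULL)
  z0 <- z0_of_s(root)
  if (z0 <= 0) return(NULL)
  z1 <- a0 * A * z0 / d1
  a <- (d0 + a0 * A) * z0 / (p$e_a * root)
  if (clone == "x") c(x0 = z0, x1 = z1, y0 = 0, y1 = 0, a = a, s = root)
  else              c(x0 = 0, x1 = 0, y0 = z0, y1 = z1, a = a, s = root)
}

## internal: damped Newton refinement of an equilibrium (full 6-D system),
## with r_m forced to zero so that branch equilibria are exact
.newton_refine <- function(state, params, stimulus, maxit = 60) {
  p0 <- .p_modify(params, r_m = 0)
  st <- unname(state)
  scale <- pmax(abs(st), 1)
  for (it in seq_len(maxit)) {
    f <- unname(.rhs_desolve(0, st, list(p = p0, I = stimulus))[[1]])
    if (max(abs(f / scale)) < 1e-13) break
    J <- .jac_desolve(0, st, list(p = p0, I = stimulus))
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- st + lam * step
      if (all(cand[c(1, 3)] >= 0) || lam < 1e-6) break
      lam <- lam / 2
    }
    st <- pmax(st + lam * step, 0)
  }
  stats::setNames(st, .state_names)
}

#' Solve for a steady state of the model on a given branch
#'
#' Branch equilibria of the mutation-free system (`r_m = 0`): `healthy`
#' (no malignant cells), `full-MPN` (no healthy cells), `trivial` (marrow
#' empty) or `coexistence` (both clones present; generically absent under
#' equal niche coefficients and is then reported as such). Roots are found
#' by 1-D reduction of the nullclines plus damped Newton refinement;
#' coexistence is additionally seeded by long integration. Stability is
#' classified from the eigenvalues of a central-difference Jacobian of the
#' full system (including the mutation term as parameterised).
#'
#' @param params an [mpn_parameters()] object.
#' @param branch one of `"healthy"`, `"full-MPN"`, `"coexistence"`,
#'   `"trivial"`.
#' @param stimulus exogenous load (pg/ml/day); default `params$I_base`.
#' @return An object of class `mpn_steady_state`: list with `state` (named
#'   vector, or `NULL` if the branch is absent), `kind`, `stability`
#'   (`"stable"`/`"unstable"`), `leading_eigenvalue` (largest real part,
#'   /day) and `residual` (max |rhs| component relative to compartment
#'   scale). Absence of a root on the branch is a result
#'   (`state = NULL`, `kind = "branch absent"`), not an error.
#' @export
solve_steady_state <- function(params,
                               branch = c("healthy", "full-MPN",
                                          "coexistence", "trivial"),
                               stimulus = params$I_base) {
  branch <- match.arg(branch)
  p <- unclass(params)
  st <- switch(branch,
    "trivial" = c(x0 = 0, x1 = 0, y0 = 0, y1 = 0, a = 0,
                  s = stimulus / p$e_s),
    "healthy" = .branch_equilibrium(params, stimulus, "x"),
    "full-MPN" = .branch_equilibrium(params, stimulus, "y"),
    "coexistence" = {
      ## seed by long integration from a mixed state, then Newton
      seed_h <- .branch_equilibrium(params, stimulus, "x")
      if (is.null(seed_h)) NULL else {
        init <- seed_h
        init[["y0"]] <- max(seed_h[["x0"]] / 2, 1)
        init[["y1"]] <- init[["y0"]] * p$a_y * p$A_y / p$d_y1
        traj <- simulate_mpn(mpn_parameters_unchecked(.p_modify(params, r_m = 0)),
                             init, span_years = 200,
                             schedule = stimulus_schedule(base_level = stimulus),
                             grid_dt_years = 1)
        cand <- .newton_refine(unlist(traj[nrow(traj), 2:7]), params, stimulus)
        if (cand[["x0"]] > 1e-3 && cand[["y0"]] > 1e-3) cand else NULL
      }
    })
  if (!is.null(st) && branch != "trivial")
    st <- .newton_refine(st, params, stimulus)
  if (is.null(st))
    return(structure(list(state = NULL, kind = "branch absent",
                          stability = NA_character_,
                          leading_eigenvalue = NA_real_, residual = NA_real_),
                     class = "mpn_steady_state"))
  p0 <- .p_modify(params, r_m = 0)
  f <- unname(.rhs_desolve(0, unname(st), list(p = p0, I = stimulus))[[1]])
  resid <- max(abs(f) / pmax(abs(unname(st)), 1))
  ev <- eigen(numeric_jacobian(st, params, stimulus), only.values = TRUE)$values
  lead <- max(Re(ev))
  structure(list(state = st, kind = branch,
                 stability = if (lead < 1e-12) "stable" else "unstable",
                 leading_eigenvalue = lead, residual = resid),
            class = "mpn_steady_state")
}

## internal constructor bypassing validation warnings (keeps attributes)
mpn_parameters_unchecked <- function(p) {
  structure(p[.param_fields], class = "mpn_parameters", parsimony = FALSE)
}

#' @export
print.mpn_steady_state <- function(x, ...) {
  cat("<mpn_steady_state>", x$kind, "\n")
  if (!is.null(x$state)) {
    print(signif(x$state, 6))
    cat(sprintf("  %s (leading eigenvalue %.3e /day), residual %.2e\n",
                x$stability, x$leading_eigenvalue, x$residual))
  }
  invisible(x)
}

#' Central-difference Jacobian of the model
#'
#' Numerical Jacobian used for stability classification (step
#' `1e-6 * max(1, |component|)` per the package's numerical conventions);
#' the analytic [mpn_jacobian()] is used by the integrator.
#'
#' @inheritParams mpn_rhs
#' @return A 6x6 matrix (/day).
#' @export
numeric_jacobian <- function(state, params, stimulus = params$I_base) {
  st <- unname(.check_state(state))
  p <- unclass(params)
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  for (j in 1:6) {
    h <- 1e-6 * max(1, abs(st[j]))
    up <- st; up[j] <- st[j] + h
    dn <- st; dn[j] <- max(st[j] - h, 0)
    fu <- unname(.rhs_desolve(0, up, list(p = p, I = stimulus))[[1]])
    fd <- unname(.rhs_desolve(0, dn, list(p = p, I = stimulus))[[1]])
    J[, j] <- (fu - fd) / (up[j] - dn[j])
  }
  J
}

#' Sample the time of the first malignant mutation
#'
#' Draws first-arrival times of the inhomogeneous Poisson process with
#' intensity `r_m * s(t) * x0(t)` evaluated along the healthy trajectory
#' (mutation-free dynamics from the supplied initial state, which defaults
#' to the healthy steady state and is then constant). Inversion sampling on
#' the integrated hazard.
#'
#' @param params an [mpn_parameters()] object.
#' @param n number of draws.
#' @param horizon_years hazard integration horizon; draws beyond it are
#'   censored to `NA`.
#' @param stimulus exogenous load (pg/ml/day).
#' @param seed optional integer seed (local RNG, global state restored).
#' @return Numeric vector of first-insult times (years); `NA` where the
#'   horizon is exceeded; all `NA` if the intensity is zero (`r_m = 0`).
#' @export
sample_first_insult_time <- function(params, n = 1L, horizon_years = 1000,
                                     stimulus = params$I_base, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  p <- unclass(params)
  if (p$r_m == 0) return(rep(NA_real_, n))
  hs <- solve_steady_state(params, "healthy", stimulus)
  if (is.null(hs$state)) stop("no healthy steady state exists for these parameters")
  ## healthy state is an equilibrium of the r_m = 0 dynamics: intensity is
  ## constant in time; keep the integrated-hazard formulation for clarity
  lambda_day <- p$r_m * hs$state[["s"]] * hs$state[["x0"]]
  lambda_yr <- lambda_day * DAYS_PER_YEAR
  u <- stats::rexp(n, rate = 1)
  t_years <- u / lambda_yr
  t_years[t_years > horizon_years] <- NA_real_
  t_years
}
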