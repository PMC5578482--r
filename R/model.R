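#' Bone-marrow niche crowding factor
#'
#' Density-dependent down-modulation of stem-cell self-renewal by marrow
#' occupancy: `1 / (1 + c_a*x0 + c_b*y0)`. Equals 1 for an empty niche and
#' decreases strictly in each stem-cell count.
#'
#' @param x0,y0 healthy and malignant stem-cell counts (cells, >= 0).
#' @param c_a,c_b niche inhibition coefficients (/cell, >= 0).
#' @return A dimensionless factor in (0, 1].
#' @export
niche_multiplier <- function(x0, y0, c_a, c_b) {
  if (any(!is.finite(c(x0, y0, c_a, c_b))))
    stop("non-finite input to niche_multiplier")
  if (any(c(x0, y0) < 0)) stop("negative stem-cell count")
  if (any(c(c_a, c_b) < 0)) stop("negative niche coefficient")
  1 / (1 + c_a * x0 + c_b * y0)
}

## internal: state vector layout
.state_names <- c("x0", "x1", "y0", "y1", "a", "s")

.check_state <- function(state) {
  if (length(state) != 6L) stop("state must have 6 components (x0, x1, y0, y1, a, s)")
  if (any(!is.finite(state))) stop("non-finite state component")
  if (any(state < 0)) stop("negative state component")
  stats::setNames(as.numeric(state), .state_names)
}

#' Right-hand side of the inflammation-MPN ODE system
#'
#' The six coupled balance equations. Both clones self-renew at a rate
#' proportional to the inflammatory level `s` and damped by the niche
#' crowding factor; healthy stem cells additionally lose the mutation flux
#' `r_m*s*x0`, which enters the malignant stem-cell pool. Mature cells are
#' produced at the differentiation rate times the progenitor amplification
#' factor. Dying cells of all four compartments feed the dead-cell debris
#' `a`, which is cleared by the second-order process `e_a*a*s` and
#' up-regulates the inflammatory level, itself eliminated at rate `e_s` and
#' driven by the exogenous stimulus.
#'
#' @param state numeric length-6 state `(x0, x1, y0, y1, a, s)`, nonnegative.
#' @param params an [mpn_parameters()] object (or plain named list with the
#'   same fields).
#' @param stimulus exogenous inflammatory load (pg/ml/day, >= 0); defaults
#'   to `params$I_base`.
#' @return Named numeric vector of the six time derivatives (per day).
#' @export
mpn_rhs <- function(state, params, stimulus = params$I_base) {
  st <- .check_state(state)
  if (!is.finite(stimulus) || stimulus < 0) stop("stimulus must be finite and >= 0")
  p <- unclass(params)
  x0 <- st[["x0"]]; x1 <- st[["x1"]]; y0 <- st[["y0"]]
  y1 <- st[["y1"]]; a <- st[["a"]]; s <- st[["s"]]
  phi_x <- 1 / (1 + p$c_xx * x0 + p$c_xy * y0)
  phi_y <- 1 / (1 + p$c_yx * x0 + p$c_yy * y0)
  c(x0 = (p$r_x * phi_x * s - p$d_x0 - p$a_x - p$r_m * s) * x0,
    x1 = p$a_x * p$A_x * x0 - p$d_x1 * x1,
    y0 = (p$r_y * phi_y * s - p$d_y0 - p$a_y) * y0 + p$r_m * s * x0,
    y1 = p$a_y * p$A_y * y0 - p$d_y1 * y1,
    a  = p$d_x0 * x0 + p$d_y0 * y0 + p$d_x1 * x1 + p$d_y1 * y1 - p$e_a * a * s,
    s  = p$r_s * a - p$e_s * s + stimulus)
}

#' Total rate of dying cells (death influx, DI)
#'
#' `DI = d_x0*x0 + d_x1*x1 + d_y0*y0 + d_y1*y1`, the model's proxy for the
#' clinically measured LDH level.
#'
#' @inheritParams mpn_rhs
#' @return Cells per day.
#' @export
death_influx <- function(state, params) {
  st <- .check_state(state)
  p <- unclass(params)
  p$d_x0 * st[["x0"]] + p$d_x1 * st[["x1"]] +
    p$d_y0 * st[["y0"]] + p$d_y1 * st[["y1"]]
}

#' Analytic Jacobian of the model right-hand side
#'
#' Used by the stiff integrator and available for stability analysis.
#'
#' @inheritParams mpn_rhs
#' @return A 6x6 numeric matrix, rows/columns ordered `(x0, x1, y0, y1, a, s)`.
#' @export
mpn_jacobian <- function(state, params, stimulus = params$I_base) {
  st <- .check_state(state)
  p <- unclass(params)
  x0 <- st[["x0"]]; y0 <- st[["y0"]]; a <- st[["a"]]; s <- st[["s"]]
  phi_x <- 1 / (1 + p$c_xx * x0 + p$c_xy * y0)
  phi_y <- 1 / (1 + p$c_yx * x0 + p$c_yy * y0)
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  J["x0", "x0"] <- p$r_x * s * phi_x^2 * (1 + p$c_xy * y0) -
    (p$d_x0 + p$a_x + p$r_m * s)
  J["x0", "y0"] <- -p$r_x * s * x0 * p$c_xy * phi_x^2
  J["x0", "s"]  <- (p$r_x * phi_x - p$r_m) * x0
  J["x1", "x0"] <- p$a_x * p$A_x
  J["x1", "x1"] <- -p$d_x1
  J["y0", "x0"] <- -p$r_y * s * y0 * p$c_yx * phi_y^2 + p$r_m * s
  J["y0", "y0"] <- p$r_y * s * phi_y^2 * (1 + p$c_yx * x0) - (p$d_y0 + p$a_y)
  J["y0", "s"]  <- p$r_y * phi_y * y0 + p$r_m * x0
  J["y1", "y0"] <- p$a_y * p$A_y
  J["y1", "y1"] <- -p$d_y1
  J["a", "x0"] <- p$d_x0
  J["a", "x1"] <- p$d_x1
  J["a", "y0"] <- p$d_y0
  J["a", "y1"] <- p$d_y1
  J["a", "a"]  <- -p$e_a * s
  J["a", "s"]  <- -p$e_a * a
  J["s", "a"]  <- p$r_s
  J["s", "s"]  <- -p$e_s
  J
}

## internal: unchecked RHS in deSolve signature (fast path; the integrator
## may probe slightly negative excursions that the public mpn_rhs rejects)
.rhs_desolve <- function(t, y, parms) {
  p <- parms$p
  x0 <- y[1]; x1 <- y[2]; y0 <- y[3]; y1 <- y[4]; a <- y[5]; s <- y[6]
  phi_x <- 1 / (1 + p$c_xx * x0 + p$c_xy * y0)
  phi_y <- 1 / (1 + p$c_yx * x0 + p$c_yy * y0)
  list(c((p$r_x * phi_x * s - p$d_x0 - p$a_x - p$r_m * s) * x0,
         p$a_x * p$A_x * x0 - p$d_x1 * x1,
         (p$r_y * phi_y * s - p$d_y0 - p$a_y) * y0 + p$r_m * s * x0,
         p$a_y * p$A_y * y0 - p$d_y1 * y1,
         p$d_x0 * x0 + p$d_y0 * y0 + p$d_x1 * x1 + p$d_y1 * y1 - p$e_a * a * s,
         p$r_s * a - p$e_s * s + parms$I))
}

.jac_desolve <- function(t, y, parms) {
  p <- parms$p
  x0 <- y[1]; y0 <- y[3]; a <- y[5]; s <- y[6]
  phi_x <- 1 / (1 + p$c_xx * x0 + p$c_xy * y0)
  phi_y <- 1 / (1 + p$c_yx * x0 + p$c_yy * y0)
  J <- matrix(0, 6, 6)
  J[1, 1] <- p$r_x * s * phi_x^2 * (1 + p$c_xy * y0) - (p$d_x0 + p$a_x + p$r_m * s)
  J[1, 3] <- -p$r_x * s * x0 * p$c_xy * phi_x^2
  J[1, 6] <- (p$r_x * phi_x - p$r_m) * x0
  J[2, 1] <- p$a_x * p$A_x
  J[2, 2] <- -p$d_x1
  J[3, 1] <- -p$r_y * s * y0 * p$c_yx * phi_y^2 + p$r_m * s
  J[3, 3] <- p$r_y * s * phi_y^2 * (1 + p$c_yx * x0) - (p$d_y0 + p$a_y)
  J[3, 6] <- p$r_y * phi_y * y0 + p$r_m * x0
  J[4, 3] <- p$a_y * p$A_y
  J[4, 4] <- -p$d_y1
  J[5, 1] <- p$d_x0; J[5, 2] <- p$d_x1; J[5, 3] <- p$d_y0; J[5, 4] <- p$d_y1
  J[5, 5] <- -p$e_a * s
  J[5, 6] <- -p$e_a * a
  J[6, 5] <- p$r_s
  J[6, 6] <- -p$e_s
  J
}
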