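#' Model parameters for the inflammation-MPN system
#'
#' Constructs and validates the full rate-constant set of the six-compartment
#' inflammation-MPN model. All rates are per day; the inflammatory level `s`
#' carries pg/ml so that the self-renewal constants `r_x`, `r_y` and the
#' mutation constant `r_m` are per day per (pg/ml).
#'
#' @param r_x healthy stem-cell self-renewal rate constant (/day/(pg/ml)).
#' @param r_y malignant stem-cell self-renewal rate constant; the malignant
#'   clone must hold a self-renewal advantage, `r_y > r_x`, for the healthy
#'   state to be invadable.
#' @param a_x,a_y stem-to-progenitor differentiation rates (/day).
#' @param A_x,A_y progenitor amplification factors (dimensionless,
#'   `A = 2^k` for `k` implicit progenitor generations).
#' @param d_x0,d_y0 stem-cell death rates (/day).
#' @param d_x1,d_y1 mature-cell death rates (/day).
#' @param r_m mutation rate constant (/day/(pg/ml)/cell); the deterministic
#'   mutation flux is `r_m * s * x0`.
#' @param c_xx,c_xy,c_yx,c_yy bone-marrow niche inhibition coefficients
#'   (/cell) entering the crowding factors
#'   `phi_x = 1/(1 + c_xx*x0 + c_xy*y0)` and
#'   `phi_y = 1/(1 + c_yx*x0 + c_yy*y0)`.
#' @param r_s inflammation up-regulation per dead cell (/day/cell).
#' @param e_s inflammation elimination rate (/day).
#' @param e_a dead-cell clearance rate constant (/(pg/ml)/day); clearance is
#'   the second-order process `e_a * a * s`.
#' @param I_base baseline exogenous inflammatory load (pg/ml/day).
#' @param parsimony if `TRUE` (default), enforce the parsimony ties
#'   `d_y0 = d_x0`, `a_y = a_x`, `A_y = A_x` and equality of the four niche
#'   coefficients.
#' @param check_advantage if `TRUE` (default), signal a warning when
#'   `r_y <= r_x` (the healthy state is then stable against invasion; useful
#'   for counterfactual runs, hence a warning rather than an error).
#'
#' @return An object of class `mpn_parameters` (a named list of the 19
#'   fields above, `parsimony` flag kept as an attribute).
#' @seealso [default_parameters()], [read_parameters()], [mpn_rhs()]
#' @export
mpn_parameters <- function(r_x, r_y, a_x, a_y, A_x, A_y,
                           d_x0, d_y0, d_x1, d_y1, r_m,
                           c_xx, c_xy, c_yx, c_yy,
                           r_s, e_s, e_a, I_base,
                           parsimony = TRUE, check_advantage = TRUE) {
  p <- list(r_x = r_x, r_y = r_y, a_x = a_x, a_y = a_y, A_x = A_x, A_y = A_y,
            d_x0 = d_x0, d_y0 = d_y0, d_x1 = d_x1, d_y1 = d_y1, r_m = r_m,
            c_xx = c_xx, c_xy = c_xy, c_yx = c_yx, c_yy = c_yy,
            r_s = r_s, e_s = e_s, e_a = e_a, I_base = I_base)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1L || !is.finite(v),
                logical(1))
  if (any(bad))
    stop("non-numeric, non-scalar or non-finite parameter(s): ",
         paste(names(p)[bad], collapse = ", "))
  neg <- vapply(p, function(v) v < 0, logical(1))
  if (any(neg))
    stop("negative parameter(s): ", paste(names(p)[neg], collapse = ", "))
  p <- lapply(p, as.numeric)  # storage mode: double (file round trips)
  if (parsimony) {
    ties <- c(d_y0 = p$d_y0 == p$d_x0, a_y = p$a_y == p$a_x,
              A_y = p$A_y == p$A_x,
              c_equal = length(unique(c(p$c_xx, p$c_xy, p$c_yx, p$c_yy))) == 1L)
    if (!all(ties))
      stop("parsimony ties violated: ", paste(names(ties)[!ties], collapse = ", "),
           " (set parsimony = FALSE to allow)")
  }
  if (check_advantage && p$r_y <= p$r_x)
    warning("r_y <= r_x: the malignant clone has no self-renewal advantage")
  if (p$d_x0 >= p$d_x1)
    warning("d_x0 >= d_x1: stem cells are expected to die much more slowly than mature cells")
  structure(p, class = "mpn_parameters", parsimony = parsimony)
}

#' Canonical default parameter set
#'
#' The shipped defaults are the output of the package's own calibration
#' pipeline (see [calibrate_steady()] and [calibrate_timeline()] and the
#' methods vignette): the healthy steady state under a baseline exogenous
#' load of 7 pg/ml/day reproduces approximately 1e4 HSC, 1e10 mature cells,
#' 700 dead cells and an inflammatory level of 3.61 pg/ml, rising to about
#' 3.66 pg/ml in full-blown MPN, and the continuous-mutation allele-burden
#' timeline passes 7%, 33% and 67% near years 23.5, 29.9 and 34.7, with
#' the characteristic 1-year left shift of the single-first-insult run.
#'
#' @return An `mpn_parameters` object.
#' @export
default_parameters <- function() {
  mpn_parameters(
    r_x  = 1.14030500048245,      # /day/(pg/ml)
    r_y  = 1.16288596988862,
    a_x  = 0.0403573758816011,    # /day
    a_y  = 0.0403573758816011,
    A_x  = 24778617.9887851,      # ~2^24.6
    A_y  = 24778617.9887851,
    d_x0 = 4e-04,                 # /day
    d_y0 = 4e-04,
    d_x1 = 1.0,
    d_y1 = 1.0,
    r_m  = 1.66964700493268e-08,  # /day/(pg/ml)/cell
    c_xx = 0.01,                  # /cell
    c_xy = 0.01,
    c_yx = 0.01,
    c_yy = 0.01,
    r_s  = 0.0207142857142857,    # /day/cell
    e_s  = 5.95567867036011,      # /day
    e_a  = 3957261.57657301,      # /(pg/ml)/day
    I_base = 7                    # pg/ml/day
  )
}

#' @export
print.mpn_parameters <- function(x, ...) {
  cat("<mpn_parameters>  (rates per day; s in pg/ml)\n")
  nm <- names(unclass(x))
  vals <- vapply(unclass(x), function(v) formatC(v, digits = 6, format = "g"),
                 character(1))
  cat(paste0("  ", format(nm, width = 5), " = ", vals), sep = "\n")
  cat("  parsimony ties:", if (isTRUE(attr(x, "parsimony"))) "enforced" else "off", "\n")
  invisible(x)
}

## canonical field order used by file I/O and validation
.param_fields <- c("r_x", "r_y", "a_x", "a_y", "A_x", "A_y",
                   "d_x0", "d_y0", "d_x1", "d_y1", "r_m",
                   "c_xx", "c_xy", "c_yx", "c_yy", "r_s", "e_s", "e_a", "I_base")

#' Read model parameters from a flat key-value file
#'
#' Parameter files are flat YAML mappings with exactly one entry per
#' `mpn_parameters` field (SI-consistent units: rates per day, loads in
#' pg/ml/day). The schema is strict: missing or unknown keys are an error.
#'
#' @param path file path.
#' @param ... passed to [mpn_parameters()] (e.g. `parsimony = FALSE`).
#' @return An `mpn_parameters` object.
#' @export
read_parameters <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("parameter file must be a flat key-value mapping")
  unknown <- setdiff(names(raw), .param_fields)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.param_fields, names(raw))
  if (length(missing))
    stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  do.call(mpn_parameters, c(raw[.param_fields], list(...)))
}

#' Write model parameters to a flat key-value file
#'
#' @param params an `mpn_parameters` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "mpn_parameters"))
  vals <- unclass(params)[.param_fields]
  ## full double precision survives the round trip
  txt <- paste0(names(vals), ": ",
                vapply(vals, function(v) sprintf("%.17g", v), character(1)))
  writeLines(txt, path)
  invisible(path)
}

## internal: coerce to plain list, with modifications
.p_modify <- function(params, ...) {
  mods <- list(...)
  p <- unclass(params)
  p[names(mods)] <- mods
  p
}
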