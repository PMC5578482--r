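#' Piecewise-constant exogenous inflammatory-load schedule
#'
#' Describes the exogenous stimulus I(t) as ordered, non-overlapping
#' segments over which the load takes a constant level, with `base_level`
#' outside all segments. Segment bounds are in years; levels in pg/ml/day.
#'
#' @param start,end numeric vectors of segment bounds (years,
#'   `start < end`, segments non-overlapping). May be empty for a constant
#'   schedule.
#' @param level numeric vector of segment levels (pg/ml/day, >= 0).
#' @param base_level load outside all segments (pg/ml/day).
#' @return An object of class `stimulus_schedule`.
#' @examples
#' stimulus_schedule(10, 30, 14)         # doubling in years 10-30
#' stimulus_schedule(base_level = 7)     # constant baseline
#' @export
stimulus_schedule <- function(start = numeric(), end = numeric(),
                              level = numeric(), base_level = 7) {
  if (length(start) != length(end) || length(end) != length(level))
    stop("start, end and level must have equal length")
  if (!is.finite(base_level) || base_level < 0)
    stop("base_level must be finite and >= 0")
  if (length(start)) {
    if (any(!is.finite(c(start, end, level)))) stop("non-finite schedule entry")
    if (any(level < 0)) stop("negative stimulus level")
    if (any(end <= start)) stop("each segment needs end > start")
    o <- order(start)
    start <- start[o]; end <- end[o]; level <- level[o]
    if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
      stop("schedule segments overlap")
  }
  structure(list(start = start, end = end, level = level,
                 base_level = base_level),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("<stimulus_schedule> base level", x$base_level, "pg/ml/day\n")
  if (length(x$start))
    cat(sprintf("  years %g-%g: %g pg/ml/day\n", x$start, x$end, x$level), sep = "")
  else cat("  (constant)\n")
  invisible(x)
}

#' Evaluate a stimulus schedule
#'
#' @param schedule a [stimulus_schedule()].
#' @param t_years time(s) in years.
#' @return Load level(s) in pg/ml/day. Segments are half-open `[start, end)`.
#' @export
schedule_level <- function(schedule, t_years) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  out <- rep(schedule$base_level, length(t_years))
  for (k in seq_along(schedule$start)) {
    w <- t_years >= schedule$start[k] & t_years < schedule$end[k]
    out[w] <- schedule$level[k]
  }
  out
}

## internal: breakpoints (years) where the level changes, within [0, span]
.schedule_breaks <- function(schedule, span) {
  b <- sort(unique(c(0, schedule$start, schedule$end, span)))
  b[b >= 0 & b <= span]
}
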