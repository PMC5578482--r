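## Linear biomarker validation: maps from the model's inflammatory level s
## to cytokine/CRP medians and from the death influx DI to LDH.

.panel_names <- c("IL-1b", "IL-1RA", "IL-2R", "IL-6", "IL-8",
                  "IL-10", "IL-12", "CRP")
.state_cols <- c("Normal", "PV", "PMF")

#' Construct a biomarker median table
#'
#' One row per biomarker with median values for the Normal, PV and PMF
#' disease states. LDH rows (matched by name) are mapped against the death
#' influx rather than the inflammatory level.
#'
#' @param biomarker character vector of biomarker names.
#' @param Normal,PV,PMF positive median values per state.
#' @param unit units per biomarker (metadata; default pg/ml, mg/l for CRP,
#'   U/l for LDH).
#' @return A data frame of class `biomarker_table`.
#' @export
biomarker_table <- function(biomarker, Normal, PV, PMF, unit = NULL) {
  stopifnot(length(biomarker) == length(Normal),
            length(Normal) == length(PV), length(PV) == length(PMF))
  if (any(c(Normal, PV, PMF) <= 0)) stop("biomarker medians must be positive")
  if (anyDuplicated(biomarker)) stop("duplicate biomarker names")
  if (is.null(unit))
    unit <- ifelse(biomarker == "CRP", "mg/l",
                   ifelse(biomarker == "LDH", "U/l", "pg/ml"))
  structure(data.frame(biomarker = biomarker, unit = unit,
                       Normal = Normal, PV = PV, PMF = PMF,
                       stringsAsFactors = FALSE),
            class = c("biomarker_table", "data.frame"))
}

#' Read a biomarker median table from delimited text
#'
#' Tab-separated with header `biomarker  unit  Normal  PV  PMF` (the `unit`
#' column optional).
#'
#' @param path file path.
#' @return A `biomarker_table`.
#' @export
read_biomarker_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("biomarker", .state_cols)
  if (!all(need %in% names(df)))
    stop("biomarker table needs columns: ", paste(need, collapse = ", "))
  biomarker_table(df$biomarker, df$Normal, df$PV, df$PMF,
                  unit = if ("unit" %in% names(df)) df$unit else NULL)
}

#' Disease-stage anchor levels of a trajectory
#'
#' The inflammatory level `s` and death influx `DI` evaluated at the three
#' disease-stage anchor times: `t_Normal = 0` (healthy steady state),
#' `t_PV` = the 33%-burden crossing and `t_PMF` = the 67%-burden crossing
#' (the stages are identified with their median allele burdens; the anchor
#' times are configurable via `burdens`).
#'
#' @param traj an `mpn_trajectory` covering the crossings.
#' @param burdens burden levels defining the PV and PMF anchors.
#' @return List with `s` and `DI` (named length-3 vectors, Normal/PV/PMF)
#'   and `times` (the anchor years).
#' @export
anchor_levels <- function(traj, burdens = c(0.33, 0.67)) {
  stopifnot(inherits(traj, "mpn_trajectory"), length(burdens) == 2L)
  tcross <- vapply(burdens, function(b) crossing_time(traj, b), numeric(1))
  if (any(is.na(tcross)))
    stop("trajectory does not reach the ", paste(burdens, collapse = "/"),
         " burden anchors")
  times <- c(Normal = 0, PV = tcross[1], PMF = tcross[2])
  s <- stats::approx(traj$time_years, traj$s, times, rule = 2)$y
  DI <- stats::approx(traj$time_years, traj$death_influx, times, rule = 2)$y
  list(s = stats::setNames(s, names(times)),
       DI = stats::setNames(DI, names(times)),
       times = times)
}

#' Fit linear biomarker maps
#'
#' Per-biomarker ordinary least squares of the three state medians on the
#' matching model anchors: `m_j = k1 * s_j + k2` (cytokines/CRP against the
#' inflammatory level; LDH against the death influx). Three points and two
#' parameters: residuals are reported honestly rather than interpolated
#' away.
#'
#' @param table a [biomarker_table()].
#' @param anchors output of [anchor_levels()].
#' @return A data frame of class `biomarker_maps`: biomarker, predictor
#'   (`"s"` or `"DI"`), `slope`, `intercept`, `r_squared`, per-state
#'   residuals and relative residuals, and `max_rel_residual`.
#' @export
fit_linear_map <- function(table, anchors) {
  stopifnot(inherits(table, "biomarker_table"))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    predictor <- if (table$biomarker[i] == "LDH") "DI" else "s"
    x <- anchors[[predictor]]
    if (max(x) - min(x) < 1e-12 * max(abs(x), 1))
      stop("identical anchors: rank-deficient fit for ", table$biomarker[i])
    y <- as.numeric(table[i, .state_cols])
    fit <- stats::lm(y ~ x)
    pred <- stats::fitted(fit)
    res <- y - pred
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1  # collinear: perfect fit
    data.frame(biomarker = table$biomarker[i], predictor = predictor,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2,
               resid_Normal = res[1], resid_PV = res[2], resid_PMF = res[3],
               rel_Normal = res[1] / y[1], rel_PV = res[2] / y[2],
               rel_PMF = res[3] / y[3],
               max_rel_residual = max(abs(res / y)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("biomarker_maps", "data.frame"), anchors = anchors)
}

#' Validate a biomarker panel against its linear maps
#'
#' Tabulates observed vs predicted medians with relative errors and flags
#' biomarkers whose worst relative residual exceeds the threshold.
#'
#' @param maps a [fit_linear_map()] result.
#' @param table the [biomarker_table()] the maps were fitted to.
#' @param flag_threshold relative-residual flag level (default 0.25).
#' @return List with `report` (data frame: biomarker, state, observed,
#'   predicted, relative_error, flagged) and `flagged` (character vector).
#' @export
validate_panel <- function(maps, table, flag_threshold = 0.25) {
  stopifnot(inherits(maps, "biomarker_maps"), inherits(table, "biomarker_table"))
  anchors <- attr(maps, "anchors")
  rep_rows <- lapply(seq_len(nrow(maps)), function(i) {
    x <- anchors[[maps$predictor[i]]]
    obs <- as.numeric(table[table$biomarker == maps$biomarker[i], .state_cols])
    pred <- maps$slope[i] * x + maps$intercept[i]
    data.frame(biomarker = maps$biomarker[i], state = .state_cols,
               observed = obs, predicted = unname(pred),
               relative_error = unname((pred - obs) / obs),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  report$flagged <- abs(report$relative_error) > flag_threshold
  flagged <- unique(report$biomarker[report$flagged])
  list(report = report, flagged = flagged)
}
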