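#' Plot an inflammation-MPN trajectory
#'
#' Three stacked panels: stem cells, mature cells (log10 counts, healthy
#' full line, malignant dashed, total dotted) and the allele burden with
#' the 7/33/67% stage medians marked.
#'
#' @param x an `mpn_trajectory`.
#' @param ... further arguments passed to `matplot`.
#' @return `x`, invisibly.
#' @export
plot.mpn_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(op), add = TRUE)
  lg <- function(v) log10(pmax(v, 1e-3))
  graphics::matplot(x$time_years, cbind(lg(x$x0), lg(x$y0), lg(x$x0 + x$y0)),
                    type = "l", lty = c(1, 2, 3), col = c("blue", "red", "darkgreen"),
                    xlab = "", ylab = "log10 stem cells", ...)
  graphics::legend("bottomleft", c("healthy", "MPN", "total"), lty = 1:3,
                   col = c("blue", "red", "darkgreen"), bty = "n", cex = 0.8)
  graphics::matplot(x$time_years, cbind(lg(x$x1), lg(x$y1), lg(x$total_mature)),
                    type = "l", lty = c(1, 2, 3), col = c("blue", "red", "darkgreen"),
                    xlab = "", ylab = "log10 mature cells")
  graphics::plot(x$time_years, x$allele_burden, type = "l",
                 xlab = "years", ylab = "allele burden", ylim = c(0, 1))
  graphics::abline(h = c(0.07, 0.33, 0.67), lty = 3, col = "grey50")
  invisible(x)
}

#' Plot an inflammatory-load scenario suite
#'
#' Overlays the allele-burden curves of all scenarios in a
#' [scenario_suite()] result.
#'
#' @param suite a [scenario_suite()] result.
#' @return The suite, invisibly.
#' @export
plot_scenarios <- function(suite) {
  res <- suite$results
  cols <- grDevices::hcl.colors(length(res), "Dark 2")
  tr1 <- res[[1]]$trajectory
  graphics::plot(tr1$time_years, tr1$allele_burden, type = "l", col = cols[1],
                 xlab = "years", ylab = "allele burden", ylim = c(0, 1))
  for (k in seq_along(res)[-1])
    graphics::lines(res[[k]]$trajectory$time_years,
                    res[[k]]$trajectory$allele_burden, col = cols[k], lty = k)
  graphics::legend("bottomright", names(res), col = cols,
                   lty = seq_along(res), bty = "n", cex = 0.8)
  graphics::abline(h = c(0.07, 0.33, 0.67), lty = 3, col = "grey70")
  invisible(suite)
}
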