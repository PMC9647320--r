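#' Radar chart of a location profile
#'
#' Circular axis: compound group ids in library order; radial axis: the
#' zero-centred relative-intensity score (or the raw fold). The outdoor
#' baseline corresponds to the zero circle.
#'
#' @param profiles output of [build_profiles()]
#' @param location location to plot
#' @param value `"score"` (default) or `"fold"`
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the plotted values
#' @export
plot_profile_radar <- function(profiles, location,
                               value = c("score", "fold"), ...) {
  value <- match.arg(value)
  p <- profiles[profiles$location == location, , drop = FALSE]
  if (nrow(p) == 0) stop("unknown location: ", location, call. = FALSE)
  v <- p[[value]]
  base <- if (value == "score") 0 else 1
  k <- nrow(p)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  r0 <- abs(min(c(v, base))) + 0.5  # radial offset so radii stay positive
  radius <- v + r0
  x <- radius * sin(theta); y <- radius * cos(theta)
  lim <- max(radius) * 1.15
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s (%s)", location, value), ...)
  bt <- seq(0, 2 * pi, length.out = 181)
  graphics::lines((base + r0) * sin(bt), (base + r0) * cos(bt),
                  lty = 2, col = "grey50")
  graphics::polygon(x, y, border = "steelblue", col = grDevices::adjustcolor(
    "steelblue", alpha.f = 0.3))
  graphics::text(1.08 * lim * sin(theta), 1.08 * lim * cos(theta),
                 labels = p$group_id, cex = 0.7)
  invisible(v)
}

#' Replicate stability plot for one analyte at one location
#'
#' Per-replicate intensity series, one line per form (monomer, dimer,
#' trimer), mirroring the way replicate stability is inspected visually.
#'
#' @param report output of [stability_report()]
#' @param location location name
#' @param group_id compound group id
#' @param ... passed to [graphics::matplot()]
#' @return invisibly, the series matrix
#' @export
plot_stability <- function(report, location, group_id, ...) {
  stopifnot(inherits(report, "stability_report"))
  ps <- report$per_series
  sel <- ps$location == location & ps$group_id == group_id
  if (!any(sel))
    stop("no series for that location/group", call. = FALSE)
  sub <- ps[sel, , drop = FALSE]
  S <- do.call(cbind, sub$series)
  graphics::matplot(S, type = "b", pch = 19, lty = 1,
                    xlab = "replicate", ylab = "intensity (V)",
                    main = sprintf("%s, group %d", location, group_id), ...)
  graphics::legend("topright", legend = sub$form, col = seq_len(ncol(S)),
                   lty = 1, pch = 19, bty = "n")
  invisible(S)
}
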