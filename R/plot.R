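#' Plot a g(r) curve with confidence intervals
#'
#' Base-graphics plot of the classified pair-correlation curve: points
#' with their resampling confidence intervals against radius in
#' micrometres, a reference line at g = 1 (complete spatial randomness),
#' red points where the interval overlaps 1 and black where the deviation
#' from CSR is significant.  Invalid radii are omitted.
#'
#' @param x a [CiResult-class].
#' @param y ignored.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the plotted data frame, invisibly.
#' @export
setMethod("plot", signature(x = "CiResult", y = "missing"), function(x, y, ...) {
  df <- as.data.frame(x)
  df <- df[df$valid & !is.na(df$ci_lo), , drop = FALSE]
  if (!nrow(df)) stop("no valid radii to plot", call. = FALSE)
  overlaps <- df$ci_lo <= 1 & df$ci_hi >= 1
  ylim <- range(c(df$ci_lo, df$ci_hi, 1))
  graphics::plot(df$r_um, df$g, ylim = ylim, pch = 19,
                 col = ifelse(overlaps, "red", "black"),
                 xlab = expression(paste("r (", mu, "m)")),
                 ylab = expression(italic(g)(italic(r))), ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  graphics::segments(df$r_um, df$ci_lo, df$r_um, df$ci_hi,
                     col = ifelse(overlaps, "red", "black"))
  invisible(df)
})

#' @rdname plot-CiResult-missing-method
#' @aliases plot,PcfResult,missing-method
#' @export
setMethod("plot", signature(x = "PcfResult", y = "missing"), function(x, y, ...) {
  tb <- x@table[x@table$valid, , drop = FALSE]
  if (!nrow(tb)) stop("no valid radii to plot", call. = FALSE)
  graphics::plot(tb$r_um, tb$g, pch = 19, type = "b",
                 xlab = expression(paste("r (", mu, "m)")),
                 ylab = expression(italic(g)(italic(r))), ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(tb)
})
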