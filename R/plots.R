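# Thin base-graphics plotting layer over the analysis tables. Aesthetics
# are not contractual; these exist so the analysis drivers can render the
# standard diagnostic figures.

#' ENC versus GC3s scatter with Wright's neutral curve
#'
#' @param points Data.frame with `gc3s`, `enc` and optionally
#'   `order_label` (used for colors).
#' @param file Optional PNG path; `NULL` draws on the active device.
#' @param main Plot title.
#' @export
plot_enc_gc3 <- function(points, file = NULL, main = "ENC vs GC3s") {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- if ("order_label" %in% names(points)) {
    as.integer(factor(points$order_label)) + 1L
  } else 1L
  plot(points$gc3s, points$enc, col = cols, pch = 19, cex = 0.6,
       xlim = c(0, 1), ylim = c(15, 65), xlab = "GC3s", ylab = "ENC",
       main = main)
  xs <- seq(0.001, 0.999, length.out = 200)
  graphics::lines(xs, pmin(enc_expected(xs), 65), lwd = 2)
  if ("order_label" %in% names(points)) {
    lv <- levels(factor(points$order_label))
    graphics::legend("bottomright", legend = lv, col = seq_along(lv) + 1L,
                     pch = 19, cex = 0.7, bty = "n")
  }
  invisible(NULL)
}

#' Neutrality plot: GC12 against GC3 with the fitted line
#'
#' @param points Data.frame with `gc3`, `gc12`.
#' @param fit A `neutrality_fit` (drawn when given).
#' @param file Optional PNG path.
#' @param main Plot title.
#' @export
plot_neutrality <- function(points, fit = NULL, file = NULL,
                            main = "Neutrality plot (GC12 ~ GC3)") {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  plot(points$gc3, points$gc12, pch = 19, cex = 0.6, col = "grey30",
       xlab = "GC3", ylab = "GC12", main = main)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(fit)) {
    graphics::abline(fit$intercept, fit$slope, col = "red", lwd = 2)
    graphics::mtext(sprintf("slope %.3f, R2 %.3f", fit$slope,
                            fit$r_squared), side = 3, line = 0.2, cex = 0.8)
  }
  invisible(NULL)
}

#' AT-skew against GC-skew by order
#'
#' @param skews Data.frame with `gc_skew`, `at_skew`, `order_label`.
#' @param file Optional PNG path.
#' @param main Plot title.
#' @export
plot_skews <- function(skews, file = NULL, main = "AT vs GC skew") {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- as.integer(factor(skews$order_label)) + 1L
  plot(skews$gc_skew, skews$at_skew, col = cols, pch = 19,
       xlab = "GC skew", ylab = "AT skew", main = main)
  graphics::abline(h = 0, v = 0, lty = 3)
  lv <- levels(factor(skews$order_label))
  graphics::legend("topright", legend = lv, col = seq_along(lv) + 1L,
                   pch = 19, cex = 0.7, bty = "n")
  invisible(NULL)
}

#' Heat map of a z-scored RSCU matrix with clustered row order
#'
#' @param m A scaled `rscu_matrix`.
#' @param file Optional PNG path.
#' @param main Plot title.
#' @export
plot_rscu_heatmap <- function(m, file = NULL, main = "RSCU (z-scored)") {
  stopifnot(inherits(m, "rscu_matrix"))
  if (!is.null(file)) {
    grDevices::png(file, width = 1100, height = 800, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ord <- hierarchical_order(m)$order
  v <- m$values[ord, , drop = FALSE]
  graphics::image(t(v), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(51, "RdYlBu", rev = TRUE))
  invisible(NULL)
}
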