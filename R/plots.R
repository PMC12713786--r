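#' Overlay of the SSD and EED cumulative distribution functions
#'
#' Plots the SSD CDF (red) with the EED CDFs on a log-10 concentration
#' axis, shades the hazard-concentration band between the SSD's 5th and
#' 95th percentile point estimates, and marks the HC5 upper confidence
#' limit (the safety threshold) as a dashed vertical line.
#'
#' @param ssd an `mp_ssd`.
#' @param eeds named list of `mp_eed` objects.
#' @param main plot title.
#' @export
plot_ssd_eed_overlay <- function(ssd, eeds,
                                 main = "SSD and exposure distributions") {
  qlo <- percentile(ssd$fit, 0.01)
  qhi <- percentile(ssd$fit, 0.99)
  for (e in eeds) {
    qlo <- min(qlo, percentile(e$fit, 0.01))
    qhi <- max(qhi, percentile(e$fit, 0.99))
  }
  xs <- exp(seq(log(qlo), log(qhi), length.out = 400))
  graphics::plot(xs, cdf_value(ssd$fit, xs), type = "n", log = "x",
                 xlab = "concentration (nb/kg dw)",
                 ylab = "cumulative probability", main = main,
                 ylim = c(0, 1))
  graphics::rect(percentile(ssd$fit, 0.05), -0.04,
                 percentile(ssd$fit, 0.95), 1.04,
                 col = grDevices::adjustcolor("red", 0.08), border = NA)
  cols <- c(sludge = "brown", diluted_sludge = "blue", sas = "orange",
            control = "darkgreen")
  ltys <- c(sludge = 1, diluted_sludge = 1, sas = 2, control = 2)
  for (m in names(eeds)) {
    graphics::lines(xs, cdf_value(eeds[[m]]$fit, xs),
                    col = cols[[m]] %||% "grey40", lty = ltys[[m]] %||% 1,
                    lwd = 2)
  }
  graphics::lines(xs, cdf_value(ssd$fit, xs), col = "red", lwd = 2.5)
  graphics::abline(v = ssd$hc5_upper, col = "purple", lty = 2, lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("red", vapply(names(eeds), function(m)
                     cols[[m]] %||% "grey40", character(1)), "purple"),
                   lty = c(1, vapply(names(eeds), function(m)
                     ltys[[m]] %||% 1, numeric(1)), 2),
                   legend = c("SSD", paste0("EED ", names(eeds)),
                              "HC5 upper limit"))
  invisible(NULL)
}

#' Proportion of affected species across dilution scenarios
#'
#' @param results list of `mp_risk` results (a [scenario_sweep()] output).
#' @param threshold protection threshold drawn as a horizontal line.
#' @export
plot_dilution_sweep <- function(results, threshold = 0.05) {
  tab <- exceedance_verdict(results, threshold)
  n <- nrow(tab)
  graphics::plot(seq_len(n), 100 * tab$proportion_point, ylim = c(0, 100 *
                   max(tab$unc_high) * 1.1), pch = 19, xaxt = "n",
                 xlab = "", ylab = "affected species (%)",
                 main = "Proportion of affected species (MC2D)")
  graphics::arrows(seq_len(n), 100 * tab$unc_low, seq_len(n),
                   100 * tab$unc_high, angle = 90, code = 3, length = 0.05)
  graphics::axis(1, at = seq_len(n), labels = tab$scenario, las = 2,
                 cex.axis = 0.7)
  graphics::abline(h = 100 * threshold, col = "red", lty = 2)
  invisible(tab)
}

#' Boxplot comparison of SAS and control concentrations
#'
#' @param sas,control exposure tables or numeric vectors.
#' @export
plot_group_boxplot <- function(sas, control) {
  x <- if (is.data.frame(sas)) sas$concentration else sas
  y <- if (is.data.frame(control)) control$concentration else control
  graphics::boxplot(list(control = y, SAS = x), log = "y",
                    ylab = "concentration (nb/kg dw)",
                    col = c("darkseagreen", "orange"))
  invisible(NULL)
}
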