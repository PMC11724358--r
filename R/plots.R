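# Base-graphics summary plots: stacked class bar, micro/homology length
# histograms (full range and zoomed to the separation region), and the
# per-chromosome variant density histogram.

#' Write the standard summary plots
#'
#' @param annotations final annotation data.frame
#' @param tallies class tallies from [tally_classes()]
#' @param summary a `mechanism_summary`
#' @param density data.frame from [chromosome_density()]
#' @param out_prefix path prefix; PNG files are written next to the tables
#' @return named vector of plot paths, invisibly
#' @export
plot_run_summary <- function(annotations, tallies, summary, density,
                             out_prefix) {
  p1 <- paste0(out_prefix, ".classes.png")
  grDevices::png(p1, width = 600, height = 450)
  graphics::barplot(as.matrix(tallies), beside = FALSE, legend.text = TRUE,
                    col = grDevices::hcl.colors(length(tallies), "Set 2"),
                    main = "Variant classes", ylab = "count")
  grDevices::dev.off()

  p2 <- paste0(out_prefix, ".homology.png")
  grDevices::png(p2, width = 900, height = 450)
  graphics::par(mfrow = c(1, 2))
  h <- summary$histogram
  if (length(h)) {
    x <- as.integer(names(h))
    graphics::plot(x, as.numeric(h), type = "h", lwd = 2,
                   xlab = "micro/homology length (bp)", ylab = "count",
                   main = "Micro/homology lengths")
    graphics::abline(v = summary$baseline + 0.5, col = "red", lty = 2)
    zoom <- x >= 10 & x <= 80
    graphics::plot(x[zoom], as.numeric(h)[zoom], type = "h", lwd = 2,
                   xlab = "micro/homology length (bp)", ylab = "count",
                   main = sprintf("Separation region (baseline %d bp)",
                                  summary$baseline))
    graphics::abline(v = summary$baseline + 0.5, col = "red", lty = 2)
  } else {
    graphics::plot.new(); graphics::plot.new()
  }
  grDevices::dev.off()

  p3 <- paste0(out_prefix, ".density.png")
  grDevices::png(p3, width = 900, height = 450)
  if (nrow(density)) {
    tab <- tapply(density$count,
                  list(density$mechanism,
                       paste0(density$chrom, ":",
                              density$window_start %/% 1000000L, "Mb")),
                  sum, default = 0L)
    graphics::barplot(tab, legend.text = TRUE, las = 2,
                      col = grDevices::hcl.colors(nrow(tab), "Dark 3"),
                      main = "Variant density along chromosomes",
                      ylab = "count")
  } else {
    graphics::plot.new()
  }
  grDevices::dev.off()
  invisible(c(classes_plot = p1, homology_plot = p2, density_plot = p3))
}
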