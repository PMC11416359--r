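#' Render an agreement report to files
#'
#' Writes `report.csv` (machine readable), `report.md` (human readable,
#' correlations significant at p < 0.05 in bold) and one Bland-Altman
#' plot per table row (`bland_altman_<region>.png`): difference vs.
#' pairwise mean with the mean-difference line and the two 95%
#' limit-of-agreement lines.
#'
#' @param report an [agreement_report()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create output directory '%s'", dir)
  pairs <- attr(report, "pairs")
  paths <- character()

  csv <- file.path(dir, "report.csv")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  paths <- c(paths, csv)

  md <- file.path(dir, "report.md")
  lines <- c("# Agreement between 3D ultrasound and histopathology",
             "", "Differences are US - histology (mm); limits are 95% limits of agreement.",
             "Correlations significant at p < 0.05 are shown in bold.", "",
             "| Region | n | r | p | Mean diff (95% LoA) |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    if (r$n == 0) {
      lines <- c(lines, sprintf("| %s | 0 |  |  |  |", r$region))
      next
    }
    sig <- !is.na(r$p) && r$p < 0.05
    fmt <- function(s) if (sig) paste0("**", s, "**") else s
    rr <- if (is.na(r$r)) "" else fmt(sprintf("%.3f", r$r))
    pp <- if (is.na(r$p)) "" else
      fmt(if (r$p < 0.001) "p < 0.001" else sprintf("p = %.3f", r$p))
    ba <- if (is.na(r$mean_diff)) "" else
      sprintf("%.2f (%.2f; %.2f)", r$mean_diff, r$loa_lower, r$loa_upper)
    lines <- c(lines, sprintf("| %s | %d | %s | %s | %s |", r$region, r$n, rr, pp, ba))
  }
  ex <- attr(report, "excluded")
  if (!is.null(ex))
    lines <- c(lines, "", paste("Excluded specimens:", paste(ex, collapse = ", ")))
  writeLines(lines, md)
  paths <- c(paths, md)

  for (i in seq_len(nrow(report))) {
    rg <- report$region[i]
    f <- file.path(dir, sprintf("bland_altman_%s.png", rg))
    sub <- if (rg == "all") pairs else pairs[pairs$region == rg, , drop = FALSE]
    grDevices::png(f, width = 720, height = 540)
    if (nrow(sub) >= 2) {
      ba <- bland_altman(sub)
      plot(ba$means, ba$differences,
           xlab = "Mean of US and histology (mm)",
           ylab = "US - histology (mm)",
           main = sprintf("Bland-Altman: %s (n = %d)", rg, ba$n),
           pch = 19, col = "grey25")
      graphics::abline(h = ba$mean_diff, col = "blue", lwd = 2)
      graphics::abline(h = ba$limits, col = "red", lty = 2, lwd = 2)
    } else {
      plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "",
           main = sprintf("Bland-Altman: %s", rg))
      graphics::text(0, 0, "no data")
    }
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  invisible(paths)
}
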