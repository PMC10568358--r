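fp_band_label <- function(fitzpatrick) {
  factor(dplyr::case_when(fitzpatrick <= 2 ~ "FP 1-2 (light)",
                          fitzpatrick <= 4 ~ "FP 3-4 (medium)",
                          TRUE ~ "FP 5-6 (dark)"),
         levels = c("FP 1-2 (light)", "FP 3-4 (medium)", "FP 5-6 (dark)"))
}

# light = blue, medium = yellow, dark = green
fp_band_palette <- function() {
  c("FP 1-2 (light)" = "#1f77b4",
    "FP 3-4 (medium)" = "#e6b422",
    "FP 5-6 (dark)" = "#2ca02c")
}

#' Scatterplot of estimate versus reference
#'
#' Estimate against reference with the 1:1 identity line (red), the
#' ordinary-least-squares best-fit line (black) and points colour-coded by
#' Fitzpatrick skin-tone band.
#'
#' @param records Records tibble.
#' @param metric Metric name (`"hr"`, `"ibi"`, `"sdnn"`, ...).
#' @param ref_prefix `"ref"` or `"truth"`.
#' @param snr_min Optional SNR threshold (dB); when given, only records with
#'   `snr_db > snr_min` are drawn.
#' @return A ggplot object.
#' @export
plot_scatter <- function(records, metric = "hr", ref_prefix = "ref",
                         snr_min = NULL) {
  if (!is.null(snr_min)) records <- stratify(records, "snr_threshold", snr_min)
  df <- data.frame(est = records[[paste0("est_", metric)]],
                   ref = records[[paste0(ref_prefix, "_", metric)]],
                   band = fp_band_label(records$fitzpatrick))
  df <- df[is.finite(df$est) & is.finite(df$ref), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref, y = .data$est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$band), size = 2) +
    ggplot2::scale_colour_manual(values = fp_band_palette(), drop = FALSE,
                                 name = "Skin tone") +
    ggplot2::labs(x = paste("Reference", toupper(metric)),
                  y = paste("Estimated", toupper(metric))) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Difference (estimate minus reference) against pair mean, with the bias line
#' and the 95% limits of agreement (bias +/- 1.96 SD, dashed), points
#' colour-coded by Fitzpatrick band.
#'
#' @inheritParams plot_scatter
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(records, metric = "hr", ref_prefix = "ref",
                              snr_min = NULL) {
  if (!is.null(snr_min)) records <- stratify(records, "snr_threshold", snr_min)
  est <- records[[paste0("est_", metric)]]
  ref <- records[[paste0(ref_prefix, "_", metric)]]
  ok <- is.finite(est) & is.finite(ref)
  df <- data.frame(m = (est[ok] + ref[ok]) / 2, d = est[ok] - ref[ok],
                   band = fp_band_label(records$fitzpatrick[ok]))
  bias <- mean(df$d); sdd <- sd(df$d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_hline(yintercept = bias, colour = "black") +
    ggplot2::geom_hline(yintercept = bias + c(-1.96, 1.96) * sdd,
                        linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$band), size = 2) +
    ggplot2::scale_colour_manual(values = fp_band_palette(), drop = FALSE,
                                 name = "Skin tone") +
    ggplot2::labs(x = paste("Mean of estimate and reference,", toupper(metric)),
                  y = "Estimate - reference") +
    ggplot2::theme_minimal()
}

#' Write the standard benchmark figures
#'
#' Scatter (all samples) and Bland-Altman (restricted to SNR > 10 dB, the
#' perfect-quality subset) figures for each requested metric.
#'
#' @param records Records tibble.
#' @param dir Output directory.
#' @param metrics Metric names.
#' @param ref_prefix `"ref"` or `"truth"`.
#' @param ba_snr_min SNR threshold for the Bland-Altman subset (dB).
#' @return Character vector of written PNG paths, invisibly.
#' @export
plot_reports <- function(records, dir, metrics = c("hr", "sdnn"),
                         ref_prefix = "ref", ba_snr_min = 10) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in metrics) {
    p1 <- file.path(dir, paste0("scatter_", m, ".png"))
    ggplot2::ggsave(p1, plot_scatter(records, m, ref_prefix),
                    width = 6, height = 5, dpi = 120)
    p2 <- file.path(dir, paste0("bland_altman_", m, ".png"))
    ggplot2::ggsave(p2, plot_bland_altman(records, m, ref_prefix,
                                          snr_min = ba_snr_min),
                    width = 6, height = 5, dpi = 120)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
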