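#' Plot a PCoA ordination
#'
#' Scatter of the first two principal coordinates, optionally colored by a
#' per-sample grouping.
#'
#' @param object An `sv_pcoa`.
#' @param groups Optional vector of labels (in sample order) or data frame
#'   with `sample_id` and `group`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_pcoa <- function(object, groups = NULL, ...) {
  df <- object$points
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      df$group <- groups$group[match(df$sample_id, groups$sample_id)]
    } else {
      df$group <- groups
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PCo2 (%.1f%%)",
                  100 * object$var_explained[min(2, object$k)])
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  }
}

#' Forest plot of pooled SV associations
#'
#' Pooled odds/hazard ratios with 95% confidence intervals on a log scale,
#' colored by decision label.
#'
#' @param object An `svmwas_meta` tibble.
#' @param max_features Cap on the number of features shown (most significant
#'   first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.svmwas_meta <- function(object, max_features = 30, ...) {
  df <- tidy.svmwas_meta(object)
  df <- df[!is.na(df$p), ]
  df <- df[order(df$p), ]
  df <- head(df, max_features)
  df$label <- paste(df$feature_id, df$outcome, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = stats::reorder(.data$label, -.data$p),
                                   colour = .data$decision)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pooled OR / HR (95% CI)", y = NULL,
                  colour = "decision") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves
#'
#' Step curves of the product-limit survival estimates per group.
#'
#' @param object A `km_logrank` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_logrank <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  subtitle = sprintf("log-rank P = %.2g", object$p)) +
    ggplot2::theme_minimal()
}

#' Deletion-rate track along a species genome
#'
#' Fraction of present samples whose normalized coverage falls below the
#' deleted-bin threshold, per 1-kbp bin — the visual signature a deletion SV
#' leaves in a cohort.
#'
#' @param norm Output of [normalize_coverage()].
#' @param species Species id to plot.
#' @param del_ratio Deleted-bin ratio threshold.
#' @return A ggplot.
#' @export
plot_deletion_rate <- function(norm, species, del_ratio = 0.25) {
  m <- ratio_matrix(norm, species)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  df <- tibble(bin = as.integer(colnames(m)),
               deletion_rate = colMeans(m < del_ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$deletion_rate)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "genome position (kbp)",
                  y = sprintf("fraction of samples with ratio < %.2f",
                              del_ratio),
                  title = species) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
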