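#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_jitter
#'   geom_point geom_errorbar geom_col labs theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Plot the fold-level balanced-accuracy distribution of a report
#' @param object a `rst_eval`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rst_eval <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.na(df$error), ]
  ggplot(df, aes(x = .data$rule_scenario, y = .data$BACC)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    labs(x = NULL, y = "Balanced accuracy",
         title = sprintf("%s DP, %d fold(s)", object$dp_mode, nrow(object$folds))) +
    theme_minimal()
}

#' Plot a scenario comparison table
#' @param object a `rst_battery`.
#' @param ... unused.
#' @return A ggplot of mean BACC with CI95 error bars per scenario and DP
#'   mode.
#' @export
autoplot.rst_battery <- function(object, ...) {
  df <- object$comparison
  ggplot(df, aes(x = .data$rule_scenario, y = .data$mean_bacc,
                 color = .data$dp_mode)) +
    geom_point(position = ggplot2::position_dodge(width = 0.4), size = 2) +
    geom_errorbar(aes(ymin = .data$ci95_lo, ymax = .data$ci95_hi),
                  width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    labs(x = NULL, y = "Mean balanced accuracy (CI95)", color = "DP mode") +
    theme_minimal()
}

#' Plot per-feature occurrence across folds
#' @param occ output of [feature_occurrence()].
#' @param top_n number of features shown.
#' @param highlight feature names to emphasize (e.g. the planted features).
#' @return A ggplot.
#' @export
plot_feature_occurrence <- function(occ, top_n = 20, highlight = character()) {
  df <- head(occ, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  df$planted <- df$feature %in% highlight
  ggplot(df, aes(x = .data$feature, y = .data$occurrence, fill = .data$planted)) +
    geom_col(show.legend = length(highlight) > 0) +
    coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = NULL, y = "Fraction of folds containing feature", fill = "directive target") +
    theme_minimal()
}
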