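#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_density
#'   geom_tile geom_text labs theme_minimal autoplot scale_fill_gradient
#'   facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Known-ness score densities for knowns vs unknowns
#'
#' @param object An `osr_scores` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osr_scores <- function(object, ...) {
  df <- object |>
    mutate(group = ifelse(.data$is_known, "known", "unknown"))
  ggplot(df, aes(x = .data$known_score, fill = .data$group)) +
    geom_density(alpha = 0.5) +
    labs(x = "known-ness score (max reciprocal-point distance)",
         y = "density", fill = NULL) +
    theme_minimal()
}

#' Per-trial metrics with their mean
#'
#' @param object An `osr_metrics` aggregate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osr_metrics <- function(object, ...) {
  long <- object$per_trial |>
    tidyr::pivot_longer(-"trial", names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_point(alpha = 0.6) +
    geom_point(data = object$summary,
               aes(x = .data$metric, y = .data$mean),
               shape = 4, size = 4) +
    labs(x = NULL, y = "percent") +
    theme_minimal()
}

#' OSCR curve (CCR vs FPR)
#'
#' @param table An `osr_scores` tibble.
#' @return A ggplot.
#' @export
plot_oscr_curve <- function(table) {
  pts <- oscr_curve(table)
  ggplot(pts, aes(x = .data$fpr, y = .data$ccr)) +
    geom_line() +
    labs(x = "false positive rate (unknowns accepted)",
         y = "correct classification rate") +
    theme_minimal()
}

#' Confusion-matrix heatmap with counts and row percents
#'
#' @param report Output of [closed_set_report()].
#' @return A ggplot.
#' @export
plot_confusion <- function(report) {
  cm <- report$confusion
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "predicted", "count")
  df$percent <- as.data.frame(as.table(report$confusion_percent))$Freq
  ggplot(df, aes(x = .data$predicted, y = .data$true,
                 fill = .data$percent)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%d\n%.0f%%", .data$count,
                                  .data$percent)), size = 2.6) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "true", fill = "row %") +
    theme_minimal()
}

#' Training-loss trajectory
#'
#' @param model An `osr_model`.
#' @return A ggplot of the per-epoch AM, AMC and total losses.
#' @export
plot_loss_log <- function(model) {
  long <- tidy(model) |>
    tidyr::pivot_longer(-"epoch", names_to = "loss", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   color = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "loss", color = NULL) +
    theme_minimal()
}
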