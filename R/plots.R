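# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_tile geom_text geom_line geom_point
#'   geom_vline geom_hline labs scale_fill_gradient theme_minimal autoplot
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot a confusion matrix as a tile heatmap
#'
#' Counts are printed in each cell; fill encodes the row-normalized
#' fraction (per-truth percentage).
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df <- df |>
    group_by(.data$truth) |>
    mutate(frac = .data$n / pmax(sum(.data$n), 1)) |>
    ungroup()
  ggplot(df, aes(x = .data$prediction, y = .data$truth, fill = .data$frac)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "#2c7fb8", limits = c(0, 1),
                        name = "fraction") +
    labs(x = "prediction", y = "truth",
         title = sprintf("LOOCV accuracy %.1f%%", 100 * object$accuracy)) +
    theme_minimal()
}

#' Plot the PCA-LDA component-selection curve
#'
#' Internal LOOCV accuracy against the number of principal components,
#' with the selected size marked.
#'
#' @param object A `pca_lda` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pca_lda <- function(object, ...) {
  ggplot(object$cv, aes(x = .data$n_pc, y = .data$accuracy)) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = object$n_pc, linetype = "dashed") +
    labs(x = "principal components", y = "LOOCV accuracy",
         title = sprintf("selected n_pc = %d (accuracy %.3f)",
                         object$n_pc, object$loocv_accuracy)) +
    theme_minimal()
}

#' Volcano plot of a differential-accessibility result
#'
#' @param result Tibble from [nb_wald()] (or one subtype of
#'   [one_vs_rest()]).
#' @param padj_max,min_abs_lfc Gates drawn as guide lines (defaults
#'   0.05 and 1).
#' @return A ggplot object.
#' @export
plot_volcano <- function(result, padj_max = 0.05, min_abs_lfc = 1) {
  df <- filter(result, !is.na(.data$pvalue))
  df$sig <- !is.na(df$padj) & df$padj < padj_max &
    abs(df$log2FC) >= min_abs_lfc
  ggplot(df, aes(x = .data$log2FC, y = -log10(pmax(.data$pvalue, 1e-300)),
                 colour = .data$sig)) +
    geom_point(size = 0.5, alpha = 0.6) +
    geom_vline(xintercept = c(-min_abs_lfc, min_abs_lfc),
               linetype = "dotted") +
    labs(x = "log2 fold change", y = "-log10 p", colour = "significant") +
    theme_minimal()
}

#' Plot mean Tn5 insertion profiles per group
#'
#' Aggregates insertion counts over occurrences of one motif and plots
#' the mean per-base rate by window offset for each group; the core
#' (motif) span is marked.
#'
#' @param profiles Insertion-profile tibble (see [footprint_score()]).
#' @param motif Motif id to plot.
#' @return A ggplot object.
#' @export
plot_footprint_profile <- function(profiles, motif) {
  pr <- filter(profiles, .data$motif_id == motif)
  if (nrow(pr) == 0) abort("no profiles for that motif")
  L <- pr$motif_len[1] + 2L * pr$w_out[1]
  df <- pr |>
    group_by(.data$group_id) |>
    summarise(mean_rate = list(Reduce(`+`, .data$counts) / dplyr::n()),
              .groups = "drop") |>
    mutate(offset = list(seq_len(L) - 1L - pr$w_out[1])) |>
    tidyr::unnest(c("mean_rate", "offset"))
  ggplot(df, aes(x = .data$offset, y = .data$mean_rate,
                 colour = .data$group_id)) +
    geom_line() +
    geom_vline(xintercept = c(0, pr$motif_len[1] - 1), linetype = "dotted") +
    labs(x = "offset from motif start (bp)", y = "mean insertions/bp",
         colour = "group", title = motif) +
    theme_minimal()
}
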