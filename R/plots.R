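#' @importFrom ggplot2 aes autoplot ggplot geom_raster geom_line geom_col
#'   geom_boxplot geom_vline facet_wrap labs scale_fill_gradient
#'   scale_fill_manual theme_minimal
NULL

#' Heatmap of a metagene matrix
#'
#' One row per gene (display order preserved: row 1 at the top), one column
#' per distance bin.
#'
#' @param object A `metagene_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metagene_matrix
#' @export
autoplot.metagene_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$distance, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "white", high = "#08306b", name = "signal") +
    labs(x = sprintf("distance from %s (bp)", toupper(object$anchor)),
         y = "genes", title = sprintf("metagene (%s)", object$sort_key)) +
    theme_minimal()
}

#' Average metagene profile, TSS and TES panels side by side
#'
#' @param object A `metagene_profile` tibble from [two_anchor_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$panel <- factor(df$panel, levels = c("TSS", "TES"))
  ggplot(df, aes(x = .data$distance, y = .data$value)) +
    geom_line(colour = "#2166ac") +
    geom_vline(xintercept = 0, linetype = "dotted") +
    facet_wrap(~panel, scales = "free_x") +
    labs(x = "distance from anchor (bp)", y = "mean signal") +
    theme_minimal()
}

#' Boxplot of center-of-gene turnover by length cluster
#'
#' @param table Tibble with columns `length_cluster` and a turnover column.
#' @param value Name of the turnover column (default `"center_turnover"`).
#' @return A ggplot object.
#' @export
plot_turnover_clusters <- function(table, value = "center_turnover") {
  df <- table[table$length_cluster != "unassigned", ]
  ggplot(df, aes(x = .data$length_cluster, y = .data[[value]])) +
    geom_boxplot(fill = "#d1e5f0") +
    labs(x = "gene length cluster", y = "log2 Flag/Myc (center of gene)") +
    theme_minimal()
}

#' Stacked percentage plot of accessibility calls
#'
#' @param summary Tibble from [summarize_calls()] (optionally with an extra
#'   `sample` column for several genotypes side by side).
#' @return A ggplot object.
#' @export
plot_call_summary <- function(summary) {
  df <- as_tibble(summary)
  if (!"sample" %in% names(df)) df$sample <- "sample"
  ggplot(df, aes(x = .data$sample, y = .data$pct, fill = .data$call)) +
    geom_col(position = "stack") +
    scale_fill_manual(values = c(decreased = "#4393c3", steady = "grey70",
                                 increased = "#f4a582")) +
    labs(x = NULL, y = "% of genes") +
    theme_minimal()
}
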