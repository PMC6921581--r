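# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a group expression comparison
#' @param x A `plast_group_test` from [compare_groups()].
#' @param ... Unused.
#' @return A plain tibble of the per-feature statistics.
#' @method tidy plast_group_test
#' @export
tidy.plast_group_test <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' Glance at a group expression comparison
#' @param x A `plast_group_test`.
#' @param ... Unused.
#' @return One-row tibble: `n_features`, `n_significant`, `alpha`, `by`.
#' @method glance plast_group_test
#' @export
glance.plast_group_test <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    by = attr(x, "by")
  )
}

#' Tidy an editing-rate comparison
#' @param x A `plast_editing_test` from [compare_editing()].
#' @param ... Unused.
#' @return A plain tibble of the per-site statistics.
#' @method tidy plast_editing_test
#' @export
tidy.plast_editing_test <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' Glance at an editing-rate comparison
#' @param x A `plast_editing_test`.
#' @param ... Unused.
#' @return One-row tibble: `n_sites`, `n_significant`, `alpha`, `by`.
#' @method glance plast_editing_test
#' @export
glance.plast_editing_test <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    by = attr(x, "by")
  )
}

#' Plot strand-specific coverage
#'
#' @param object A `plast_coverage` from [depth_of_coverage()].
#' @param region Optional c(start, end) window.
#' @param ... Unused.
#' @return A ggplot: per-base depth, minus strand drawn downward.
#' @method autoplot plast_coverage
#' @export
autoplot.plast_coverage <- function(object, region = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(region)) {
    df <- df |> filter(.data$pos >= region[1], .data$pos <= region[2])
  }
  df <- df |>
    mutate(signed = if_else(.data$strand == "+", .data$depth,
                            -.data$depth))
  ggplot(df, aes(x = .data$pos, y = .data$signed, colour = .data$strand)) +
    geom_line() +
    scale_colour_manual(values = c(`+` = "#7a4fae", `-` = "#3a9a6e")) +
    labs(x = "position (bp)", y = "depth of coverage (minus strand down)",
         colour = "strand") +
    theme_minimal()
}

#' Plot an editing-rate comparison between two groups
#'
#' Scatter of per-site pooled rates, group 1 versus group 2, with the
#' identity line; significant sites highlighted.
#'
#' @param object A `plast_editing_test` from [compare_editing()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plast_editing_test
#' @export
autoplot.plast_editing_test <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$rate1, y = .data$rate2,
                 colour = .data$significant)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(size = 2) +
    scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "#c23b22")) +
    labs(
      x = sprintf("editing rate, %s", df$group1[1] %||% "group 1"),
      y = sprintf("editing rate, %s", df$group2[1] %||% "group 2"),
      colour = "FDR-significant"
    ) +
    theme_minimal()
}

#' Plot per-feature expression by group
#'
#' @param tpm Long TPM tibble (columns `feature`, `tpm`, and the grouping
#'   column).
#' @param by Grouping column name.
#' @return A ggplot of log10 TPM per feature, coloured by group.
#' @export
plot_expression <- function(tpm, by = "sex") {
  ggplot(tpm, aes(x = .data$feature, y = .data$tpm + 1,
                  colour = .data[[by]])) +
    geom_point(position = ggplot2::position_jitter(width = 0.15, height = 0),
               alpha = 0.8) +
    ggplot2::scale_y_log10() +
    labs(x = NULL, y = "TPM + 1", colour = by) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
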