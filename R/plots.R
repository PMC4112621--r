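#' Plot the pocket-finding funnel of a run
#'
#' Bar chart of pocket counts at each funnel stage (candidates, merged,
#' biochemical, physical).
#'
#' @param object A `pg_pocket_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pg_pocket_run
#' @export
autoplot.pg_pocket_run <- function(object, ...) {
  df <- object$funnel
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "pockets",
                  title = sprintf("Pocket funnel for %s", object$id)) +
    ggplot2::theme_minimal()
}

#' Plot pocket geometry
#'
#' Depth against cavity surface area, point size by atom count — the two
#' quantities the physical filter compares with the ligand's dimensions.
#'
#' @param object A `pg_pockets` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pg_pockets
#' @export
autoplot.pg_pockets <- function(object, ...) {
  df <- tidy_pockets(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$surface,
                                   size = .data$n_atoms)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::labs(x = "depth (Å)", y = "surface (Å²)",
                  size = "atoms") +
    ggplot2::theme_minimal()
}

#' Plot pocket-by-site cf values
#'
#' Tile map of the correct fraction for every (pocket, active site) pair.
#'
#' @param object A `pg_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pg_evaluation
#' @export
autoplot.pg_evaluation <- function(object, ...) {
  df <- object$cf
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id,
                                   y = factor(.data$pocket_id),
                                   fill = .data$cf)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "active site", y = "pocket", fill = "cf") +
    ggplot2::theme_minimal()
}

#' Histogram of per-pair best cf in a benchmark
#'
#' @param object A `pg_benchmark`.
#' @param binwidth Histogram bin width on the cf axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pg_benchmark
#' @export
autoplot.pg_benchmark <- function(object, binwidth = 0.1, ...) {
  df <- filter(object$results, .data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_cf)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "maximum cf per protein", y = "proteins") +
    ggplot2::theme_minimal()
}
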