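# Agreement of ICU rankings across models and metrics, CI flag counts,
# and the display layer (caterpillar plots, rank-set plots, kernel
# densities).  Plot builders return the exact plotted data so tests and
# reports never need to parse image files.

#' Rank concordance between two metrics or models
#'
#' Kendall's tau-b (tie-corrected) and Spearman's rho between two
#' rankings (or raw metric vectors) over the same units.
#'
#' @param ranking_a,ranking_b Named numeric vectors (names are unit
#'   ids), or plain vectors of equal length in matching order.
#' @return List with \code{kendall_tau_b}, \code{spearman_rho} and
#'   \code{n_units}.
#' @export
concordance <- function(ranking_a, ranking_b) {
  if (!is.null(names(ranking_a)) && !is.null(names(ranking_b))) {
    if (!setequal(names(ranking_a), names(ranking_b))) {
      stop("unit sets differ between the two rankings")
    }
    ranking_b <- ranking_b[names(ranking_a)]
  } else if (length(ranking_a) != length(ranking_b)) {
    stop("rankings must cover the same units")
  }
  list(kendall_tau_b = stats::cor(ranking_a, ranking_b, method = "kendall"),
       spearman_rho = stats::cor(ranking_a, ranking_b, method = "spearman"),
       n_units = length(ranking_a))
}

#' Count ICUs whose interval excludes the null
#'
#' @param metric_table A \code{metric_table}.
#' @param null_value Null value of the metric (1 for ratios, 0 for
#'   differences and random effects); endpoints equal to the null count
#'   as not excluded.
#' @return List with \code{n_below} (CI entirely below the null),
#'   \code{n_above} and \code{n_units}.
#' @export
flag_counts <- function(metric_table, null_value = NULL) {
  stopifnot(inherits(metric_table, "metric_table"))
  if (is.null(null_value)) {
    null_value <- if (all(metric_table$metric_kind %in%
                            c("ralosr_arith", "ralosr_geo"))) 1 else 0
  }
  list(n_below = sum(metric_table$ci_high < null_value),
       n_above = sum(metric_table$ci_low > null_value),
       n_units = nrow(metric_table), null_value = null_value)
}

#' Ranked caterpillar plot of a metric table
#'
#' ICUs ordered by point estimate with horizontal 95\% CI bars and a
#' null reference line.
#'
#' @param metric_table A \code{metric_table}.
#' @param out_path Optional file path (png/pdf/svg) to write.
#' @param null_value Reference line; defaults as in
#'   \code{\link{flag_counts}}.
#' @return Invisibly, a list with the \code{ggplot} object and the
#'   plotted-data table (in plotted order).
#' @export
render_caterpillar <- function(metric_table, out_path = NULL,
                               null_value = NULL) {
  stopifnot(inherits(metric_table, "metric_table"))
  if (nrow(metric_table) == 0) stop("empty metric table")
  if (is.null(null_value)) {
    null_value <- flag_counts(metric_table)$null_value
  }
  d <- as.data.frame(metric_table)[order(metric_table$point), ]
  d$plot_order <- seq_len(nrow(d))
  g <- ggplot2::ggplot(d, ggplot2::aes(x = point, y = plot_order)) +
    ggplot2::geom_vline(xintercept = null_value, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0, colour = "grey55") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = unique(d$metric_kind), y = "ICU (ranked)",
                  title = sprintf("%s (%s)", unique(d$metric_kind),
                                  toupper(unique(d$source_model)))) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) ggplot2::ggsave(out_path, g, width = 6, height = 7)
  invisible(list(plot = g, data = d))
}

#' Rank confidence-set plot
#'
#' Units ordered by point rank; bars span the rank confidence set with
#' a marker at the point rank.
#'
#' @param rank_table A \code{rank_table}.
#' @param out_path Optional file path to write.
#' @return Invisibly, list of \code{ggplot} object and plotted data.
#' @export
render_rank_sets <- function(rank_table, out_path = NULL) {
  stopifnot(inherits(rank_table, "rank_table"))
  if (nrow(rank_table) == 0) stop("empty rank table")
  d <- as.data.frame(rank_table)[order(rank_table$point_rank,
                                       rank_table$rank_low), ]
  d$plot_order <- seq_len(nrow(d))
  g <- ggplot2::ggplot(d, ggplot2::aes(x = point_rank, y = plot_order)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = rank_low, xmax = rank_high),
                            height = 0, colour = "grey55") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank", y = "ICU (by point rank)",
                  title = sprintf("%s rank confidence sets",
                                  unique(d$kind))) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) ggplot2::ggsave(out_path, g, width = 6, height = 7)
  invisible(list(plot = g, data = d))
}

#' Kernel density overlay
#'
#' Gaussian-kernel densities (Silverman's bandwidth rule) for one or
#' more labelled series, optionally truncated for display.
#'
#' @param values_by_label Named list of numeric vectors.
#' @param out_path Optional file path to write.
#' @param truncate_at Optional upper display truncation (e.g. 20 days).
#' @return Invisibly, list with the \code{ggplot} object and the
#'   evaluated density grid (label, x, density).
#' @export
render_density <- function(values_by_label, out_path = NULL,
                           truncate_at = NULL) {
  stopifnot(is.list(values_by_label), length(values_by_label) >= 1)
  grids <- lapply(names(values_by_label), function(lab) {
    v <- values_by_label[[lab]]
    if (length(v) < 2) stop("need at least 2 values per series")
    if (!is.null(truncate_at)) v <- v[v <= truncate_at]
    dd <- stats::density(v, kernel = "gaussian", bw = "nrd0")
    data.frame(label = lab, x = dd$x, density = dd$y)
  })
  grid <- do.call(rbind, grids)
  g <- ggplot2::ggplot(grid, ggplot2::aes(x = x, y = density,
                                          colour = label)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "value", y = "density", colour = NULL)
  if (!is.null(out_path)) ggplot2::ggsave(out_path, g, width = 6, height = 4)
  invisible(list(plot = g, data = grid))
}
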