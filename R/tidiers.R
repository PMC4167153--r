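#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' One row per (method, repetition, metric): the combiner metrics and,
#' optionally, the 27 experts' metrics.
#'
#' @param x an `lk_cv_result`.
#' @param experts include per-expert rows (default `FALSE`).
#' @param ... unused.
#' @return tibble with `method`, `kind`, `repetition`, `metric`, `value`.
#' @method tidy lk_cv_result
#' @export
tidy.lk_cv_result <- function(x, experts = FALSE, ...) {
  out <- x$combiner_metrics |>
    dplyr::transmute(method = .data$combiner, kind = "combiner",
                     repetition = .data$repetition, metric = .data$metric,
                     value = .data$value)
  if (experts) {
    out <- dplyr::bind_rows(
      out,
      x$expert_metrics |>
        dplyr::transmute(method = .data$id, kind = "expert",
                         repetition = .data$repetition, metric = .data$metric,
                         value = .data$value)
    )
  }
  out
}

#' One-row summary of a cross-validation result
#'
#' @param x an `lk_cv_result`.
#' @param ... unused.
#' @return tibble with repetitions, mean accuracies of the four combiners,
#'   the fused-vs-best-baseline gap, and lambda.
#' @method glance lk_cv_result
#' @export
glance.lk_cv_result <- function(x, ...) {
  acc <- x$combiner_metrics |>
    dplyr::filter(.data$metric == "ACC") |>
    dplyr::group_by(.data$combiner) |>
    dplyr::summarise(acc = mean(.data$value), .groups = "drop")
  get <- function(m) acc$acc[acc$combiner == m]
  baselines <- c(get("average"), get("weighted"), get("majority"))
  tibble::tibble(
    n = x$n, K = x$cv$K, repetitions = x$cv$repetitions, mode = x$mode,
    acc_average = get("average"), acc_weighted = get("weighted"),
    acc_majority = get("majority"), acc_soft_fusion = get("soft_fusion"),
    fusion_minus_best_baseline = get("soft_fusion") - max(baselines),
    lambda = x$lambda
  )
}

#' Tidy a combiner comparison
#'
#' @param x an `lk_comparison`.
#' @param ... unused.
#' @return tibble with one row per method: mean rank and whether the method
#'   differs significantly from the best-ranked one.
#' @method tidy lk_comparison
#' @export
tidy.lk_comparison <- function(x, ...) {
  best <- names(which.min(x$mean_ranks))
  tibble::tibble(
    method = names(x$mean_ranks),
    mean_rank = as.numeric(x$mean_ranks),
    differs_from_best = x$significant[best, names(x$mean_ranks)]
  )
}

#' One-row summary of a combiner comparison
#' @param x an `lk_comparison`.
#' @param ... unused.
#' @return tibble with the Friedman statistic, p-value, critical difference
#'   and the rank gap between the two best methods.
#' @method glance lk_comparison
#' @export
glance.lk_comparison <- function(x, ...) {
  r <- sort(x$mean_ranks)
  tibble::tibble(
    friedman_statistic = x$friedman_statistic, p_value = x$p_value,
    cd = x$cd, alpha = x$alpha, N = x$N, k = x$k,
    best = names(r)[1], top_two_gap = as.numeric(r[2] - r[1]),
    top_two_significant = as.numeric(r[2] - r[1]) > x$cd
  )
}

#' Plot per-repetition combiner accuracies
#'
#' @param object an `lk_cv_result`.
#' @param metric metric to plot (default `"ACC"`).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lk_cv_result
#' @export
autoplot.lk_cv_result <- function(object, metric = "ACC", ...) {
  df <- object$combiner_metrics |>
    dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combiner, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric,
                  title = paste0(metric, " per repetition by combination method"))
}

#' Critical-difference style plot of a combiner comparison
#'
#' Mean rank per method with a segment of length CD anchored at the best
#' method: methods whose point lies beyond the segment differ significantly.
#'
#' @param object an `lk_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lk_comparison
#' @export
autoplot.lk_comparison <- function(object, ...) {
  df <- tibble::tibble(method = names(object$mean_ranks),
                       rank = as.numeric(object$mean_ranks))
  best <- min(df$rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = stats::reorder(.data$method, .data$rank))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::annotate("segment", x = best, xend = best + object$cd,
                      y = 0.6, yend = 0.6, linewidth = 1.2) +
    ggplot2::annotate("text", x = best + object$cd / 2, y = 0.75,
                      label = sprintf("CD = %.3f", object$cd), size = 3) +
    ggplot2::labs(x = "mean rank (1 = best)", y = NULL,
                  title = "Nemenyi critical-difference comparison")
}

#' Raster plot of a synthetic eye image
#'
#' @param object an `eye_image`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot eye_image
#' @export
autoplot.eye_image <- function(object, ...) {
  pix <- object$pixels
  s <- dim(pix)[1]
  df <- expand.grid(row = seq_len(s), col = seq_len(s))
  df$fill <- grDevices::rgb(pix[, , 1][as.matrix(df)],
                            pix[, , 2][as.matrix(df)],
                            pix[, , 3][as.matrix(df)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = if (object$label == 1) "leukocoric" else "healthy")
}

#' @export
print.lk_cv_result <- function(x, ...) {
  cat("Repeated ", x$cv$K, "-fold CV (", x$cv$repetitions, " repetitions, ",
      x$mode, " densities) on ", x$n, " images\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.lk_comparison <- function(x, ...) {
  cat("Friedman test over", x$N, "criteria x", x$k, "methods:",
      sprintf("chi^2 = %.3f, p = %.3g; Nemenyi CD = %.4f\n",
              x$friedman_statistic, x$p_value, x$cd))
  print(tidy(x))
  invisible(x)
}
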