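#' Desired direction of each performance metric
#'
#' For ranking, every metric has a target: error-style metrics (RMSE,
#' NRMSE, |mean residual|, residual SD, FPR, FDR, BER) aim at zero, the
#' remaining bounded metrics aim at one. Rank 1 is the value closest to
#' the target.
#'
#' @return tibble with columns `metric`, `direction`
#'   (`"zero"`/`"one"`), `target`.
#' @export
metric_directions <- function() {
  m <- metric_names()
  dir <- ifelse(m %in% c("RMSE", "NRMSE", "abs_mu_eps", "sigma_eps",
                         "FPR", "FDR", "BER"), "zero", "one")
  tibble::tibble(metric = m, direction = dir,
                 target = ifelse(dir == "zero", 0, 1))
}

#' Rank classifiers on one metric
#'
#' Rank 1 is the best: the value closest to the desired target (0 for
#' error-style metrics, 1 for agreement-style metrics). Ties receive
#' averaged fractional ranks; missing (undefined) values are excluded and
#' returned as `NA` ranks with a warning.
#'
#' @param values numeric metric values, one per classifier.
#' @param direction `"zero"`, `"one"`, `"smallest"` or `"largest"`; or a
#'   numeric target value.
#' @return numeric ranks aligned with `values`.
#' @export
rank_metric <- function(values, direction) {
  if (is.character(direction)) {
    target <- switch(direction,
                     zero = 0, smallest = 0, one = 1, largest = NULL,
                     stop("rank_metric(): unknown direction ", direction,
                          call. = FALSE))
  } else {
    target <- as.numeric(direction)
  }
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("rank_metric(): needs >= 2 finite values", call. = FALSE)
  if (any(!ok)) {
    warning("rank_metric(): ", sum(!ok),
            " undefined value(s) excluded from ranking")
  }
  key <- if (is.null(target)) -values else abs(values - target)
  r <- rep(NA_real_, length(values))
  r[ok] <- rank(key[ok], ties.method = "average")
  r
}

#' Average rank of each classifier across metrics
#'
#' @param rank_table numeric matrix or data frame, metrics in rows,
#'   classifiers in columns, entries from [rank_metric()].
#' @return named numeric vector of mean ranks (NA entries ignored).
#' @export
average_rank <- function(rank_table) {
  colMeans(as.matrix(rank_table), na.rm = TRUE)
}

#' Fuzzy densities from average ranks
#'
#' Converts average ranks into importances: `g_i` is the reciprocal average
#' rank normalized by the sum of reciprocals, so the densities sum to one
#' and a better-ranked (smaller `r`) classifier always receives a larger
#' density.
#'
#' @param r average ranks, all >= 1 (named by expert id if available).
#' @return an [fuzzy_densities()] vector summing to 1.
#' @export
#' @examples
#' densities_from_ranks(c(a = 1, b = 2))  # 2/3, 1/3
densities_from_ranks <- function(r) {
  r <- unlist(r)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("densities_from_ranks(): ranks must be finite and > 0", call. = FALSE)
  }
  fuzzy_densities(stats::setNames((1 / r) / sum(1 / r), names(r)))
}

#' Published per-channel average ranks of the 27 experts
#'
#' The average ranks reported for the original 144-image study, one value
#' per expert per channel, in bank order (ANN_1..3, DA_1, DA_2, SVM_1..4
#' for R, then G, then B). Shipped so densities can be built without
#' retraining ("paper-2014" preset).
#'
#' @return named numeric vector of 27 average ranks.
#' @export
paper_2014_ranks <- function() {
  vals <- c(
    # red channel
    7.29, 6.47, 8.06, 2.47, 5.88, 3.82, 4.59, 3.88, 2.53,
    # green channel
    4.88, 5.35, 6.82, 4.06, 7.41, 5.12, 7.29, 2.59, 1.47,
    # blue channel
    8.00, 7.00, 5.88, 4.24, 7.41, 3.29, 5.35, 1.88, 1.94
  )
  stats::setNames(vals, default_bank()$id)
}

#' Per-channel rank tables from expert metric summaries
#'
#' Builds the per-channel ranking of the nine experts on each of the 16
#' metrics, plus each expert's average rank, from a long table of
#' per-expert mean metric values.
#'
#' @param metric_summary tibble with columns `id`, `channel`, `metric`,
#'   `value` (one mean value per expert per metric).
#' @return list with `ranks` (tibble: `channel`, `metric`, `id`, `rank`)
#'   and `avg_rank` (tibble: `id`, `channel`, `avg_rank`).
#' @export
channel_rank_tables <- function(metric_summary) {
  dirs <- metric_directions()
  ranks <- metric_summary |>
    dplyr::inner_join(dirs, by = "metric") |>
    dplyr::group_by(.data$channel, .data$metric) |>
    dplyr::mutate(rank = rank_metric(.data$value, .data$direction[1])) |>
    dplyr::ungroup() |>
    dplyr::select("channel", "metric", "id", "rank")
  avg <- ranks |>
    dplyr::group_by(.data$id, .data$channel) |>
    dplyr::summarise(avg_rank = mean(.data$rank, na.rm = TRUE), .groups = "drop")
  list(ranks = ranks, avg_rank = avg)
}
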