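#' Cross-validation configuration
#'
#' @param K number of folds (default 10).
#' @param repetitions number of repeated CV runs (default 10; the full
#'   protocol uses 100).
#' @param seed integer base seed; folds and expert training derive their
#'   streams from it.
#' @param stratified keep class proportions per fold (default `TRUE`; with
#'   a 37.5% positive class, small unstratified folds can degenerate).
#' @return a `cv_config` list.
#' @export
cv_config <- function(K = 10, repetitions = 10, seed = 1L, stratified = TRUE) {
  if (K < 2) stop("cv_config(): K must be >= 2", call. = FALSE)
  if (repetitions < 1) stop("cv_config(): repetitions must be >= 1", call. = FALSE)
  structure(list(K = as.integer(K), repetitions = as.integer(repetitions),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Partition indices into K folds
#'
#' Seeded shuffle into folds of size differing by at most one; when
#' `labels` are supplied the partition is stratified (sizes differ by at
#' most one within each class).
#'
#' @param n number of observations.
#' @param K number of folds.
#' @param seed integer seed.
#' @param labels optional class labels for stratification.
#' @return integer vector of fold assignments in `1..K`.
#' @export
kfold_partition <- function(n, K, seed = 1L, labels = NULL) {
  if (n < K) stop("kfold_partition(): n < K", call. = FALSE)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (is.null(labels)) {
      fold <- sample(rep_len(seq_len(K), n))
    } else {
      stopifnot(length(labels) == n)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        start <- sample.int(K, 1)  # rotate so no fold systematically larger
        seq_f <- ((start - 1 + seq_along(idx) - 1) %% K) + 1
        fold[sample(idx)] <- seq_f
      }
    }
  })
  fold
}

# per-instance combiner outputs for one fold
# h: n x m matrix of positive certainties; g densities; lambda solved
combiner_outputs <- function(h, g, lambda) {
  y_exp <- 2 * h - 1
  fus <- t(apply(h, 1, function(hr) {
    fp <- fuse_predict(hr, g, lambda)
    c(fp$e_pos - fp$e_neg, fp$class)
  }))
  votes <- ifelse(y_exp >= 0, 1, -1)
  vote_frac <- rowMeans(votes == 1)
  y_avg <- rowMeans(y_exp)
  y_wavg <- drop(y_exp %*% as.numeric(g))
  y_maj <- ifelse(vote_frac >= 0.5, 1, -1)
  list(
    average = list(y = y_avg, labels = ifelse(y_avg >= 0, 1L, -1L),
                   scores = (y_avg + 1) / 2),
    weighted = list(y = y_wavg, labels = ifelse(y_wavg >= 0, 1L, -1L),
                    scores = (y_wavg + 1) / 2),
    majority = list(y = y_maj, labels = as.integer(y_maj), scores = vote_frac),
    soft_fusion = list(y = fus[, 1], labels = as.integer(fus[, 2]),
                       scores = (fus[, 1] + 1) / 2)
  )
}

# metrics for one method within one repetition: per-fold residual/confusion
# metrics averaged over folds, AUC pooled over the repetition's folds
rep_metrics <- function(per_fold, pooled_scores, pooled_d) {
  folds <- dplyr::bind_rows(per_fold)
  out <- colMeans(folds, na.rm = TRUE)
  out["AUC"] <- auc_rank(pooled_scores, pooled_d)
  tibble::as_tibble(as.list(out))
}

# fit bank on one training split of a corrected stack, return test
# certainty matrix (n_test x n_experts)
fold_certainties <- function(stack, d, train_idx, test_idx, bank, seed) {
  prep <- fit_prep_on_stack(stack, train_idx)
  tr <- project_stack(stack, prep, train_idx)
  te <- project_stack(stack, prep, test_idx)
  h <- matrix(NA_real_, length(test_idx), nrow(bank),
              dimnames = list(NULL, bank$id))
  for (i in seq_len(nrow(bank))) {
    sp <- bank[i, ]
    ex <- train_expert(sp, tr[[sp$channel]], d[train_idx],
                       seed = seed + i * 131L)
    h[, i] <- certainty(ex, te[[sp$channel]])[, "h_pos"]
  }
  h
}

# expert metric table (long) for one repetition given fold certainty data
expert_rep_metrics <- function(fold_data, bank, rep) {
  purrr::map_dfr(seq_len(nrow(bank)), function(i) {
    per_fold <- lapply(fold_data, function(fd) {
      h <- fd$h[, i]
      metric_vector(2 * h - 1, ifelse(h >= 0.5, 1L, -1L), h, fd$d)
    })
    pooled_h <- unlist(lapply(fold_data, function(fd) fd$h[, i]))
    pooled_d <- unlist(lapply(fold_data, function(fd) fd$d))
    mv <- rep_metrics(per_fold, pooled_h, pooled_d)
    tibble::tibble(repetition = rep, id = bank$id[i], channel = bank$channel[i],
                   metric = names(mv), value = as.numeric(mv[1, ]))
  })
}

# combiner metric table (long) for one repetition
combiner_rep_metrics <- function(fold_data, g, lambda, rep) {
  outs <- lapply(fold_data, function(fd) combiner_outputs(fd$h, g, lambda))
  purrr::map_dfr(c("average", "weighted", "majority", "soft_fusion"),
                 function(m) {
    per_fold <- Map(function(o, fd) {
      metric_vector(o[[m]]$y, o[[m]]$labels, o[[m]]$scores, fd$d)
    }, outs, fold_data)
    pooled_s <- unlist(lapply(outs, function(o) o[[m]]$scores))
    pooled_d <- unlist(lapply(fold_data, function(fd) fd$d))
    mv <- rep_metrics(per_fold, pooled_s, pooled_d)
    tibble::tibble(repetition = rep, combiner = m,
                   metric = names(mv), value = as.numeric(mv[1, ]))
  })
}

#' Repeated K-fold cross-validation of the expert bank and combiners
#'
#' Runs the full protocol: for every repetition, a fresh (stratified)
#' K-fold partition; for every fold, preprocessing statistics, KLT bases
#' and all experts are fitted only on the training folds and certainties
#' recorded on the held-out fold. Expert metrics are computed per fold and
#' averaged within each repetition (AUC pooled per repetition). Fuzzy
#' densities are then derived and the four combiners (average, weighted
#' average, majority vote, soft fusion) evaluated on the same recorded
#' certainties.
#'
#' Two density modes: `"paper"` derives densities from the experts' average
#' ranks over all repetitions of this same CV (faithful to the original
#' protocol, which reuses the CV twice); `"honest"` derives them per fold
#' from an inner CV on that fold's training data only, so no test instance
#' ever influences its own densities.
#'
#' @param dataset tibble of eye images ([generate_dataset()] layout).
#' @param bank expert specification tibble (default [default_bank()]).
#' @param cv a [cv_config()].
#' @param mode `"paper"` or `"honest"`.
#' @param density_source `"trained"` (from this run's ranks) or
#'   `"paper-2014"` (the shipped published average ranks; requires the
#'   default 27-expert bank).
#' @param inner_K folds of the inner CV in honest mode (default 5).
#' @return an `lk_cv_result` with long tibbles `expert_metrics` and
#'   `combiner_metrics`, the densities, lambda, average ranks, bank and
#'   configuration.
#' @export
run_repeated_cv <- function(dataset, bank = default_bank(), cv = cv_config(),
                            mode = c("paper", "honest"),
                            density_source = c("trained", "paper-2014"),
                            inner_K = 5) {
  mode <- match.arg(mode)
  density_source <- match.arg(density_source)
  stopifnot(inherits(cv, "cv_config"))
  n <- nrow(dataset)
  d <- dataset$label
  stack <- corrected_stack(dataset)
  strat <- if (cv$stratified) d else NULL

  all_reps <- vector("list", cv$repetitions)
  for (rep in seq_len(cv$repetitions)) {
    fold <- kfold_partition(n, cv$K, seed = cv$seed + rep * 7919L, labels = strat)
    fold_data <- lapply(seq_len(cv$K), function(k) {
      test_idx <- which(fold == k)
      train_idx <- which(fold != k)
      h <- tryCatch(
        fold_certainties(stack, d, train_idx, test_idx, bank,
                         seed = cv$seed + rep * 1009L + k * 97L),
        error = function(e) {
          stop("repetition ", rep, ", fold ", k, ": ", conditionMessage(e),
               call. = FALSE)
        }
      )
      fd <- list(h = h, d = d[test_idx], test_idx = test_idx)
      if (mode == "honest") {
        fd$g_inner <- honest_densities(stack, d, train_idx, bank, inner_K,
                                       seed = cv$seed + rep * 4001L + k * 13L)
      }
      fd
    })
    all_reps[[rep]] <- fold_data
  }

  expert_metrics <- purrr::map_dfr(seq_len(cv$repetitions), function(rep) {
    expert_rep_metrics(all_reps[[rep]], bank, rep)
  })

  # densities
  if (density_source == "paper-2014") {
    preset <- paper_2014_ranks()
    if (!identical(names(preset), bank$id)) {
      stop("density_source 'paper-2014' requires the default 27-expert bank",
           call. = FALSE)
    }
    avg_ranks <- preset
    g <- densities_from_ranks(avg_ranks)
  } else {
    summ <- expert_metrics |>
      dplyr::group_by(.data$id, .data$channel, .data$metric) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    rk <- channel_rank_tables(summ)
    avg <- rk$avg_rank[match(bank$id, rk$avg_rank$id), ]
    avg_ranks <- stats::setNames(avg$avg_rank, avg$id)
    g <- densities_from_ranks(avg_ranks)
  }
  lambda <- solve_lambda(g)

  combiner_metrics <- purrr::map_dfr(seq_len(cv$repetitions), function(rep) {
    if (mode == "honest") {
      fd2 <- lapply(all_reps[[rep]], function(fd) {
        fd$g <- fd$g_inner; fd
      })
      purrr::map_dfr(c("average", "weighted", "majority", "soft_fusion"),
                     function(m) {
        outs <- lapply(fd2, function(fd) {
          combiner_outputs(fd$h, fd$g, solve_lambda(fd$g))
        })
        per_fold <- Map(function(o, fd) {
          metric_vector(o[[m]]$y, o[[m]]$labels, o[[m]]$scores, fd$d)
        }, outs, fd2)
        pooled_s <- unlist(lapply(outs, function(o) o[[m]]$scores))
        pooled_d <- unlist(lapply(fd2, function(fd) fd$d))
        mv <- rep_metrics(per_fold, pooled_s, pooled_d)
        tibble::tibble(repetition = rep, combiner = m,
                       metric = names(mv), value = as.numeric(mv[1, ]))
      })
    } else {
      combiner_rep_metrics(all_reps[[rep]], g, lambda, rep)
    }
  })

  structure(
    list(expert_metrics = expert_metrics, combiner_metrics = combiner_metrics,
         densities = g, lambda = lambda, avg_ranks = avg_ranks,
         bank = bank, cv = cv, mode = mode, density_source = density_source,
         n = n),
    class = "lk_cv_result"
  )
}

# honest-mode densities: inner CV on a training split only
honest_densities <- function(stack, d, train_idx, bank, inner_K, seed) {
  fold <- kfold_partition(length(train_idx), inner_K, seed = seed,
                          labels = d[train_idx])
  fold_data <- lapply(seq_len(inner_K), function(k) {
    te <- train_idx[fold == k]
    tr <- train_idx[fold != k]
    list(h = fold_certainties(stack, d, tr, te, bank, seed = seed + k * 17L),
         d = d[te])
  })
  em <- expert_rep_metrics(fold_data, bank, rep = 1L)
  summ <- em |>
    dplyr::group_by(.data$id, .data$channel, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  rk <- channel_rank_tables(summ)
  avg <- rk$avg_rank[match(bank$id, rk$avg_rank$id), ]
  densities_from_ranks(stats::setNames(avg$avg_rank, avg$id))
}

#' Friedman rank test over a criterion-by-method table
#'
#' Ranks the methods on every criterion (direction-aware, fractional ranks
#' on ties) and computes the classical Friedman chi-square statistic
#' `12N / (k(k+1)) * (sum R_j^2 - k (k+1)^2 / 4)` on the mean ranks, with
#' a chi-square p-value on k - 1 degrees of freedom.
#'
#' @param values numeric N x k matrix: criteria in rows, methods in columns.
#' @param directions character vector of length N (`"zero"`/`"one"` or
#'   numeric targets), one per criterion.
#' @return list with `statistic`, `p_value`, `mean_ranks`, `ranks`, `N`, `k`.
#' @export
friedman_rank_test <- function(values, directions) {
  values <- as.matrix(values)
  N <- nrow(values); k <- ncol(values)
  if (k < 3) stop("friedman_rank_test(): needs k >= 3 methods", call. = FALSE)
  if (N < 2) stop("friedman_rank_test(): needs N >= 2 criteria", call. = FALSE)
  stopifnot(length(directions) == N)
  ranks <- t(vapply(seq_len(N), function(i) {
    rank_metric(values[i, ], directions[i])
  }, numeric(k)))
  R <- colMeans(ranks)
  stat <- 12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       mean_ranks = stats::setNames(R, colnames(values)),
       ranks = ranks, N = N, k = k)
}

#' Nemenyi critical difference
#'
#' Minimum average-rank gap between two of `k` methods compared over `N`
#' criteria that is significant at level `alpha`:
#' `CD = q_alpha * sqrt(k (k+1) / (6 N))`, where `q_alpha` is the
#' studentized-range quantile divided by `sqrt(2)` (2.5694 for k = 4 at
#' alpha = 0.05).
#'
#' @param k number of methods (>= 2).
#' @param N number of criteria (>= 1).
#' @param alpha significance level in (0, 0.5].
#' @return the critical difference (positive scalar).
#' @export
#' @examples
#' nemenyi_cd(4, 17)  # 1.1376
nemenyi_cd <- function(k, N, alpha = 0.05) {
  if (k < 2) stop("nemenyi_cd(): k must be >= 2", call. = FALSE)
  if (N < 1) stop("nemenyi_cd(): N must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha > 0.5) {
    stop("nemenyi_cd(): alpha must lie in (0, 0.5]", call. = FALSE)
  }
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Compare the four combination methods over 17 criteria
#'
#' Builds the combiner comparison: per-method mean and SD over repetitions
#' for the 16 metrics, plus a 17th criterion, the average SD across
#' repetitions (statistical stability, smaller is better). Runs the
#' Friedman test over the 17 criteria and, if significant, the Nemenyi
#' post-hoc critical difference.
#'
#' @param cv_result an `lk_cv_result`.
#' @param alpha significance level (default 0.05).
#' @return an `lk_comparison` with the criterion table, mean ranks,
#'   Friedman statistic/p, CD, and pairwise significance flags.
#' @export
compare_combiners <- function(cv_result, alpha = 0.05) {
  stopifnot(inherits(cv_result, "lk_cv_result"))
  cm <- cv_result$combiner_metrics
  methods <- c("average", "weighted", "majority", "soft_fusion")
  summ <- cm |>
    dplyr::group_by(.data$combiner, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value), .groups = "drop")
  mnames <- metric_names()
  mean_tab <- vapply(methods, function(m) {
    v <- summ$mean[match(paste(m, mnames), paste(summ$combiner, summ$metric))]
    v
  }, numeric(length(mnames)))
  sd_tab <- vapply(methods, function(m) {
    summ$sd[match(paste(m, mnames), paste(summ$combiner, summ$metric))]
  }, numeric(length(mnames)))
  avg_sd <- colMeans(sd_tab, na.rm = TRUE)
  values <- rbind(mean_tab, avg_sd)
  rownames(values) <- c(mnames, "avg_sd")
  dirs <- c(metric_directions()$direction, "zero")
  # a criterion can only be ranked if at least two methods have defined
  # values on it (e.g. the SD row is undefined with a single repetition)
  ok <- rowSums(is.finite(values)) >= 2
  if (any(!ok)) {
    warning("compare_combiners(): dropping unrankable criteria: ",
            paste(rownames(values)[!ok], collapse = ", "))
    values <- values[ok, , drop = FALSE]
    dirs <- dirs[ok]
  }
  ft <- friedman_rank_test(values, dirs)
  cd <- nemenyi_cd(length(methods), nrow(values), alpha)
  gap <- abs(outer(ft$mean_ranks, ft$mean_ranks, "-"))
  structure(
    list(criteria = values, sd_table = sd_tab, mean_ranks = ft$mean_ranks,
         friedman_statistic = ft$statistic, p_value = ft$p_value,
         cd = cd, alpha = alpha, significant = gap > cd,
         N = nrow(values), k = length(methods)),
    class = "lk_comparison"
  )
}
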