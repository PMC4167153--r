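#' The default 27-expert classifier bank
#'
#' Nine experts per color channel: three single-hidden-layer neural networks
#' (hidden sizes tuned per channel), a linear and a quadratic discriminant,
#' and four soft-margin SVMs (linear, quadratic, cubic polynomial, RBF) with
#' per-channel hyperparameters. The kernel forms are: linear `x.y`,
#' polynomial `(x.y + 1)^p`, RBF `exp(-||x - y||^2 / (2 tau^2))`.
#'
#' @return tibble with one row per expert: `id`, `channel`, `family`
#'   (`ANN`, `DA`, `SVM`), `variant`, `hidden`, `kernel`, `C`, `p`, `tau`.
#' @export
#' @examples
#' nrow(default_bank())  # 27
default_bank <- function() {
  ann_hidden <- list(R = c(2, 20, 50), G = c(3, 10, 15), B = c(2, 3, 5))
  svm_par <- list(
    R = list(lin_C = 7, quad_C = 4, poly_C = 0.5, rbf_C = 9, rbf_tau = 0.5),
    G = list(lin_C = 3, quad_C = 2, poly_C = 2, rbf_C = 33, rbf_tau = 2),
    B = list(lin_C = 2, quad_C = 1, poly_C = 2, rbf_C = 0.13, rbf_tau = 0.5)
  )
  rows <- purrr::map_dfr(c("R", "G", "B"), function(ch) {
    sp <- svm_par[[ch]]
    tibble::tibble(
      id = paste0(c("ANN_1", "ANN_2", "ANN_3", "DA_1", "DA_2",
                    "SVM_1", "SVM_2", "SVM_3", "SVM_4"), "@", ch),
      channel = ch,
      family = c("ANN", "ANN", "ANN", "DA", "DA", "SVM", "SVM", "SVM", "SVM"),
      variant = c("ANN_1", "ANN_2", "ANN_3", "DA_1", "DA_2",
                  "SVM_1", "SVM_2", "SVM_3", "SVM_4"),
      hidden = c(ann_hidden[[ch]], rep(NA_real_, 6)),
      kernel = c(rep(NA_character_, 5), "linear", "polynomial", "polynomial", "rbf"),
      C = c(rep(NA_real_, 5), sp$lin_C, sp$quad_C, sp$poly_C, sp$rbf_C),
      p = c(rep(NA_real_, 5), NA, 2, 3, NA),
      tau = c(rep(NA_real_, 5), NA, NA, NA, sp$rbf_tau)
    )
  })
  rows
}

# regularized Gaussian discriminant fit, used when MASS::lda/qda cannot
# handle a degenerate fold covariance (ridge 1e-6 * I)
fit_gauss_da <- function(X, d, quadratic, ridge = 1e-6) {
  cls <- c(-1, 1)
  prior <- vapply(cls, function(k) mean(d == k), numeric(1))
  mu <- lapply(cls, function(k) colMeans(X[d == k, , drop = FALSE]))
  covs <- lapply(cls, function(k) {
    Xi <- X[d == k, , drop = FALSE]
    if (nrow(Xi) < 2) matrix(0, ncol(X), ncol(X)) else stats::cov(Xi)
  })
  if (!quadratic) {
    ns <- vapply(cls, function(k) sum(d == k), numeric(1))
    pooled <- Reduce(`+`, Map(function(S, n) S * (n - 1), covs, ns)) /
      (sum(ns) - 2)
    covs <- list(pooled, pooled)
  }
  covs <- lapply(covs, function(S) S + diag(ridge, ncol(X)))
  list(prior = prior, mu = mu, cov = covs, classes = cls)
}

predict_gauss_da <- function(fit, X) {
  logd <- vapply(1:2, function(j) {
    S <- fit$cov[[j]]
    ic <- solve(S)
    dx <- sweep(X, 2, fit$mu[[j]])
    -0.5 * rowSums((dx %*% ic) * dx) - 0.5 * determinant(S)$modulus[1] +
      log(fit$prior[j])
  }, numeric(nrow(X)))
  if (nrow(X) == 1) logd <- matrix(logd, 1)
  m <- apply(logd, 1, max)
  p <- exp(logd - m)
  p / rowSums(p)   # columns: class -1, class +1
}

#' Train one expert on a channel's 2-D feature set
#'
#' @param spec one row of [default_bank()] (a one-row tibble or list).
#' @param X numeric n x 2 matrix of KLT features.
#' @param d targets in \{-1, +1\}; both classes must be present.
#' @param seed integer seed controlling stochastic training (ANN weight
#'   initialization); identical seed and data give identical fits.
#' @return an `lk_expert` with the fitted model and its spec.
#' @export
train_expert <- function(spec, X, d, seed = 1L) {
  spec <- as.list(spec)
  X <- as.matrix(X)
  if (ncol(X) != 2) stop("train_expert(): features must be 2-dimensional", call. = FALSE)
  if (length(unique(d)) < 2) {
    stop("train_expert(): training set for ", spec$id,
         " contains a single class; check the fold composition", call. = FALSE)
  }
  y <- factor(d, levels = c(-1, 1))
  fit <- switch(
    spec$family,
    ANN = withr::with_seed(as.integer(seed), {
      tgt <- cbind(`-1` = as.numeric(d == -1), `1` = as.numeric(d == 1))
      withCallingHandlers(
        nnet::nnet(x = X, y = tgt, size = spec$hidden, softmax = TRUE,
                   maxit = 300, trace = FALSE, MaxNWts = 5000),
        warning = function(w) {
          warning("ANN ", spec$id, ": ", conditionMessage(w), call. = FALSE)
          invokeRestart("muffleWarning")
        }
      )
    }),
    SVM = {
      args <- list(x = X, y = y, scale = FALSE, cost = spec$C, probability = FALSE)
      args <- c(args, switch(spec$kernel,
        linear = list(kernel = "linear"),
        polynomial = list(kernel = "polynomial", degree = spec$p,
                          gamma = 1, coef0 = 1),
        rbf = list(kernel = "radial", gamma = 1 / (2 * spec$tau^2))
      ))
      do.call(e1071::svm, args)
    },
    DA = {
      quadratic <- spec$variant == "DA_2"
      tryCatch({
        if (quadratic) MASS::qda(X, grouping = y) else MASS::lda(X, grouping = y)
      }, error = function(e) {
        warning("DA ", spec$id, ": ", conditionMessage(e),
                "; falling back to ridge-regularized Gaussian fit", call. = FALSE)
        fit_gauss_da(X, d, quadratic)
      })
    },
    stop("train_expert(): unknown family ", spec$family, call. = FALSE)
  )
  structure(list(spec = spec, fit = fit, seed = as.integer(seed)),
            class = "lk_expert")
}

#' Certainty of a trained expert
#'
#' Maps an expert's raw output to a complementary pair of class certainties
#' in [0,1]: softmax outputs for the neural networks, Gaussian posterior
#' probabilities for the discriminants, and a unit-slope logistic of the
#' signed SVM decision value (oriented so positive favors the leukocoric
#' class). Always `h_pos + h_neg = 1`.
#'
#' @param expert an `lk_expert`.
#' @param X numeric matrix (n x 2) or length-2 vector of features.
#' @return n x 2 matrix with columns `h_pos`, `h_neg`.
#' @export
certainty <- function(expert, X) {
  stopifnot(inherits(expert, "lk_expert"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("certainty(): non-finite features", call. = FALSE)
  fit <- expert$fit
  h_pos <- switch(
    expert$spec$family,
    ANN = {
      pr <- stats::predict(fit, X)
      pr[, "1"]
    },
    SVM = {
      pv <- stats::predict(fit, X, decision.values = TRUE)
      f <- drop(attr(pv, "decision.values"))
      # libsvm's decision value is positive for the class named first in
      # the column label; orient so positive always favors class +1
      lab <- colnames(attr(pv, "decision.values"))[1]
      if (startsWith(lab, "-1")) f <- -f
      stats::plogis(f)
    },
    DA = {
      if (inherits(fit, c("lda", "qda"))) {
        stats::predict(fit, X)$posterior[, "1"]
      } else {
        predict_gauss_da(fit, X)[, 2]
      }
    }
  )
  h_pos <- pmin(1, pmax(0, unname(h_pos)))
  cbind(h_pos = h_pos, h_neg = 1 - h_pos)
}

#' Train a full expert bank
#'
#' Trains every expert of `bank` on the features of its own color channel.
#'
#' @param features tibble from [preprocess_features()] (training rows only).
#' @param bank expert specification tibble (default [default_bank()]).
#' @param seed base seed; each expert trains with a seed derived from it
#'   and the expert's position, so refits are reproducible.
#' @return an `lk_bank`: list of `lk_expert` keyed by id, plus the spec.
#' @export
train_bank <- function(features, bank = default_bank(), seed = 1L) {
  experts <- purrr::map(seq_len(nrow(bank)), function(i) {
    sp <- bank[i, ]
    fx <- features[features$channel == sp$channel, ]
    train_expert(sp, cbind(fx$x1, fx$x2), fx$label,
                 seed = as.integer(seed) + i * 131L)
  })
  names(experts) <- bank$id
  structure(list(experts = experts, bank = bank, seed = as.integer(seed)),
            class = "lk_bank")
}

#' Per-expert positive-class certainties for a feature set
#'
#' @param trained an `lk_bank`.
#' @param features tibble from [preprocess_features()]; must contain all
#'   three channels for the same image ids.
#' @return list with `h_pos` (n_images x 27 matrix, columns in bank order),
#'   `ids` (image ids) and `d` (targets).
#' @export
bank_certainties <- function(trained, features) {
  stopifnot(inherits(trained, "lk_bank"))
  by_ch <- split(features, features$channel)
  ids <- by_ch[[1]]$id
  h <- vapply(seq_len(nrow(trained$bank)), function(i) {
    sp <- trained$bank[i, ]
    fx <- by_ch[[sp$channel]]
    if (!identical(fx$id, ids)) fx <- fx[match(ids, fx$id), ]
    certainty(trained$experts[[sp$id]], cbind(fx$x1, fx$x2))[, "h_pos"]
  }, numeric(length(ids)))
  if (length(ids) == 1) h <- matrix(h, 1)
  colnames(h) <- trained$bank$id
  list(h_pos = h, ids = ids, d = by_ch[[1]]$label[match(ids, by_ch[[1]]$id)])
}
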