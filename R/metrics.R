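#' Confusion counts for binary predictions
#'
#' Cross-tabulates predicted against actual classes with +1 as the positive
#' (leukocoric) class.
#'
#' @param labels predicted classes in \{-1, +1\}.
#' @param d true classes in \{-1, +1\}.
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, d) {
  if (length(labels) == 0 || length(labels) != length(d)) {
    stop("confusion(): labels and d must be nonempty and aligned", call. = FALSE)
  }
  if (!all(labels %in% c(-1, 1)) || !all(d %in% c(-1, 1))) {
    stop("confusion(): classes must be coded -1/+1", call. = FALSE)
  }
  list(TP = sum(labels == 1 & d == 1), TN = sum(labels == -1 & d == -1),
       FP = sum(labels == 1 & d == -1), FN = sum(labels == -1 & d == 1))
}

#' Residual-error metrics
#'
#' RMSE, NRMSE (RMSE divided by the sample standard deviation of the
#' continuous outputs), the absolute mean residual, and the sample standard
#' deviation of the residuals (n-1 divisor), for continuous outputs `y`
#' in [-1,1] against targets `d` in \{-1,+1\}.
#'
#' @param y continuous classifier outputs.
#' @param d targets in \{-1, +1\}.
#' @return named list: `RMSE`, `NRMSE` (NA when sd(y) = 0), `abs_mu_eps`,
#'   `sigma_eps`.
#' @export
residual_metrics <- function(y, d) {
  if (length(y) == 0 || length(y) != length(d)) {
    stop("residual_metrics(): y and d must be nonempty and aligned", call. = FALSE)
  }
  eps <- y - d
  rmse <- sqrt(mean(eps^2))
  sdy <- stats::sd(y)
  nrmse <- if (length(y) > 1 && sdy > 0) rmse / sdy else NA_real_
  sigma_eps <- if (length(y) > 1) stats::sd(eps) else 0
  list(RMSE = rmse, NRMSE = nrmse, abs_mu_eps = abs(mean(eps)),
       sigma_eps = sigma_eps)
}

# safe ratio: NA (undefined) on zero denominator instead of NaN/Inf
ratio_ <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix metrics
#'
#' The ten ratio metrics of the evaluation protocol: accuracy, true/false
#' positive rate, specificity, positive/negative predictive value, false
#' discovery rate, Matthews correlation, F1 score and balanced error rate.
#' Zero-denominator cells are returned as `NA` (undefined) rather than
#' coerced to a number.
#'
#' @param cm list from [confusion()].
#' @return named list of the ten metrics.
#' @export
confusion_metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  tot <- TP + TN + FP + FN
  if (tot == 0) stop("confusion_metrics(): empty confusion counts", call. = FALSE)
  tpr <- ratio_(TP, TP + FN)
  fpr <- ratio_(FP, FP + TN)
  ppv <- ratio_(TP, TP + FP)
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  f1 <- if (is.na(ppv) || is.na(tpr) || (ppv + tpr) == 0) NA_real_ else
    2 * ppv * tpr / (ppv + tpr)
  ber <- if (any(is.na(c(fpr, tpr)))) NA_real_ else 0.5 * (fpr + (1 - tpr))
  list(
    ACC = (TP + TN) / tot,
    TPR = tpr,
    FPR = fpr,
    SPC = ratio_(TN, FP + TN),
    PPV = ppv,
    NPV = ratio_(TN, TN + FN),
    FDR = ratio_(FP, FP + TP),
    MCC = if (mcc_den == 0) NA_real_ else
      (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den,
    F1 = f1,
    BER = ber
  )
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive scores above a
#' random negative, with ties counting one half.
#'
#' @param scores positive-class certainties in [0, 1].
#' @param d targets in \{-1, +1\}; both classes must be present for a
#'   defined value.
#' @return AUC in [0, 1], or `NA` if one class is absent.
#' @export
auc_rank <- function(scores, d) {
  if (length(scores) != length(d)) stop("auc_rank(): length mismatch", call. = FALSE)
  n_pos <- sum(d == 1); n_neg <- sum(d == -1)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[d == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products. Reported unclamped (kappa can be
#' negative for worse-than-chance prediction).
#'
#' @param cm list from [confusion()].
#' @return kappa, or `NA` when expected agreement equals 1.
#' @export
kappa_cohen <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  tot <- TP + TN + FP + FN
  if (tot == 0) stop("kappa_cohen(): empty confusion counts", call. = FALSE)
  p_o <- (TP + TN) / tot
  p_e <- ((TP + FP) / tot) * ((TP + FN) / tot) +
    ((TN + FN) / tot) * ((TN + FP) / tot)
  if (abs(1 - p_e) < 1e-15) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' All sixteen performance metrics for one prediction set
#'
#' @param y continuous outputs in [-1, 1] (`2 h_pos - 1`).
#' @param labels hard predictions in \{-1, +1\}.
#' @param scores positive-class certainties in [0, 1] (for AUC).
#' @param d targets in \{-1, +1\}.
#' @return one-row tibble with the 16 metric columns.
#' @export
metric_vector <- function(y, labels, scores, d) {
  rm_ <- residual_metrics(y, d)
  cm <- confusion(labels, d)
  cmm <- confusion_metrics(cm)
  tibble::as_tibble(c(rm_, cmm,
                      list(AUC = auc_rank(scores, d), kappa = kappa_cohen(cm))))
}

#' Names of the sixteen metrics in report order
#' @return character vector.
#' @export
metric_names <- function() {
  c("RMSE", "NRMSE", "abs_mu_eps", "sigma_eps", "ACC", "TPR", "FPR", "SPC",
    "PPV", "NPV", "FDR", "MCC", "F1", "BER", "AUC", "kappa")
}
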