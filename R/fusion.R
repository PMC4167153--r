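#' Construct a fuzzy density vector
#'
#' Densities are the measures of the singleton sets: the importance each
#' expert carries in the fusion. All must lie in (0, 1).
#'
#' @param g numeric vector of densities, optionally named by expert id.
#' @return an `lk_densities` (named numeric vector).
#' @export
fuzzy_densities <- function(g) {
  g <- unlist(g)
  if (length(g) < 1 || any(!is.finite(g)) || any(g <= 0) || any(g >= 1)) {
    stop("fuzzy_densities(): densities must all lie strictly in (0, 1)",
         call. = FALSE)
  }
  structure(as.numeric(g), names = names(g), class = "lk_densities")
}

#' Solve for the measure parameter lambda
#'
#' The g-lambda fuzzy measure requires the unique lambda > -1 satisfying
#' `lambda + 1 = prod_i (1 + lambda * g_i)`. When the densities sum to one
#' the unique root is 0 and the measure is additive; when they sum to less
#' than one the root is positive; when they sum to more than one it lies in
#' (-1, 0). Solved by bracketing plus Newton polishing to a residual below
#' 1e-12.
#'
#' @param g densities in (0,1) (an [fuzzy_densities()] or plain vector).
#' @return lambda (numeric scalar).
#' @export
#' @examples
#' solve_lambda(c(0.5, 0.5))  # 0: additive measure
#' solve_lambda(c(0.3, 0.3))  # (1 - 0.6) / 0.09 = 4.444...
solve_lambda <- function(g) {
  g <- as.numeric(g)
  if (any(g <= 0) || any(g >= 1)) {
    stop("solve_lambda(): densities must lie strictly in (0, 1)", call. = FALSE)
  }
  s <- sum(g)
  if (abs(s - 1) < 1e-9) return(0)
  f <- function(lam) prod(1 + lam * g) - (1 + lam)
  fp <- function(lam) {
    terms <- 1 + lam * g
    prod(terms) * sum(g / terms) - 1
  }
  # lambda = 0 is always a root of f; divide it out so the nonzero root
  # stays well-conditioned even when sum(g) is close to 1
  q <- function(lam) if (lam == 0) s - 1 else f(lam) / lam
  if (s < 1) {           # unique positive root: q(0) < 0, q(hi) > 0
    hi <- 1
    while (q(hi) < 0) hi <- hi * 2
    lam <- stats::uniroot(q, c(0, hi), tol = 1e-15)$root
  } else {               # unique root in (-1, 0): q(-1+eps) < 0, q(0) > 0
    lam <- stats::uniroot(q, c(-1 + 1e-12, 0), tol = 1e-15)$root
  }
  for (k in 1:8) {        # Newton polish on f to machine residual
    step <- f(lam) / fp(lam)
    if (!is.finite(step) || abs(step) > abs(lam) + 1) break
    lam2 <- lam - step
    if (lam2 <= -1) break
    lam <- lam2
    if (abs(f(lam)) < 1e-15) break
  }
  lam
}

# measure of an arbitrary subset under the g-lambda closed form
# g(E) = (prod_{i in E} (1 + lambda g_i) - 1) / lambda, or sum for lambda=0
measure_subset <- function(g, lambda, idx) {
  if (length(idx) == 0) return(0)
  if (lambda == 0) return(sum(g[idx]))
  (prod(1 + lambda * g[idx]) - 1) / lambda
}

#' Measure chain over nested expert coalitions
#'
#' Given densities already sorted by descending certainty, returns the
#' measures of the nested sets A_i = \{top i experts\} via the recursion
#' `g(A_1) = g_1`, `g(A_i) = g_i + g(A_{i-1}) + lambda g_i g(A_{i-1})`.
#' The final value must equal 1 (the whole-set axiom); a mismatch beyond
#' 1e-6 signals an inconsistent lambda and raises an error.
#'
#' @param g densities sorted in the fusion order.
#' @param lambda measure parameter from [solve_lambda()] on the same
#'   (complete) density vector.
#' @return numeric vector `g(A_1), ..., g(A_n)`, nondecreasing, ending at 1.
#' @export
measure_chain <- function(g, lambda) {
  g <- as.numeric(g)
  n <- length(g)
  out <- numeric(n)
  out[1] <- g[1]
  if (n > 1) {
    for (i in 2:n) out[i] <- g[i] + out[i - 1] + lambda * g[i] * out[i - 1]
  }
  if (abs(out[n] - 1) > 1e-6) {
    stop("measure_chain(): chain terminates at ", format(out[n]),
         " instead of 1; lambda is inconsistent with these densities",
         call. = FALSE)
  }
  out
}

#' Sugeno fuzzy integral of expert certainties
#'
#' Sorts the experts by descending certainty (ties broken by density, then
#' by position) and evaluates `max_i min(h_(i), g(A_i))` where A_i is the
#' coalition of the i top-ranked experts under the g-lambda measure. This
#' is the fused confidence that the evidence supports the class.
#'
#' @param h certainties in [0,1], aligned with `g`.
#' @param g densities in (0,1), one per expert.
#' @param lambda optional precomputed measure parameter; solved from `g`
#'   when omitted.
#' @return scalar integral value in [0, 1].
#' @export
sugeno_integral <- function(h, g, lambda = NULL) {
  h <- as.numeric(h); g <- as.numeric(g)
  if (length(h) != length(g)) {
    stop("sugeno_integral(): h and g lengths differ", call. = FALSE)
  }
  if (any(h < 0 | h > 1)) stop("sugeno_integral(): h outside [0,1]", call. = FALSE)
  if (is.null(lambda)) lambda <- solve_lambda(g)
  ord <- order(-h, -g, seq_along(h))
  chain <- measure_chain(g[ord], lambda)
  max(pmin(h[ord], chain))
}

#' Brute-force fuzzy integral by subset enumeration
#'
#' Direct evaluation of `max over nonempty E of min(min_{y in E} h(y),
#' g(E))` with subset measures from the g-lambda closed form. Exponential in
#' n; intended as an independent oracle for [sugeno_integral()] in tests.
#'
#' @inheritParams sugeno_integral
#' @return scalar integral value.
#' @export
brute_force_integral <- function(h, g, lambda = NULL) {
  h <- as.numeric(h); g <- as.numeric(g)
  n <- length(h)
  if (n > 12) stop("brute_force_integral(): n > 12 not supported", call. = FALSE)
  if (is.null(lambda)) lambda <- solve_lambda(g)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    v <- min(min(h[idx]), measure_subset(g, lambda, idx))
    if (v > best) best <- v
  }
  best
}

#' Fuse a full bank's certainty pairs into a class decision
#'
#' Computes the fuzzy integral of the positive-class certainties and of the
#' complementary negative-class certainties, and decides for the class with
#' the larger integral (ties go to +1, leukocoric: in screening a false
#' negative is costlier than a false positive).
#'
#' @param h_pos positive-class certainties, one per expert, aligned to `g`.
#' @param g densities (one per expert).
#' @param lambda optional precomputed lambda.
#' @return list with `class` (+1/-1), `e_pos`, `e_neg`.
#' @export
fuse_predict <- function(h_pos, g, lambda = NULL) {
  h_pos <- as.numeric(h_pos)
  if (length(h_pos) != length(g)) {
    stop("fuse_predict(): expected one certainty pair per expert (",
         length(g), "), got ", length(h_pos), call. = FALSE)
  }
  if (is.null(lambda)) lambda <- solve_lambda(g)
  e_pos <- sugeno_integral(h_pos, g, lambda)
  e_neg <- sugeno_integral(1 - h_pos, g, lambda)
  list(class = if (e_pos >= e_neg) 1L else -1L, e_pos = e_pos, e_neg = e_neg)
}

#' Baseline combiners: average, weighted average, majority vote
#'
#' `combine_average()` takes the sign of the mean continuous output
#' `y = 2 h_pos - 1`; `combine_weighted()` the sign of the density-weighted
#' sum; `combine_majority()` the modal hard label. All ties resolve to +1.
#'
#' @param y continuous outputs in [-1, 1] (average / weighted).
#' @param g densities (weighted average only).
#' @param labels hard labels in \{-1, +1\} (majority only).
#' @return predicted class, +1 or -1.
#' @export
combine_average <- function(y) {
  if (length(y) == 0) stop("combine_average(): empty input", call. = FALSE)
  if (mean(y) >= 0) 1L else -1L
}

#' @rdname combine_average
#' @export
combine_weighted <- function(y, g) {
  if (length(y) == 0) stop("combine_weighted(): empty input", call. = FALSE)
  if (length(y) != length(g)) stop("combine_weighted(): length mismatch", call. = FALSE)
  if (sum(as.numeric(g) * y) >= 0) 1L else -1L
}

#' @rdname combine_average
#' @export
combine_majority <- function(labels) {
  if (length(labels) == 0) stop("combine_majority(): empty input", call. = FALSE)
  if (!all(labels %in% c(-1, 1))) {
    stop("combine_majority(): labels must be -1/+1", call. = FALSE)
  }
  if (sum(labels == 1) >= sum(labels == -1)) 1L else -1L
}
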