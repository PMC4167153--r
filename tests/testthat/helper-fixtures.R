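# shared fixtures: all built in code at test time

# an easy, nearly-clean synthetic dataset (well-separated classes): large
# crops, calm illumination, steady gaze, little noise
easy_config <- function(n_pos = 12, n_neg = 18, seed = 42) {
  synth_config(n_positive = n_pos, n_negative = n_neg,
               size_min = 40, size_max = 100,
               illumination_offset_range = 0.03,
               illumination_gradient_range = 0.05,
               noise_sd = 0.02, gaze_jitter = 0.08, seed = seed)
}

# a reduced expert bank (3 deterministic experts per channel) for fast
# cross-validation tests; spec rows come straight from default_bank()
small_bank <- function() {
  b <- default_bank()
  b[b$variant %in% c("DA_1", "SVM_1", "SVM_3"), ]
}

# brute-force double-sum forward DCT (independent oracle for dct2)
dct2_bruteforce <- function(x) {
  M <- nrow(x); N <- ncol(x)
  a <- function(k, n) if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, M, N)
  for (k1 in 0:(M - 1)) for (k2 in 0:(N - 1)) {
    s <- 0
    for (n1 in 0:(M - 1)) for (n2 in 0:(N - 1)) {
      s <- s + x[n1 + 1, n2 + 1] *
        cos(pi / M * (n1 + 0.5) * k1) * cos(pi / N * (n2 + 0.5) * k2)
    }
    out[k1 + 1, k2 + 1] <- a(k1, M) * a(k2, N) * s
  }
  out
}

# brute-force double-sum inverse DCT (independent oracle for idct2)
idct2_bruteforce <- function(co) {
  M <- nrow(co); N <- ncol(co)
  a <- function(k, n) if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, M, N)
  for (n1 in 0:(M - 1)) for (n2 in 0:(N - 1)) {
    s <- 0
    for (k1 in 0:(M - 1)) for (k2 in 0:(N - 1)) {
      s <- s + a(k1, M) * a(k2, N) * co[k1 + 1, k2 + 1] *
        cos(pi / M * (n1 + 0.5) * k1) * cos(pi / N * (n2 + 0.5) * k2)
    }
    out[n1 + 1, n2 + 1] <- s
  }
  out
}

# random density vector strictly inside (0, 1), sum varying around 1
random_densities <- function(n) {
  raw <- stats::runif(n)
  target <- stats::runif(1, 0.4, 1.6)
  pmin(pmax(target * raw / sum(raw), 1e-3), 0.95)
}
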