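#' Orthonormal DCT-II basis matrix
#'
#' Rows are the orthonormal type-II discrete cosine basis functions of length
#' `n`: row `k + 1` is `a(k) * cos(pi/n * (0:(n-1) + 1/2) * k)` with
#' `a(0) = sqrt(1/n)` and `a(k) = sqrt(2/n)` otherwise, so the matrix is
#' orthogonal and the forward/inverse pair is exactly unitary.
#'
#' @param n transform length (>= 1).
#' @return an `n x n` orthogonal matrix.
#' @keywords internal
dct_matrix <- function(n) {
  stopifnot(n >= 1)
  k <- 0:(n - 1)
  m <- 0:(n - 1)
  alpha <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  outer(k, m, function(k, m) cos(pi / n * (m + 0.5) * k)) * alpha
}

#' Forward 2D discrete cosine transform
#'
#' Computes the orthonormal 2D DCT-II of a real matrix. Scaling is
#' dimension-appropriate (`sqrt(1/M)`/`sqrt(2/M)` along rows, `sqrt(1/N)`/
#' `sqrt(2/N)` along columns) so that [idct2()] is its exact inverse and
#' Parseval energy is preserved. Coefficient `(0,0)` (R index `[1, 1]`)
#' carries the image mean times `sqrt(M * N)`; coefficients `(0,1)` and
#' `(1,0)` carry the lowest horizontal and vertical variation — together
#' the constant-plus-linear illumination component.
#'
#' @param x real matrix (M x N, M and N >= 2) of pixel values.
#' @return matrix of DCT coefficients, same shape as `x`.
#' @seealso [idct2()], [discard_illumination()]
#' @export
#' @examples
#' co <- dct2(matrix(1, 4, 4))
#' co[1, 1]          # 4: the DC term of a constant image
#' max(abs(co[-1]))  # all other coefficients vanish
dct2 <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("dct2() requires an image of at least 2 x 2 pixels, got ",
         nrow(x), " x ", ncol(x), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("dct2(): image contains non-finite pixels", call. = FALSE)
  dct_matrix(nrow(x)) %*% x %*% t(dct_matrix(ncol(x)))
}

#' Inverse 2D discrete cosine transform
#'
#' Exact inverse of [dct2()] (the basis matrices are orthogonal, so the
#' inverse is the transpose pair).
#'
#' @param coeffs matrix of DCT coefficients.
#' @return real matrix of pixel values, same shape.
#' @export
idct2 <- function(coeffs) {
  coeffs <- as.matrix(coeffs)
  if (!all(is.finite(coeffs))) {
    stop("idct2(): coefficients contain non-finite values", call. = FALSE)
  }
  t(dct_matrix(nrow(coeffs))) %*% coeffs %*% dct_matrix(ncol(coeffs))
}

#' Zero the three lowest-frequency DCT coefficients
#'
#' Illumination correction: sets the coefficients at positions
#' (0,0), (0,1) and (1,0) to zero and leaves everything else untouched.
#' These three coefficients capture the constant offset and the lowest
#' horizontal/vertical gradients, so reconstructing the image without them
#' removes additive illumination offsets and (approximately) linear
#' illumination ramps.
#'
#' @param coeffs matrix of DCT coefficients (at least 2 x 2).
#' @return coefficient matrix with the three entries zeroed.
#' @export
discard_illumination <- function(coeffs) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) < 2 || ncol(coeffs) < 2) {
    stop("discard_illumination() needs at least a 2 x 2 coefficient matrix",
         call. = FALSE)
  }
  coeffs[1, 1] <- 0
  coeffs[1, 2] <- 0
  coeffs[2, 1] <- 0
  coeffs
}

# 1D resampling weight matrix (n_out x n_in), rows summing to 1.
# Downsampling: area averaging over [j*s, (j+1)*s) in input-pixel units.
# Upsampling (or equal size): linear interpolation between pixel centers,
# clamped at the borders. Both preserve constant signals exactly, and equal
# sizes give the identity.
resample_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  if (n_out == n_in) {
    diag(w) <- 1
    return(w)
  }
  if (n_out < n_in) {
    s <- n_in / n_out
    for (j in seq_len(n_out)) {
      lo <- (j - 1) * s
      hi <- j * s
      first <- floor(lo) + 1
      last <- min(ceiling(hi), n_in)
      for (i in first:last) {
        overlap <- min(hi, i) - max(lo, i - 1)
        if (overlap > 0) w[j, i] <- overlap / s
      }
    }
  } else {
    # centers of output pixels mapped into input pixel-center coordinates
    s <- n_in / n_out
    centers <- ((seq_len(n_out) - 0.5) * s) - 0.5
    centers <- pmin(pmax(centers, 0), n_in - 1)
    for (j in seq_len(n_out)) {
      c0 <- centers[j]
      i0 <- floor(c0)
      frac <- c0 - i0
      if (i0 >= n_in - 1) {
        w[j, n_in] <- 1
      } else {
        w[j, i0 + 1] <- 1 - frac
        w[j, i0 + 2] <- frac
      }
    }
  }
  w
}

#' Resample an image to a fixed square size
#'
#' Separable resampling used to bring every corrected eye image to the common
#' working resolution (32 x 32 by default). Downsampling uses exact area
#' averaging (anti-aliasing); upsampling uses bilinear interpolation between
#' pixel centers. Constant images are preserved exactly and an input already
#' at the target size is returned unchanged.
#'
#' @param x real matrix (M x N, both >= 2).
#' @param side target side length in pixels (default 32).
#' @return a `side x side` matrix.
#' @export
resample_to_fixed <- function(x, side = 32) {
  x <- as.matrix(x)
  if (side < 2) stop("resample_to_fixed(): side must be >= 2", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("resample_to_fixed() requires at least a 2 x 2 image", call. = FALSE)
  }
  wr <- resample_weights(nrow(x), side)
  wc <- resample_weights(ncol(x), side)
  wr %*% x %*% t(wc)
}
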