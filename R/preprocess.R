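#' Illumination-correct one channel image at native size
#'
#' Forward DCT, discard of the (0,0), (0,1) and (1,0) coefficients, inverse
#' DCT — i.e. the image minus its constant-plus-lowest-frequency
#' illumination component, computed at the image's native resolution.
#'
#' @param x real M x N matrix (one color channel).
#' @return corrected matrix, same shape.
#' @export
correct_illumination <- function(x) {
  idct2(discard_illumination(dct2(x)))
}

#' Fit per-pixel z-scoring statistics
#'
#' Per-pixel mean and standard deviation images over a training set of
#' fixed-size channel images. The standard deviation is floored at `eps` so
#' that degenerate (constant) pixels map to zero rather than infinity.
#' Statistics must come from training images only; test images are always
#' standardized with a training-fitted model.
#'
#' @param images list of numeric matrices, all the same shape (>= 2 images).
#' @param eps positive floor for the standard deviation (default 1e-8).
#' @return an `lk_normalizer` with `mean` and `sd` matrices.
#' @export
fit_normalizer <- function(images, eps = 1e-8) {
  if (length(images) < 2) {
    stop("fit_normalizer() needs at least 2 training images", call. = FALSE)
  }
  dm <- dim(images[[1]])
  flat <- do.call(rbind, lapply(images, as.vector))
  mu <- colMeans(flat)
  sd_ <- apply(flat, 2, stats::sd)
  sd_ <- pmax(sd_, eps)
  structure(list(mean = matrix(mu, dm[1], dm[2]),
                 sd = matrix(sd_, dm[1], dm[2]), eps = eps),
            class = "lk_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param norm an `lk_normalizer`.
#' @param x matrix of the shape the normalizer was fitted on.
#' @return standardized matrix.
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "lk_normalizer"))
  (x - norm$mean) / norm$sd
}

#' Fit a 2-component Karhunen-Loeve basis
#'
#' Eigendecomposition of the training covariance of flattened images,
#' keeping the two leading eigenvectors. Each basis vector's sign is fixed
#' so its largest-magnitude entry is positive, making projections
#' deterministic across platforms. Projections are whitened: each component
#' is divided by the square root of its eigenvalue, so features have unit
#' training variance per component and the expert hyperparameters (kernel
#' widths in particular) are commensurate with the feature scale.
#'
#' @param images list of standardized matrices (>= 3), all the same shape.
#' @return an `lk_klt` with `basis` (d x 2, orthonormal columns),
#'   `eigenvalues` (length 2, descending), `sdev` (their square roots, the
#'   whitening scales), and `center` (length-d mean).
#' @export
fit_klt <- function(images) {
  if (length(images) < 3) stop("fit_klt() needs at least 3 training images", call. = FALSE)
  flat <- do.call(rbind, lapply(images, as.vector))
  fit_klt_matrix(flat)
}

# internal: KLT on an n x d matrix of flattened images
fit_klt_matrix <- function(flat) {
  if (nrow(flat) < 3) stop("fit_klt() needs at least 3 training samples", call. = FALSE)
  if (max(apply(flat, 2, stats::var)) < 1e-24) {
    stop("fit_klt(): training images are all identical (rank-0 covariance)",
         call. = FALSE)
  }
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE, rank. = 2)
  basis <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (basis[which.max(abs(basis[, j])), j] < 0) basis[, j] <- -basis[, j]
  }
  ev <- unname(pc$sdev[1:2]^2)
  structure(list(basis = unname(basis),
                 eigenvalues = ev,
                 sdev = pmax(sqrt(ev), 1e-12),
                 center = unname(pc$center)),
            class = "lk_klt")
}

#' Project a standardized image onto a fitted KLT basis
#'
#' @param klt an `lk_klt`.
#' @param x standardized matrix (or flat vector) of matching dimension.
#' @param whiten divide each component by its training standard deviation
#'   (default `TRUE`; `FALSE` gives the raw orthogonal projection).
#' @return numeric length-2 feature vector.
#' @export
apply_klt <- function(klt, x, whiten = TRUE) {
  stopifnot(inherits(klt, "lk_klt"))
  pr <- drop(crossprod(klt$basis, as.vector(x) - klt$center))
  if (whiten) pr <- pr / klt$sdev
  pr
}

# internal: per-channel illumination-corrected + resampled flat matrices
# for a whole dataset; these depend only on each image, never on a training
# split, so they can be computed once and reused across CV folds.
corrected_stack <- function(dataset, side = 32) {
  n <- nrow(dataset)
  out <- lapply(1:3, function(ch) {
    m <- matrix(0, n, side * side)
    for (i in seq_len(n)) {
      x <- dataset$image[[i]]$pixels[, , ch]
      m[i, ] <- as.vector(resample_to_fixed(correct_illumination(x), side))
    }
    m
  })
  names(out) <- c("R", "G", "B")
  out
}

# internal: fit per-channel normalizer + KLT on the rows `idx` of a
# corrected stack
fit_prep_on_stack <- function(stack, idx, side = 32, eps = 1e-8) {
  channels <- lapply(stack, function(m) {
    tr <- m[idx, , drop = FALSE]
    mu <- colMeans(tr)
    sd_ <- pmax(apply(tr, 2, stats::sd), eps)
    z <- sweep(sweep(tr, 2, mu), 2, sd_, "/")
    list(mean = mu, sd = sd_, klt = fit_klt_matrix(z))
  })
  structure(list(channels = channels, side = side, eps = eps,
                 n_train = length(idx)),
            class = "lk_preprocessor")
}

# internal: project rows `idx` of a corrected stack through a fitted
# preprocessor; returns a list of n x 2 matrices per channel
project_stack <- function(stack, prep, idx) {
  lapply(stats::setNames(names(stack), names(stack)), function(ch) {
    m <- stack[[ch]][idx, , drop = FALSE]
    p <- prep$channels[[ch]]
    z <- sweep(sweep(m, 2, p$mean), 2, p$sd, "/")
    zc <- sweep(z, 2, p$klt$center)
    sweep(unname(zc %*% p$klt$basis), 2, p$klt$sdev, "/")
  })
}

#' Fit the full preprocessing model on a training dataset
#'
#' For each color channel: illumination-correct every training image at its
#' native size, resample to `side x side`, fit per-pixel z-scoring
#' statistics, and fit a 2-component KLT basis on the standardized images.
#'
#' @param dataset tibble from [generate_dataset()] or [read_eye_dataset()]
#'   (rows used for fitting).
#' @param side working resolution (default 32).
#' @param eps standard-deviation floor for z-scoring.
#' @return an `lk_preprocessor` holding per-channel normalizer and KLT.
#' @export
fit_preprocessor <- function(dataset, side = 32, eps = 1e-8) {
  stack <- corrected_stack(dataset, side)
  fit_prep_on_stack(stack, seq_len(nrow(dataset)), side, eps)
}

#' Extract 2-component features for one channel of one image
#'
#' Applies, in order: channel split, forward DCT, discard of the three
#' illumination coefficients, inverse DCT, resampling to the working
#' resolution, z-scoring with training statistics, and KLT projection.
#'
#' @param eye an `eye_image`.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param prep a fitted `lk_preprocessor`.
#' @return numeric length-2 feature vector.
#' @export
preprocess_channel <- function(eye, channel, prep) {
  if (!inherits(prep, "lk_preprocessor")) {
    stop("preprocess_channel(): prep must be a fitted lk_preprocessor", call. = FALSE)
  }
  channel <- match.arg(channel, c("R", "G", "B"))
  ch <- match(channel, c("R", "G", "B"))
  x <- resample_to_fixed(correct_illumination(eye$pixels[, , ch]), prep$side)
  p <- prep$channels[[channel]]
  z <- (as.vector(x) - p$mean) / p$sd
  apply_klt(p$klt, z)
}

#' Extract features for every image and channel of a dataset
#'
#' @param dataset tibble of eye images.
#' @param prep fitted `lk_preprocessor`.
#' @return tibble with columns `id`, `label`, `channel`, `x1`, `x2`.
#' @export
preprocess_features <- function(dataset, prep) {
  stack <- corrected_stack(dataset, prep$side)
  proj <- project_stack(stack, prep, seq_len(nrow(dataset)))
  purrr::map_dfr(names(proj), function(ch) {
    tibble::tibble(id = dataset$id, label = dataset$label, channel = ch,
                   x1 = proj[[ch]][, 1], x2 = proj[[ch]][, 2])
  })
}
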