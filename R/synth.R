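#' Configuration for the synthetic eye-image generator
#'
#' Describes a synthetic database of cropped eye images mirroring the
#' composition of the screening collection the pipeline targets: 54
#' leukocoric ("white pupil") and 90 healthy eyes, square crops from 19 to
#' 138 pixels a side, uncontrolled illumination, varied iris color and gaze.
#'
#' @param n_positive,n_negative number of leukocoric / healthy images
#'   (defaults 54 and 90, i.e. a 37.5% positive class).
#' @param size_min,size_max smallest and largest crop side in pixels
#'   (defaults 19 and 138).
#' @param illumination_offset_range half-width of the uniform additive
#'   intensity offset applied to a whole image, in [0,1] intensity units
#'   (default 0.60). An offset of `b` shifts every pixel of every channel
#'   by `b`; large offsets saturate against the [0,1] clip, emulating
#'   over/under-exposed flash photographs.
#' @param illumination_gradient_range maximum total intensity change of the
#'   linear illumination ramp across the full crop width, in [0,1] intensity
#'   units (default 1.5); ramp direction is uniform on the circle.
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise added
#'   per channel, in intensity units (default 0.45).
#' @param gaze_jitter maximum displacement of the pupil center, as a
#'   fraction of the iris radius (default 0.25).
#' @param seed integer seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_positive = 54, n_negative = 90,
                         size_min = 19, size_max = 138,
                         illumination_offset_range = 0.60,
                         illumination_gradient_range = 1.5,
                         noise_sd = 0.45,
                         gaze_jitter = 0.25,
                         seed = 1L) {
  if (n_positive < 1 || n_negative < 1) {
    stop("synth_config(): n_positive and n_negative must both be >= 1",
         call. = FALSE)
  }
  if (size_min > size_max) stop("synth_config(): size_min > size_max", call. = FALSE)
  if (size_min < 8) stop("synth_config(): size_min must be >= 8 pixels", call. = FALSE)
  if (noise_sd < 0) stop("synth_config(): noise_sd must be >= 0", call. = FALSE)
  if (illumination_offset_range < 0 || illumination_gradient_range < 0) {
    stop("synth_config(): illumination ranges must be >= 0", call. = FALSE)
  }
  if (gaze_jitter < 0 || gaze_jitter > 1) {
    stop("synth_config(): gaze_jitter must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_positive = as.integer(n_positive),
         n_negative = as.integer(n_negative),
         size_min = as.integer(size_min), size_max = as.integer(size_max),
         illumination_offset_range = illumination_offset_range,
         illumination_gradient_range = illumination_gradient_range,
         noise_sd = noise_sd, gaze_jitter = gaze_jitter,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# continuous HSV -> RGB (h, s, v in [0,1]); avoids 8-bit quantization
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

#' Generate one synthetic cropped eye image
#'
#' Renders a concentric-disc eye: sclera background, iris annulus with a
#' randomized hue, and a central pupil disc displaced by gaze jitter. A
#' healthy eye gets a dark, faintly red pupil with a small bright specular
#' dot; a leukocoric eye gets a bright low-saturation white/yellow pupil.
#' An additive constant offset and a linear illumination ramp with random
#' direction are then applied, followed by i.i.d. Gaussian noise and
#' clipping to [0, 1].
#'
#' @param label `+1` (leukocoric) or `-1` (healthy).
#' @param size crop side in pixels; must lie in the config's size range.
#' @param config a [synth_config()].
#' @param seed integer seed for this image's private random stream.
#' @return an `eye_image`: list with `pixels` (size x size x 3 array in
#'   [0,1]), `label`, and `meta` (geometry and illumination parameters).
#' @export
generate_eye <- function(label, size, config = synth_config(), seed = 1L) {
  if (!label %in% c(-1L, 1L)) stop("generate_eye(): label must be -1 or +1", call. = FALSE)
  if (size < config$size_min || size > config$size_max) {
    stop("generate_eye(): size ", size, " outside the configured range [",
         config$size_min, ", ", config$size_max, "]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    s <- as.integer(size)
    iris_r <- 0.48 * s
    pupil_r <- stats::runif(1, 0.25, 0.40) * iris_r
    gaze_ang <- stats::runif(1, 0, 2 * pi)
    gaze_mag <- stats::runif(1, 0, config$gaze_jitter) * iris_r
    cx <- (s + 1) / 2; cy <- (s + 1) / 2
    px <- cx + gaze_mag * cos(gaze_ang)
    py <- cy + gaze_mag * sin(gaze_ang)

    # colors; iris value range deliberately overlaps the leukocoric pupil
    # brightness so "bright pupil vs bright iris" is genuinely ambiguous
    sclera <- pmin(1, pmax(0, c(0.90, 0.88, 0.86) + stats::runif(3, -0.15, 0.15)))
    iris_col <- hsv_to_rgb(stats::runif(1, 0.02, 0.65),
                           stats::runif(1, 0.05, 0.80),
                           stats::runif(1, 0.10, 0.95))
    if (label == 1L) {
      v <- stats::runif(1, 0.66, 0.95)                # bright, low saturation
      pupil_col <- c(v, v * stats::runif(1, 0.85, 1.0), v * stats::runif(1, 0.55, 0.90))
    } else {
      r <- stats::runif(1, 0.15, 0.50)                # dark with faint red tint
      g <- r * stats::runif(1, 0.35, 0.80)
      pupil_col <- c(r, g, g * stats::runif(1, 0.70, 1.10))
    }

    xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index
    ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index
    d_center <- sqrt((xs - cx)^2 + (ys - cy)^2)
    d_pupil <- sqrt((xs - px)^2 + (ys - py)^2)
    soft <- function(d, r) pmin(1, pmax(0, r - d + 0.5))  # 1-px soft edge
    iris_m <- soft(d_center, iris_r)
    pupil_m <- soft(d_pupil, pupil_r)

    # specular dot inside a healthy pupil, kept small relative to the pupil
    dot_m <- matrix(0, s, s)
    dot_col <- c(0.95, 0.95, 0.95)
    if (label == -1L) {
      dot_r <- min(2, 0.45 * pupil_r)
      dot_ang <- stats::runif(1, 0, 2 * pi)
      dot_mag <- stats::runif(1, 0, 0.4) * pupil_r
      dot_m <- soft(sqrt((xs - (px + dot_mag * cos(dot_ang)))^2 +
                         (ys - (py + dot_mag * sin(dot_ang)))^2), dot_r)
    }

    # illumination: constant offset + linear ramp with random direction
    off <- stats::runif(1, -1, 1) * config$illumination_offset_range
    ramp_amp <- stats::runif(1, 0, config$illumination_gradient_range)
    ramp_ang <- stats::runif(1, 0, 2 * pi)
    u <- ((xs - cx) * cos(ramp_ang) + (ys - cy) * sin(ramp_ang)) / s
    illum <- off + ramp_amp * u   # u spans about [-1/2, 1/2]

    pix <- array(0, dim = c(s, s, 3))
    for (ch in 1:3) {
      layer <- sclera[ch] * (1 - iris_m) + iris_col[ch] * iris_m
      layer <- layer * (1 - pupil_m) + pupil_col[ch] * pupil_m
      layer <- layer * (1 - dot_m) + dot_col[ch] * dot_m
      layer <- layer + illum
      if (config$noise_sd > 0) {
        layer <- layer + stats::rnorm(s * s, 0, config$noise_sd)
      }
      pix[, , ch] <- pmin(1, pmax(0, layer))
    }

    structure(
      list(pixels = pix, label = as.integer(label),
           meta = list(size = s, iris_r = iris_r, pupil_r = pupil_r,
                       pupil_cx = px, pupil_cy = py,
                       iris_col = iris_col, pupil_col = pupil_col,
                       offset = off, ramp_amp = ramp_amp, ramp_ang = ramp_ang,
                       seed = as.integer(seed))),
      class = "eye_image"
    )
  })
}

#' Pupil mask from an image's own generative geometry
#'
#' Logical mask of pixels whose centers fall inside the rendered pupil disc.
#' Used by tests that check class separation directly against the geometry
#' the generator used, independent of any classifier.
#'
#' @param eye an `eye_image`.
#' @return logical size x size matrix.
#' @export
pupil_mask <- function(eye) {
  s <- eye$meta$size
  xs <- matrix(rep(seq_len(s), each = s), s, s)
  ys <- matrix(rep(seq_len(s), times = s), s, s)
  sqrt((xs - eye$meta$pupil_cx)^2 + (ys - eye$meta$pupil_cy)^2) <= eye$meta$pupil_r
}

# Rec. 709 luminance of an eye_image's pixels
luminance <- function(pix) {
  0.2126 * pix[, , 1] + 0.7152 * pix[, , 2] + 0.0722 * pix[, , 3]
}

# deterministic per-image seed derived from the dataset seed and image index
per_image_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 65536 * 32749 + i * 2677) %% 2147483647)
}

#' Generate a labeled synthetic eye-image dataset
#'
#' Draws `n_positive + n_negative` images with sizes uniform over the
#' configured range, shuffles their order, and renders each with its own
#' deterministic random stream (so an image's pixels depend only on the
#' dataset seed and its index, not on generation order).
#'
#' @param config a [synth_config()].
#' @return a tibble with one row per image: `id`, `filename`, `class`
#'   (`"healthy"`/`"leukocoric"`), `label` (-1/+1), `size`, and `image`
#'   (list-column of `eye_image` objects).
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_positive = 3, n_negative = 5, seed = 7))
#' table(ds$class)
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_positive + config$n_negative
  withr::with_seed(config$seed, {
    labels <- sample(c(rep(1L, config$n_positive), rep(-1L, config$n_negative)))
    sizes <- sample(config$size_min:config$size_max, n, replace = TRUE)
  })
  images <- purrr::map(seq_len(n), function(i) {
    generate_eye(labels[i], sizes[i], config, seed = per_image_seed(config$seed, i))
  })
  tibble::tibble(
    id = seq_len(n),
    filename = sprintf("eye_%03d.png", seq_len(n)),
    class = ifelse(labels == 1L, "leukocoric", "healthy"),
    label = labels,
    size = as.integer(sizes),
    image = images
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes one 8-bit PNG per image plus `labels.csv` (`filename,label` with
#' label in healthy/leukocoric) and `manifest.json` recording the full
#' generator configuration.
#'
#' @param dataset tibble from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param config the [synth_config()] used, stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_eye_dataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    png::writePNG(dataset$image[[i]]$pixels, file.path(dir, dataset$filename[i]))
  }
  utils::write.csv(data.frame(filename = dataset$filename, label = dataset$class),
                   file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an eye-image dataset from disk
#'
#' Reads the PNG/JPEG images listed in a `labels.csv` (columns `filename`
#' and `label`, label in healthy/leukocoric). Non-square images are
#' center-cropped to square with a warning. Pixels are scaled to [0,1].
#'
#' @param dir directory containing images and `labels.csv`.
#' @return tibble in the layout of [generate_dataset()] (without meta).
#' @export
read_eye_dataset <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) {
    stop("read_eye_dataset(): no labels.csv in ", dir, call. = FALSE)
  }
  lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(lab))) {
    stop("read_eye_dataset(): labels.csv must have columns filename,label", call. = FALSE)
  }
  if (!all(lab$label %in% c("healthy", "leukocoric"))) {
    stop("read_eye_dataset(): labels must be 'healthy' or 'leukocoric'", call. = FALSE)
  }
  images <- purrr::map(lab$filename, function(f) {
    pix <- png::readPNG(file.path(dir, f))
    if (length(dim(pix)) == 2) pix <- array(rep(pix, 3), dim = c(dim(pix), 3))
    if (dim(pix)[3] > 3) pix <- pix[, , 1:3, drop = FALSE]
    if (dim(pix)[1] != dim(pix)[2]) {
      warning("center-cropping non-square image ", f, " to square")
      side <- min(dim(pix)[1:2])
      r0 <- floor((dim(pix)[1] - side) / 2)
      c0 <- floor((dim(pix)[2] - side) / 2)
      pix <- pix[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
    }
    lb <- if (lab$label[match(f, lab$filename)] == "leukocoric") 1L else -1L
    structure(list(pixels = pix, label = lb,
                   meta = list(size = dim(pix)[1], file = f)),
              class = "eye_image")
  })
  labels <- ifelse(lab$label == "leukocoric", 1L, -1L)
  tibble::tibble(
    id = seq_len(nrow(lab)),
    filename = lab$filename,
    class = lab$label,
    label = labels,
    size = vapply(images, function(im) im$meta$size, integer(1)),
    image = images
  )
}
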