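#' Train a full model bundle on a dataset
#'
#' Fits the preprocessing model and all experts on the whole dataset and
#' attaches fuzzy densities: either derived from a repeated CV on the same
#' dataset (`densities = "trained"`) or the shipped published average ranks
#' (`densities = "paper-2014"`).
#'
#' @param dataset tibble of eye images.
#' @param bank expert specification (default [default_bank()]).
#' @param densities `"trained"` or `"paper-2014"`.
#' @param cv [cv_config()] used when `densities = "trained"`.
#' @param seed integer seed for expert training.
#' @return an `lk_model`: preprocessor, trained bank, densities, lambda.
#' @export
train_model <- function(dataset, bank = default_bank(),
                        densities = c("paper-2014", "trained"),
                        cv = cv_config(repetitions = 3), seed = 1L) {
  densities <- match.arg(densities)
  prep <- fit_preprocessor(dataset)
  feats <- preprocess_features(dataset, prep)
  trained <- train_bank(feats, bank, seed = seed)
  if (densities == "paper-2014") {
    ranks <- paper_2014_ranks()
    if (!identical(names(ranks), bank$id)) {
      stop("'paper-2014' densities require the default bank", call. = FALSE)
    }
  } else {
    res <- run_repeated_cv(dataset, bank, cv)
    ranks <- res$avg_ranks
  }
  g <- densities_from_ranks(ranks)
  structure(list(prep = prep, bank = trained, densities = g,
                 lambda = solve_lambda(g), density_source = densities,
                 seed = as.integer(seed)),
            class = "lk_model")
}

#' Classify one eye image with a trained model
#'
#' Extracts per-channel features, queries all experts, and fuses their
#' certainties with the Sugeno integral.
#'
#' @param model an `lk_model`.
#' @param eye an `eye_image` (or path to a PNG readable by
#'   [read_eye_image()]).
#' @return list with `class` (+1 leukocoric / -1 healthy), `e_pos`,
#'   `e_neg`, and `h` (named vector of the 27 positive certainties).
#' @export
predict_eye <- function(model, eye) {
  stopifnot(inherits(model, "lk_model"))
  if (is.character(eye)) eye <- read_eye_image(eye)
  h <- vapply(seq_len(nrow(model$bank$bank)), function(i) {
    sp <- model$bank$bank[i, ]
    x <- preprocess_channel(eye, sp$channel, model$prep)
    certainty(model$bank$experts[[sp$id]], x)[, "h_pos"]
  }, numeric(1))
  names(h) <- model$bank$bank$id
  fp <- fuse_predict(h, model$densities, model$lambda)
  c(fp, list(h = h))
}

#' Read a single eye image from a PNG file
#'
#' @param path PNG file; non-square images are center-cropped with a
#'   warning, grayscale replicated to RGB.
#' @return an `eye_image` with label `NA`.
#' @export
read_eye_image <- function(path) {
  if (!file.exists(path)) stop("read_eye_image(): no such file: ", path, call. = FALSE)
  pix <- png::readPNG(path)
  if (length(dim(pix)) == 2) pix <- array(rep(pix, 3), dim = c(dim(pix), 3))
  if (dim(pix)[3] > 3) pix <- pix[, , 1:3, drop = FALSE]
  if (dim(pix)[1] != dim(pix)[2]) {
    warning("center-cropping non-square image to square")
    side <- min(dim(pix)[1:2])
    r0 <- floor((dim(pix)[1] - side) / 2)
    c0 <- floor((dim(pix)[2] - side) / 2)
    pix <- pix[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  }
  structure(list(pixels = pix, label = NA_integer_,
                 meta = list(size = dim(pix)[1], file = path)),
            class = "eye_image")
}

#' Save a trained model bundle to a directory
#'
#' Writes a JSON manifest (expert ids, densities, lambda, z-scoring floor,
#' working resolution), per-channel normalizer and KLT arrays as CSV, and
#' the fitted expert objects as RDS files.
#'
#' @param model an `lk_model`.
#' @param dir target directory (created; must be empty or absent unless
#'   `force`).
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir, force = FALSE) {
  stopifnot(inherits(model, "lk_model"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    stop("save_model(): ", dir, " exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(file.path(dir, "experts"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "leukofuse", format = 1L,
    side = model$prep$side, eps = model$prep$eps,
    expert_ids = model$bank$bank$id,
    densities = as.list(stats::setNames(as.numeric(model$densities),
                                        names(model$densities))),
    lambda = model$lambda, density_source = model$density_source,
    seed = model$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ch in names(model$prep$channels)) {
    p <- model$prep$channels[[ch]]
    utils::write.csv(data.frame(mean = p$mean, sd = p$sd,
                                klt_center = p$klt$center,
                                basis1 = p$klt$basis[, 1],
                                basis2 = p$klt$basis[, 2]),
                     file.path(dir, paste0("prep_", ch, ".csv")),
                     row.names = FALSE)
    writeLines(as.character(p$klt$eigenvalues),
               file.path(dir, paste0("eigenvalues_", ch, ".txt")))
  }
  for (id in names(model$bank$experts)) {
    saveRDS(model$bank$experts[[id]],
            file.path(dir, "experts", paste0(gsub("@", "_", id), ".rds")))
  }
  invisible(dir)
}

#' Load a model bundle saved by [save_model()]
#'
#' @param dir bundle directory.
#' @return an `lk_model`.
#' @export
load_model <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop("load_model(): no manifest.json in ", dir, call. = FALSE)
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  channels <- lapply(stats::setNames(c("R", "G", "B"), c("R", "G", "B")),
                     function(ch) {
    df <- utils::read.csv(file.path(dir, paste0("prep_", ch, ".csv")))
    ev <- as.numeric(readLines(file.path(dir, paste0("eigenvalues_", ch, ".txt"))))
    list(mean = df$mean, sd = df$sd,
         klt = structure(list(basis = cbind(df$basis1, df$basis2),
                              eigenvalues = ev, sdev = pmax(sqrt(ev), 1e-12),
                              center = df$klt_center),
                         class = "lk_klt"))
  })
  prep <- structure(list(channels = channels, side = man$side, eps = man$eps,
                         n_train = NA_integer_),
                    class = "lk_preprocessor")
  experts <- lapply(man$expert_ids, function(id) {
    readRDS(file.path(dir, "experts", paste0(gsub("@", "_", id), ".rds")))
  })
  names(experts) <- man$expert_ids
  bank <- default_bank()
  if (!identical(bank$id, man$expert_ids)) {
    bank <- purrr::map_dfr(experts, function(e) tibble::as_tibble(e$spec))
  }
  g <- fuzzy_densities(unlist(man$densities))
  structure(list(prep = prep,
                 bank = structure(list(experts = experts, bank = bank,
                                       seed = man$seed), class = "lk_bank"),
                 densities = g, lambda = man$lambda,
                 density_source = man$density_source, seed = man$seed),
            class = "lk_model")
}
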