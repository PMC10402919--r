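#' Annotations for pixel-classifier training
#'
#' Training labels are sparse: an annotation mask has the same shape as its
#' image and assigns each pixel one of `0` (unlabeled), `1` (background),
#' `2` (core) or `3` (outgrowth). Masks can come from user strokes exported
#' as label-mask TIFFs ([read_label_mask()]), from polygon annotations in
#' JSON ([read_polygon_annotations()]), or — for validation on synthetic
#' data — by subsampling ground-truth masks ([annotate_from_truth()]).
#'
#' @param truth A `synthetic_truth` from [render_scene()].
#' @param fraction Fraction of each region's pixels to label.
#' @param seed RNG seed for the subsample.
#' @return An integer annotation mask (0 = unlabeled).
#' @export
annotate_from_truth <- function(truth, fraction = 0.01, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), fraction > 0, fraction <= 1)
  masks <- list(truth$background_mask, truth$core_mask, truth$outgrowth_mask)
  ann <- matrix(0L, nrow(truth$core_mask), ncol(truth$core_mask))
  withr::with_seed(seed, {
    for (k in seq_along(masks)) {
      idx <- which(masks[[k]])
      n <- max(1L, round(length(idx) * fraction))
      ann[sample(idx, min(n, length(idx)))] <- k
    }
  })
  ann
}

#' @rdname annotate_from_truth
#' @param path File path (TIFF for label masks, JSON for polygons).
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (!is.matrix(m)) stop("label mask must be a single-channel grayscale TIFF")
  if (any(!m %in% 0:3)) stop("label mask values must be 0..3")
  storage.mode(m) <- "integer"
  m
}

#' @rdname annotate_from_truth
#' @param shape `(height, width)` of the annotated image, required for
#'   polygon rasterisation.
#' @details Polygon JSON is a list of objects with fields `class` (one of
#'   `"background"`, `"core"`, `"outgrowth"`) and `vertices`, an Nx2 array
#'   of 1-based `(row, col)` pixel coordinates. Pixels whose centre falls
#'   inside the polygon (even-odd rule) receive the class label; later
#'   polygons overwrite earlier ones.
#' @export
read_polygon_annotations <- function(path, shape) {
  polys <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  ann <- matrix(0L, shape[1], shape[2])
  for (p in polys) {
    k <- match(p$class, REGION_NAMES)
    if (is.na(k)) stop("unknown annotation class '", p$class, "'")
    v <- if (is.matrix(p$vertices)) p$vertices else
      do.call(rbind, lapply(p$vertices, as.numeric))
    inside <- points_in_polygon(shape, v)
    ann[inside] <- k
  }
  ann
}

# Even-odd-rule point-in-polygon test for all pixel centres; returns a
# logical matrix. Vertices are (row, col).
points_in_polygon <- function(shape, vertices) {
  nr <- shape[1]; nc <- shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  n <- nrow(vertices)
  inside <- matrix(FALSE, nr, nc)
  j <- n
  for (i in seq_len(n)) {
    yi <- vertices[i, 1]; xi <- vertices[i, 2]
    yj <- vertices[j, 1]; xj <- vertices[j, 2]
    crosses <- ((yi > rr) != (yj > rr)) &
      (cc < (xj - xi) * (rr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Train a random-forest pixel classifier
#'
#' Fits a bagged-tree ensemble on the labeled pixels of one or more
#' projected images, mapping multiscale local features to the classes
#' background, core and outgrowth. Class weights are balanced (inverse
#' label frequency), a stratified hold-out split estimates generalisation
#' accuracy, and the final forest is refit on all labeled pixels. Training
#' and inference are deterministic for a fixed seed.
#'
#' @param images A [projected_image()] or list of them.
#' @param annotations An annotation mask (see [annotate_from_truth()]) or
#'   list of masks, parallel to `images`.
#' @param spec A [feature_spec()].
#' @param seed Integer seed for the split and the forest.
#' @param num_trees Ensemble size.
#' @param holdout_fraction Fraction of labeled pixels held out for the
#'   accuracy estimate.
#' @param min_pixels_per_class Below this per-class label count a warning is
#'   recorded in the training summary.
#' @return A `pixel_classifier` object; inspect with [tidy()] (per-class
#'   label counts and weights) and [glance()] (hold-out accuracy, ensemble
#'   size).
#' @export
train_pixel_classifier <- function(images, annotations, spec = feature_spec(),
                                   seed = 1L, num_trees = 100L,
                                   holdout_fraction = 0.2,
                                   min_pixels_per_class = 50L) {
  if (inherits(images, "projected_image")) images <- list(images)
  if (is.matrix(annotations)) annotations <- list(annotations)
  stopifnot(length(images) == length(annotations))
  feats <- list(); labels <- integer(0)
  for (i in seq_along(images)) {
    ann <- annotations[[i]]
    stopifnot(all(dim(ann) == image_shape(images[[i]])))
    idx <- which(ann > 0)
    if (length(idx) == 0) next
    fm <- extract_features(images[[i]], spec)
    feats[[length(feats) + 1L]] <- fm[idx, , drop = FALSE]
    labels <- c(labels, ann[idx])
  }
  x <- do.call(rbind, feats)
  y <- factor(REGION_NAMES[labels], levels = REGION_NAMES)
  counts <- table(y)
  missing <- REGION_NAMES[counts == 0]
  if (length(missing) > 0) {
    stop("no labeled pixels for class(es): ", paste(missing, collapse = ", "))
  }
  warnings <- character(0)
  scarce <- REGION_NAMES[counts < min_pixels_per_class]
  if (length(scarce) > 0) {
    warnings <- c(warnings, paste0("fewer than ", min_pixels_per_class,
                                   " labeled pixels for: ",
                                   paste(scarce, collapse = ", ")))
  }
  wts <- as.numeric(1 / counts)
  wts <- wts / sum(wts)
  names(wts) <- names(counts)

  holdout_acc <- NA_real_
  if (holdout_fraction > 0 && all(counts >= 5)) {
    test_idx <- withr::with_seed(seed, {
      unlist(lapply(levels(y), function(lv) {
        ii <- which(y == lv)
        sample(ii, max(1L, round(length(ii) * holdout_fraction)))
      }))
    })
    fit0 <- ranger::ranger(
      x = x[-test_idx, , drop = FALSE], y = y[-test_idx],
      num.trees = num_trees, probability = FALSE, class.weights = wts,
      seed = seed, num.threads = 1L
    )
    pred <- predict(fit0, data = x[test_idx, , drop = FALSE],
                    num.threads = 1L)$predictions
    holdout_acc <- mean(pred == y[test_idx])
  }

  fit <- ranger::ranger(
    x = x, y = y, num.trees = num_trees, probability = TRUE,
    class.weights = wts, seed = seed, num.threads = 1L
  )
  structure(
    list(
      forest = fit,
      feature_spec = spec,
      class_order = REGION_NAMES,
      channel_names = images[[1]]$channel_names,
      training_seed = as.integer(seed),
      training_summary = tibble::tibble(
        class = REGION_NAMES,
        n_labeled = as.integer(counts[REGION_NAMES]),
        class_weight = as.numeric(wts[REGION_NAMES])
      ),
      holdout_accuracy = holdout_acc,
      warnings = warnings
    ),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier> ", x$forest$num.trees, " trees, ",
      sum(x$training_summary$n_labeled), " labeled pixels, hold-out accuracy ",
      round(x$holdout_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pixel_classifier <- function(x, ...) x$training_summary

#' @exportS3Method generics::glance
glance.pixel_classifier <- function(x, ...) {
  tibble::tibble(
    num_trees = x$forest$num.trees,
    n_labeled_pixels = sum(x$training_summary$n_labeled),
    n_features = length(x$forest$forest$independent.variable.names),
    holdout_accuracy = x$holdout_accuracy,
    training_seed = x$training_seed,
    n_warnings = length(x$warnings)
  )
}

#' Classify every pixel of a projected image
#'
#' Applies a trained [pixel classifier][train_pixel_classifier()]: the
#' per-pixel class is the probability argmax (ties broken toward the first
#' class in background < core < outgrowth order) and per-class probability
#' maps are returned alongside. Inference is deterministic.
#'
#' @param model A `pixel_classifier`.
#' @param img A [projected_image()] with the channel layout the model was
#'   trained on.
#' @return A list with `labels` (a [region_label_map()]) and
#'   `probabilities`, an array `(class, row, col)` whose per-pixel sums are
#'   1.
#' @export
apply_pixel_classifier <- function(model, img) {
  stopifnot(inherits(model, "pixel_classifier"),
            inherits(img, "projected_image"))
  if (length(img$channel_names) != length(model$channel_names)) {
    stop("channel mismatch: model expects ", length(model$channel_names),
         " channel(s) [", paste(model$channel_names, collapse = ", "),
         "], image has ", length(img$channel_names), " [",
         paste(img$channel_names, collapse = ", "), "]")
  }
  fm <- extract_features(img, model$feature_spec)
  shp <- attr(fm, "image_shape")
  prob <- predict(model$forest, data = fm, num.threads = 1L)$predictions
  prob <- prob[, model$class_order, drop = FALSE]
  cls <- max.col(prob, ties.method = "first")
  labels <- matrix(cls - 1L, shp[1], shp[2])
  parr <- array(0, dim = c(length(model$class_order), shp[1], shp[2]))
  for (k in seq_along(model$class_order)) {
    parr[k, , ] <- matrix(prob[, k], shp[1], shp[2])
  }
  list(
    labels = region_label_map(labels, provenance = "classifier"),
    probabilities = parr
  )
}

#' Deterministic threshold fallback for cell/background separation
#'
#' A classifier-free alternative: the summed composite intensity is
#' thresholded globally, either at a fixed value or by Otsu's method
#' (exhaustive between-class-variance maximisation over a 256-bin
#' histogram). The result is a cell mask only; splitting it into core and
#' outgrowth is done by [derive_regions_from_cellmask()].
#'
#' @param img A [projected_image()].
#' @param threshold Fixed threshold; `NULL` (default) selects Otsu.
#' @return A logical cell mask with attributes `threshold` and, when no
#'   pixel exceeds it, the flag `empty_mask`.
#' @export
threshold_fallback <- function(img, threshold = NULL) {
  stopifnot(inherits(img, "projected_image"))
  shp <- image_shape(img)
  comp <- matrix(0, shp[1], shp[2])
  for (ch in seq_along(img$channel_names)) comp <- comp + img$pixels[ch, , ]
  thr <- threshold %||% otsu_threshold(comp)
  mask <- comp > thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- if (is.null(threshold)) "otsu" else "fixed"
  if (!any(mask)) attr(mask, "qc_flags") <- "empty cell mask"
  mask
}

#' Save or load a pixel classifier
#'
#' The archive bundles the fitted forest with its feature spec, channel
#' layout and class order, so [apply_pixel_classifier()] is self-contained
#' after loading.
#'
#' @param model A `pixel_classifier`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pixel_classifier")) {
    stop("'", path, "' does not contain a pixel_classifier")
  }
  model
}
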