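#' Multiscale pixel features for classification
#'
#' Defines which local image features are computed per pixel before
#' classification, in the style of trainable-segmentation tools: each
#' feature kind is evaluated at every smoothing scale on every channel (or
#' on the summed composite when `use_all_channels = FALSE`). Border pixels
#' are handled by reflection, so feature extraction is fully deterministic.
#'
#' Supported kinds:
#' \describe{
#'   \item{gaussian}{Gaussian-smoothed intensity.}
#'   \item{gradient_magnitude}{magnitude of the central-difference gradient
#'     of the smoothed image.}
#'   \item{laplacian}{discrete Laplacian of the smoothed image.}
#'   \item{difference_of_gaussians}{smoothing at `1.6 * sigma` minus
#'     smoothing at `sigma`.}
#'   \item{structure_tensor_eigenvalues}{both eigenvalues of the smoothed
#'     structure tensor (two features per scale and channel).}
#' }
#'
#' @param sigmas Strictly increasing positive smoothing scales in pixels.
#' @param feature_kinds Non-empty subset of the kinds above.
#' @param use_all_channels Compute features on every channel (default) or on
#'   the channel sum.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(sigmas = c(1, 2, 4, 8),
                         feature_kinds = c("gaussian", "gradient_magnitude",
                                           "laplacian",
                                           "difference_of_gaussians"),
                         use_all_channels = TRUE) {
  kinds_all <- c("gaussian", "gradient_magnitude", "laplacian",
                 "structure_tensor_eigenvalues", "difference_of_gaussians")
  if (length(sigmas) == 0 || any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE)) {
    stop("sigmas must be strictly increasing and positive")
  }
  bad <- setdiff(feature_kinds, kinds_all)
  if (length(bad) > 0) {
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  }
  if (length(feature_kinds) == 0) stop("feature_kinds must be non-empty")
  structure(
    list(sigmas = as.numeric(sigmas), feature_kinds = feature_kinds,
         use_all_channels = isTRUE(use_all_channels)),
    class = "feature_spec"
  )
}

#' Extract per-pixel feature vectors from a projected image
#'
#' @param img A [projected_image()].
#' @param spec A [feature_spec()].
#' @return A numeric matrix with one row per pixel (column-major pixel
#'   order) and one named column per feature.
#' @export
extract_features <- function(img, spec = feature_spec()) {
  stopifnot(inherits(img, "projected_image"), inherits(spec, "feature_spec"))
  shp <- image_shape(img)
  if (max(spec$sigmas) > min(shp) / 2) {
    stop("sigma ", max(spec$sigmas), " exceeds half the image extent (",
         min(shp) / 2, ")")
  }
  if (spec$use_all_channels) {
    chans <- lapply(seq_along(img$channel_names), function(ch) img$pixels[ch, , ])
    names(chans) <- img$channel_names
  } else {
    comp <- matrix(0, shp[1], shp[2])
    for (ch in seq_along(img$channel_names)) comp <- comp + img$pixels[ch, , ]
    chans <- list(composite = comp)
  }
  cols <- list()
  for (cn in names(chans)) {
    m <- chans[[cn]]
    for (s in spec$sigmas) {
      g <- gaussian_blur(m, s)
      for (kind in spec$feature_kinds) {
        nm <- function(suffix = NULL) {
          paste0(cn, "_", kind, if (!is.null(suffix)) paste0("_", suffix),
                 "_s", s)
        }
        if (kind == "gaussian") {
          cols[[nm()]] <- as.vector(g)
        } else if (kind == "gradient_magnitude") {
          cols[[nm()]] <- as.vector(sqrt(grad_row(g)^2 + grad_col(g)^2))
        } else if (kind == "laplacian") {
          cols[[nm()]] <- as.vector(conv2_reflect(g, LAPLACIAN_KERNEL))
        } else if (kind == "difference_of_gaussians") {
          cols[[nm()]] <- as.vector(gaussian_blur(m, 1.6 * s) - g)
        } else if (kind == "structure_tensor_eigenvalues") {
          gr <- grad_row(g); gc <- grad_col(g)
          jrr <- gaussian_blur(gr * gr, s)
          jcc <- gaussian_blur(gc * gc, s)
          jrc <- gaussian_blur(gr * gc, s)
          tr2 <- (jrr + jcc) / 2
          disc <- sqrt(pmax(0, ((jrr - jcc) / 2)^2 + jrc^2))
          cols[[nm("e1")]] <- as.vector(tr2 + disc)
          cols[[nm("e2")]] <- as.vector(tr2 - disc)
        }
      }
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "image_shape") <- shp
  out
}
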