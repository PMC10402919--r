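#' Describe a synthetic spheroid scene
#'
#' A scene is the parametric description of one synthetic spheroid image:
#' a bright cohesive core disk, `n_sprouts` filamentous extensions radiating
#' from the core rim (carrying the fibroblast and endothelial channels), and
#' `n_detached_cells` small disks scattered in an annulus around the core
#' (carrying the macrophage channel only), emulating single cells that
#' migrated out of the core. Rendering a scene with [render_scene()] yields
#' both the image and its pixel-exact ground truth, so every measurement the
#' package produces can be validated against a known answer.
#'
#' Detached-cell centres are placed by rejection sampling inside
#' `detached_ring` with a minimum pairwise distance of
#' `2 * detached_cell_radius`, so planted cells never merge and the planted
#' count is unambiguous. Sprouts may overlap each other and the detached
#' cells; region masks are unions.
#'
#' @param image_shape Integer `(height, width)` of the image in pixels.
#' @param core_center Subpixel `(row, col)` of the core centre; defaults to
#'   the image centre.
#' @param core_radius Core disk radius in pixels.
#' @param n_sprouts Number of radiating sprouts.
#' @param sprout_length_mean,sprout_length_sd Sprout length distribution
#'   (normal, truncated at 5 px) in pixels.
#' @param sprout_width Sprout thickness in pixels.
#' @param n_detached_cells Number of detached single cells.
#' @param detached_cell_radius Radius of a detached cell in pixels.
#' @param detached_ring `(inner, outer)` radii in pixels, measured from
#'   `core_center`, of the annulus holding detached-cell centres. The inner
#'   radius must be at least `core_radius`.
#' @param channel_assignment Named integer vector mapping cell type to
#'   channel index (1-based).
#' @param channel_intensity Named numeric vector of nominal fluorescence
#'   levels (arbitrary units, integer-valued after quantisation).
#' @param noise_sigma Standard deviation of additive Gaussian read noise.
#' @param photon_scale Poisson (photon) noise scale; 0 disables. When
#'   positive, each pixel is replaced by
#'   `rpois(value * photon_scale) / photon_scale` before read noise.
#' @param n_planes Number of Z planes; 1 renders a flat image, more planes
#'   distribute sprouts and cells over planes to exercise projection.
#' @param seed Integer RNG seed; the same seed renders a bit-identical image.
#'
#' @return An object of class `spheroid_scene` (a validated list of the
#'   above parameters).
#' @seealso [render_scene()], [make_condition_set()]
#' @examples
#' sc <- spheroid_scene(n_sprouts = 4, n_detached_cells = 5, seed = 7)
#' rendered <- render_scene(sc)
#' rendered$truth$true_core_area
#' @export
spheroid_scene <- function(image_shape = c(256L, 256L),
                           core_center = NULL,
                           core_radius = 40,
                           n_sprouts = 10L,
                           sprout_length_mean = 60,
                           sprout_length_sd = 10,
                           sprout_width = 3,
                           n_detached_cells = 25L,
                           detached_cell_radius = 3,
                           detached_ring = c(55, 120),
                           channel_assignment = c(FLS = 1L, EC = 2L, MACROPHAGE = 3L),
                           channel_intensity = c(FLS = 200, EC = 180, MACROPHAGE = 160),
                           noise_sigma = 0,
                           photon_scale = 0,
                           n_planes = 1L,
                           seed = 1L) {
  image_shape <- as.integer(image_shape)
  core_center <- core_center %||% ((image_shape + 1) / 2)
  scene <- structure(
    list(
      image_shape = image_shape,
      core_center = as.numeric(core_center),
      core_radius = as.numeric(core_radius),
      n_sprouts = as.integer(n_sprouts),
      sprout_length_mean = as.numeric(sprout_length_mean),
      sprout_length_sd = as.numeric(sprout_length_sd),
      sprout_width = as.numeric(sprout_width),
      n_detached_cells = as.integer(n_detached_cells),
      detached_cell_radius = as.numeric(detached_cell_radius),
      detached_ring = as.numeric(detached_ring),
      channel_assignment = channel_assignment,
      channel_intensity = channel_intensity,
      noise_sigma = as.numeric(noise_sigma),
      photon_scale = as.numeric(photon_scale),
      n_planes = as.integer(n_planes),
      seed = as.integer(seed)
    ),
    class = "spheroid_scene"
  )
  validate_scene(scene)
}

validate_scene <- function(scene) {
  stopifnot(
    length(scene$image_shape) == 2, all(scene$image_shape >= 16),
    length(scene$core_center) == 2
  )
  if (scene$core_radius <= 0) stop("core_radius must be > 0")
  if (scene$n_sprouts < 0 || scene$n_detached_cells < 0) {
    stop("n_sprouts and n_detached_cells must be non-negative")
  }
  if (scene$n_detached_cells > 0) {
    if (scene$detached_ring[1] < scene$core_radius) {
      stop("detached_ring inner radius must be >= core_radius")
    }
    if (scene$detached_ring[2] <= scene$detached_ring[1]) {
      stop("detached_ring outer radius must exceed the inner radius")
    }
  }
  if (scene$sprout_width <= 0) stop("sprout_width must be > 0")
  if (scene$noise_sigma < 0 || scene$photon_scale < 0) {
    stop("noise_sigma and photon_scale must be non-negative")
  }
  types <- names(scene$channel_assignment)
  if (is.null(types) || !setequal(types, names(scene$channel_intensity))) {
    stop("channel_assignment and channel_intensity must be named consistently")
  }
  if (anyDuplicated(scene$channel_assignment)) {
    stop("channel_assignment must map each cell type to a distinct channel")
  }
  if (scene$n_planes < 1) stop("n_planes must be >= 1")
  scene
}

#' @export
print.spheroid_scene <- function(x, ...) {
  cat("<spheroid_scene> ", x$image_shape[1], "x", x$image_shape[2],
      " px, core r=", x$core_radius,
      ", ", x$n_sprouts, " sprouts, ",
      x$n_detached_cells, " detached cells, ",
      x$n_planes, " plane(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Analytic expectation of the outgrowth area in pixels, ignoring sprout
# overlap: sprouts contribute length x width each, detached cells a disk.
expected_outgrowth_area <- function(scene) {
  scene$n_sprouts * scene$sprout_length_mean * scene$sprout_width +
    scene$n_detached_cells * pi * scene$detached_cell_radius^2
}
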