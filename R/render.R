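#' Render a synthetic spheroid scene with pixel-exact ground truth
#'
#' Draws the scene geometry (core disk, radiating sprouts, detached cells)
#' with a seeded RNG, rasterises it into a multi-channel image, freezes the
#' noiseless rendering as ground truth, and only then applies photon and
#' read noise. Noise therefore never changes the truth masks: metrics
#' computed downstream always have a fixed reference.
#'
#' The core disk carries every cell-type channel at its nominal intensity.
#' Sprouts are anti-aliased thick line segments starting on the core rim at
#' random angles and carry all channels except the detached-cell channel,
#' with independent per-sprout, per-channel intensity jitter (uniform in
#' 0.8-1.2). Detached cells are small anti-aliased disks carrying only the
#' macrophage channel (the channel named `"MACROPHAGE"`, or the last named
#' cell type when no such name exists). All intensities are quantised to
#' non-negative integers, as an unsigned-integer camera would record them.
#'
#' Ground-truth masks partition the image: `core_mask` is the set of pixels
#' whose centre lies within `core_radius` of the core centre,
#' `outgrowth_mask` is every other pixel with positive noiseless composite
#' intensity, and `background_mask` is the rest.
#'
#' @param scene A [spheroid_scene()].
#' @return A list with elements
#'   \describe{
#'     \item{stack}{a [channel_stack()] of quantised noisy intensities,
#'       dimensions `(plane, channel, row, col)`;}
#'     \item{truth}{a `synthetic_truth` object: logical `core_mask`,
#'       `outgrowth_mask`, `background_mask`; pixel counts `true_core_area`,
#'       `true_outgrowth_area`; `detached_cell_centers` tibble (`row`,
#'       `col`); `per_channel_truth` noiseless array `(channel, row, col)`;
#'       and the `scene`.}
#'   }
#' @examples
#' r <- render_scene(spheroid_scene(n_sprouts = 3, n_detached_cells = 4))
#' r$truth$true_outgrowth_area
#' @export
render_scene <- function(scene) {
  validate_scene(scene)
  withr::with_seed(scene$seed, render_scene_impl(scene))
}

render_scene_impl <- function(scene) {
  H <- scene$image_shape[1]; W <- scene$image_shape[2]
  assign <- scene$channel_assignment
  types <- names(sort(assign))              # types ordered by channel index
  n_ch <- length(types)
  detached_type <- if ("MACROPHAGE" %in% types) "MACROPHAGE" else types[n_ch]
  sprout_types <- setdiff(types, detached_type)
  intensity <- scene$channel_intensity

  # --- geometry draws (fixed order for reproducibility) ---
  ns <- scene$n_sprouts
  # stratified random angles: sprouts spread around the rim (as radially
  # migrating cells do) so their union area stays close to the sum of the
  # per-sprout areas
  angles <- if (ns > 0) 2 * pi * (seq_len(ns) - 1 + runif(ns)) / ns else numeric(0)
  lengths <- if (ns > 0) pmax(5, rnorm(ns, scene$sprout_length_mean, scene$sprout_length_sd)) else numeric(0)
  jitter <- matrix(
    if (ns > 0) runif(ns * length(sprout_types), 0.8, 1.2) else numeric(0),
    nrow = max(ns, 0), ncol = length(sprout_types),
    dimnames = if (ns > 0) list(NULL, sprout_types)
  )
  centers <- place_detached_cells(scene)
  np <- scene$n_planes
  core_plane <- as.integer(ceiling(np / 2))
  sprout_planes <- if (ns > 0) sample.int(np, ns, replace = TRUE) else integer(0)
  cell_planes <- if (nrow(centers) > 0) sample.int(np, nrow(centers), replace = TRUE) else integer(0)

  # --- noiseless rasterisation, plane by plane ---
  clean <- array(0, dim = c(np, n_ch, H, W))
  dist_core <- pixel_distance(c(H, W), scene$core_center)
  core_cov <- dist_core <= scene$core_radius

  for (i in seq_len(ns)) {
    u <- c(cos(angles[i]), sin(angles[i]))
    p0 <- scene$core_center + scene$core_radius * u
    p1 <- p0 + lengths[i] * u
    cov <- segment_coverage(c(H, W), p0, p1, scene$sprout_width)
    if (is.null(cov)) next
    for (ty in sprout_types) {
      ch <- assign[[ty]]
      val <- intensity[[ty]] * jitter[i, ty] * cov$cov
      sl <- clean[sprout_planes[i], ch, cov$rows, cov$cols]
      clean[sprout_planes[i], ch, cov$rows, cov$cols] <- pmax(sl, val)
    }
  }
  for (j in seq_len(nrow(centers))) {
    cov <- disk_coverage(c(H, W), centers[j, ], scene$detached_cell_radius)
    if (is.null(cov)) next
    ch <- assign[[detached_type]]
    val <- intensity[[detached_type]] * cov$cov
    sl <- clean[cell_planes[j], ch, cov$rows, cov$cols]
    clean[cell_planes[j], ch, cov$rows, cov$cols] <- pmax(sl, val)
  }
  # core takes precedence over anything drawn across it on its plane
  for (ty in types) {
    ch <- assign[[ty]]
    sl <- clean[core_plane, ch, , ]
    sl[core_cov] <- intensity[[ty]]
    clean[core_plane, ch, , ] <- sl
  }
  clean <- round(clean)

  # --- ground truth from the quantised noiseless rendering ---
  per_channel_truth <- array(0, dim = c(n_ch, H, W))
  for (ch in seq_len(n_ch)) {
    m <- matrix(0, H, W)
    for (p in seq_len(np)) m <- pmax(m, clean[p, ch, , ])
    per_channel_truth[ch, , ] <- m
  }
  composite <- matrix(0, H, W)
  for (ch in seq_len(n_ch)) composite <- composite + per_channel_truth[ch, , ]
  core_mask <- core_cov
  outgrowth_mask <- (composite > 0) & !core_mask
  background_mask <- !core_mask & !outgrowth_mask

  truth <- structure(
    list(
      core_mask = core_mask,
      outgrowth_mask = outgrowth_mask,
      background_mask = background_mask,
      true_core_area = sum(core_mask),
      true_outgrowth_area = sum(outgrowth_mask),
      detached_cell_centers = tibble::tibble(
        row = centers[, 1] %||% numeric(0),
        col = centers[, 2] %||% numeric(0)
      ),
      per_channel_truth = per_channel_truth,
      channel_names = types,
      scene = scene
    ),
    class = "synthetic_truth"
  )

  # --- noise, applied after truth is frozen ---
  noisy <- clean
  if (scene$photon_scale > 0) {
    noisy[] <- stats::rpois(length(noisy), noisy * scene$photon_scale) / scene$photon_scale
  }
  if (scene$noise_sigma > 0) {
    noisy <- noisy + rnorm(length(noisy), 0, scene$noise_sigma)
  }
  noisy <- round(pmin(pmax(noisy, 0), 65535))

  stack <- channel_stack(noisy, channel_names = types, source_path = "synthetic")
  list(stack = stack, truth = truth)
}

# Rejection-sample detached-cell centres: uniform over the annulus, pairwise
# distance >= 2 * radius, whole disk inside the image.
place_detached_cells <- function(scene) {
  n <- scene$n_detached_cells
  if (n == 0) return(matrix(numeric(0), 0, 2))
  H <- scene$image_shape[1]; W <- scene$image_shape[2]
  rc <- scene$detached_cell_radius
  inner <- scene$detached_ring[1]; outer <- scene$detached_ring[2]
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(structure(
        class = c("outgrowthr_placement_error", "error", "condition"),
        list(message = sprintf(
          "could not place %d detached cells of radius %g in ring [%g, %g] without overlap (%d attempts)",
          n, rc, inner, outer, max_attempts
        ), call = NULL)
      ))
    }
    r <- sqrt(runif(1, inner^2, outer^2))
    th <- runif(1, 0, 2 * pi)
    cand <- scene$core_center + r * c(cos(th), sin(th))
    if (cand[1] < 1 + rc || cand[1] > H - rc || cand[2] < 1 + rc || cand[2] > W - rc) next
    if (placed > 0) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 + (centers[seq_len(placed), 2] - cand[2])^2
      if (any(d2 < (2 * rc)^2)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# Anti-aliased coverage of a thick segment within its bounding box.
# Returns NULL when the box misses the image entirely.
segment_coverage <- function(shape, p0, p1, width) {
  half <- width / 2 + 0.5
  r0 <- floor(min(p0[1], p1[1]) - half); r1 <- ceiling(max(p0[1], p1[1]) + half)
  c0 <- floor(min(p0[2], p1[2]) - half); c1 <- ceiling(max(p0[2], p1[2]) + half)
  rows <- max(1, r0):min(shape[1], r1)
  cols <- max(1, c0):min(shape[2], c1)
  if (r0 > shape[1] || r1 < 1 || c0 > shape[2] || c1 < 1) return(NULL)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- if (len2 == 0) matrix(0, length(rows), length(cols)) else
    pmin(1, pmax(0, ((rr - p0[1]) * d[1] + (cc - p0[2]) * d[2]) / len2))
  dist <- sqrt((rr - (p0[1] + t * d[1]))^2 + (cc - (p0[2] + t * d[2]))^2)
  cov <- pmin(1, pmax(0, width / 2 + 0.5 - dist))
  list(rows = rows, cols = cols, cov = cov)
}

# Anti-aliased coverage of a disk within its bounding box.
disk_coverage <- function(shape, center, radius) {
  half <- radius + 1
  rows <- max(1, floor(center[1] - half)):min(shape[1], ceiling(center[1] + half))
  cols <- max(1, floor(center[2] - half)):min(shape[2], ceiling(center[2] + half))
  if (length(rows) == 0 || length(cols) == 0) return(NULL)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  cov <- pmin(1, pmax(0, radius + 0.5 - d))
  list(rows = rows, cols = cols, cov = cov)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> core", x$true_core_area, "px, outgrowth",
      x$true_outgrowth_area, "px,", nrow(x$detached_cell_centers),
      "detached cells\n")
  invisible(x)
}

#' Generate a replicated synthetic condition with a known outgrowth fold
#'
#' Produces `n_replicates` independently seeded renders of a scene whose
#' expected true outgrowth area is `fold_outgrowth` times that of `base`,
#' emulating a stimulated-versus-unstimulated experimental contrast with a
#' known effect size. The fold is imposed analytically by rescaling the
#' number of sprouts (to the nearest integer) and absorbing the remainder
#' into the mean sprout length; the detached-cell contribution is held fixed
#' and compensated by the sprout term.
#'
#' @param base A [spheroid_scene()] defining the reference condition.
#' @param fold_outgrowth Positive scale factor on the expected outgrowth
#'   area.
#' @param n_replicates Number of replicates, between 2 and 16 (mirroring the
#'   2-7 biological replicates typical of spheroid assays).
#' @param seed Integer seed from which per-replicate seeds are derived.
#' @return A tibble with one row per replicate: `replicate`, `seed`,
#'   `fold`, and list-columns `stack` and `truth` as returned by
#'   [render_scene()].
#' @examples
#' reps <- make_condition_set(spheroid_scene(n_detached_cells = 0),
#'                            fold_outgrowth = 2, n_replicates = 2, seed = 1)
#' reps$truth[[1]]$true_outgrowth_area
#' @export
make_condition_set <- function(base, fold_outgrowth, n_replicates, seed) {
  stopifnot(inherits(base, "spheroid_scene"))
  if (!is.numeric(fold_outgrowth) || fold_outgrowth <= 0) {
    stop("fold_outgrowth must be > 0")
  }
  if (n_replicates < 2 || n_replicates > 16) {
    stop("n_replicates must be between 2 and 16")
  }
  unit <- base$sprout_length_mean * base$sprout_width
  detached_area <- base$n_detached_cells * pi * base$detached_cell_radius^2
  target_sprout <- fold_outgrowth * expected_outgrowth_area(base) - detached_area
  if (target_sprout < 0) {
    stop("fold_outgrowth too small: detached cells alone exceed the target outgrowth area")
  }
  if (target_sprout > 0 && base$n_sprouts == 0) {
    stop("base scene has no sprouts to scale")
  }
  n_new <- if (target_sprout == 0) 0L else max(1L, as.integer(round(target_sprout / unit)))
  len_new <- if (n_new > 0) {
    max(5, base$sprout_length_mean * target_sprout / (n_new * unit))
  } else {
    base$sprout_length_mean
  }
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_replicates))
  rows <- purrr::map(seq_len(n_replicates), function(i) {
    sc <- base
    sc$n_sprouts <- n_new
    sc$sprout_length_mean <- len_new
    sc$seed <- seeds[i]
    r <- render_scene(sc)
    tibble::tibble(replicate = i, seed = seeds[i], fold = fold_outgrowth,
                   stack = list(r$stack), truth = list(r$truth))
  })
  dplyr::bind_rows(rows)
}
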