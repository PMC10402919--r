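#' Measure region areas, ratio and per-channel integrated densities
#'
#' Computes, for one projected image and its region label map, the
#' measurement parameters of the spheroid assay: core and outgrowth areas
#' (pixels, and µm² when the image is calibrated), the outgrowth/core area
#' ratio, and for every channel and region the mean fluorescence intensity,
#' the integrated density and its percentage of the total integrated
#' density. Integrated density is computed as the direct sum of pixel
#' intensities over the region; this equals mean intensity × area by
#' definition and the identity is asserted. The percentage total is
#' core + outgrowth by default (the two measured areas); set
#' `include_background = TRUE` to add the background term for QC.
#'
#' Missing-value semantics: the ratio is `NA` when the core is empty (never
#' a division by zero); a channel's percentages are `NA` when its total
#' integrated density over the measured regions is zero; the mean intensity
#' of an empty region is `NA` and its integrated density 0.
#'
#' @param img A [projected_image()].
#' @param labels A [region_label_map()] of the same shape.
#' @param include_background Include background in the percentage
#'   denominator (default `FALSE`).
#' @return A `region_metrics` object. [tidy()] returns the per-channel,
#'   per-region tibble (`channel`, `region`, `area_px`, `mean_intensity`,
#'   `integrated_density`, `pct_total_integrated_density`); [glance()]
#'   returns a one-row tibble of areas, ratio and QC flags.
#' @examples
#' r <- render_scene(spheroid_scene(n_sprouts = 3, n_detached_cells = 4))
#' m <- measure_regions(project(r$stack), refine_regions(
#'   threshold_fallback(project(r$stack)) |> derive_regions_from_cellmask()))
#' glance(m)$outgrowth_core_ratio
#' @export
measure_regions <- function(img, labels, include_background = FALSE) {
  stopifnot(inherits(img, "projected_image"), inherits(labels, "region_label_map"))
  shp <- image_shape(img)
  if (!all(dim(labels$labels) == shp)) {
    stop("image (", paste(shp, collapse = "x"), ") and label map (",
         paste(dim(labels$labels), collapse = "x"), ") shapes differ")
  }
  lab <- labels$labels
  regions <- c("core", "outgrowth", "background")
  region_idx <- list(core = lab == 1L, outgrowth = lab == 2L,
                     background = lab == 0L)
  areas <- vapply(region_idx, sum, numeric(1))

  rows <- list()
  for (ch in seq_along(img$channel_names)) {
    m <- img$pixels[ch, , ]
    for (rg in regions) {
      a <- areas[[rg]]
      s <- sum(m[region_idx[[rg]]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = img$channel_names[ch], region = rg, area_px = a,
        mean_intensity = if (a > 0) s / a else NA_real_,
        integrated_density = s
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  # definitional identity: mean x area must reproduce the direct sum
  chk <- tab[tab$area_px > 0, ]
  stopifnot(all(abs(chk$mean_intensity * chk$area_px - chk$integrated_density) <=
                  1e-9 * pmax(1, abs(chk$integrated_density))))

  denom_regions <- if (include_background) regions else c("core", "outgrowth")
  tab <- dplyr::group_by(tab, .data$channel)
  tab <- dplyr::mutate(tab, pct_total_integrated_density = {
    tot <- sum(.data$integrated_density[.data$region %in% denom_regions])
    ifelse(.data$region %in% denom_regions & tot > 0,
           100 * .data$integrated_density / tot, NA_real_)
  })
  tab <- dplyr::ungroup(tab)

  px_area <- if (!is.null(img$pixel_size)) img$pixel_size^2 else NA_real_
  structure(
    list(
      core_area_px = areas[["core"]],
      outgrowth_area_px = areas[["outgrowth"]],
      core_area_um2 = areas[["core"]] * px_area,
      outgrowth_area_um2 = areas[["outgrowth"]] * px_area,
      outgrowth_core_ratio = if (areas[["core"]] > 0)
        areas[["outgrowth"]] / areas[["core"]] else NA_real_,
      table = tab,
      qc_flags = labels$qc_flags,
      include_background = include_background
    ),
    class = "region_metrics"
  )
}

#' @export
print.region_metrics <- function(x, ...) {
  cat("<region_metrics> core ", x$core_area_px, " px, outgrowth ",
      x$outgrowth_area_px, " px, ratio ",
      if (is.na(x$outgrowth_core_ratio)) "NA (empty core)"
      else round(x$outgrowth_core_ratio, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.region_metrics <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.region_metrics <- function(x, ...) {
  tibble::tibble(
    core_area_px = x$core_area_px,
    outgrowth_area_px = x$outgrowth_area_px,
    core_area_um2 = x$core_area_um2,
    outgrowth_area_um2 = x$outgrowth_area_um2,
    outgrowth_core_ratio = x$outgrowth_core_ratio,
    n_qc_flags = length(x$qc_flags),
    qc_flags = paste(x$qc_flags, collapse = "; ")
  )
}

# One wide row for the per-image cohort CSV: glance + pivoted channel table.
metrics_row <- function(metrics) {
  wide <- tidyr::pivot_wider(
    dplyr::filter(tidy(metrics), .data$region != "background"),
    id_cols = c(),
    names_from = c("channel", "region"),
    values_from = c("mean_intensity", "integrated_density",
                    "pct_total_integrated_density"),
    names_glue = "{.value}_{channel}_{region}"
  )
  dplyr::bind_cols(glance(metrics), wide)
}

#' Detect and count cells outside the core
#'
#' Finds individual cells (small bright blobs) in one channel — by default
#' the macrophage channel, the detached cell type of the assay — using
#' scale-normalised Laplacian-of-Gaussian detection over a range of scales.
#' Detection is restricted to pixels outside the core after dilating the
#' core mask by `exclusion_margin` to avoid rim artefacts; detections in
#' background-labeled pixels are kept, because a cell whose dim halo was
#' classified background is still a migrated cell. Maxima below the
#' response threshold are discarded and maxima closer than `min_separation`
#' are merged, keeping the stronger.
#'
#' The response threshold defaults to `0.2 *` the channel's maximum
#' intensity, expressed in scale-normalised LoG units; for a uniform disk
#' of the matched scale the peak response is roughly half the disk
#' amplitude, so the default keeps blobs at half the nominal brightness
#' while rejecting noise maxima at the stated noise regimes.
#'
#' @param img A [projected_image()].
#' @param labels A [region_label_map()] of the same shape.
#' @param channel Channel name or index to search (default
#'   `"MACROPHAGE"` when present, else the last channel).
#' @param sigma_range `(min, max)` blob scales in pixels; a blob of radius r
#'   is matched at sigma near `r / sqrt(2)`.
#' @param n_sigma Number of scales, geometrically spaced.
#' @param threshold Absolute response threshold; `NULL` for the default
#'   above.
#' @param min_separation Minimum distance between detections in pixels.
#' @param exclusion_margin Core dilation radius in pixels.
#' @return A `cell_detections` tibble (`row`, `col`, `sigma`, `response`)
#'   with attributes `count`, `channel` and `params`.
#' @examples
#' r <- render_scene(spheroid_scene(n_sprouts = 0, n_detached_cells = 8))
#' det <- detect_cells_outside_core(project(r$stack), truth_labels(r$truth))
#' attr(det, "count")
#' @export
detect_cells_outside_core <- function(img, labels, channel = NULL,
                                      sigma_range = c(1.5, 4), n_sigma = 4L,
                                      threshold = NULL, min_separation = 5,
                                      exclusion_margin = 2L) {
  stopifnot(inherits(img, "projected_image"), inherits(labels, "region_label_map"))
  channel <- channel %||%
    (if ("MACROPHAGE" %in% img$channel_names) "MACROPHAGE"
     else length(img$channel_names))
  m <- channel_matrix(img, channel)
  thr <- threshold %||% (0.2 * max(m))

  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_sigma))
  resp <- lapply(sigmas, function(s) {
    -s^2 * conv2_reflect(gaussian_blur(m, s), LAPLACIAN_KERNEL)
  })

  core <- labels$labels == 1L
  excluded <- if (any(core)) {
    EBImage::dilate(core + 0, disc_brush(exclusion_margin)) > 0
  } else core

  cand <- list()
  for (k in seq_along(sigmas)) {
    mx <- local_maxima(resp[[k]])
    # require a maximum across neighbouring scales too
    if (k > 1) mx <- mx & (resp[[k]] >= resp[[k - 1]])
    if (k < length(sigmas)) mx <- mx & (resp[[k]] >= resp[[k + 1]])
    mx <- mx & !excluded & (resp[[k]] >= thr)
    if (any(mx)) {
      idx <- which(mx, arr.ind = TRUE)
      cand[[length(cand) + 1L]] <- tibble::tibble(
        row = as.numeric(idx[, 1]), col = as.numeric(idx[, 2]),
        sigma = sigmas[k], response = resp[[k]][mx]
      )
    }
  }
  det <- if (length(cand) > 0) dplyr::bind_rows(cand) else
    tibble::tibble(row = numeric(0), col = numeric(0), sigma = numeric(0),
                   response = numeric(0))
  det <- dplyr::arrange(det, dplyr::desc(.data$response))
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- det[keep, , drop = FALSE]
    d2 <- (prev$row - det$row[i])^2 + (prev$col - det$col[i])^2
    keep[i] <- all(d2 >= min_separation^2)
  }
  det <- det[keep, , drop = FALSE]
  structure(
    det,
    class = c("cell_detections", class(det)),
    count = nrow(det),
    channel = if (is.character(channel)) channel else
      img$channel_names[channel],
    params = list(sigma_range = sigma_range, n_sigma = n_sigma,
                  threshold = thr, min_separation = min_separation,
                  exclusion_margin = exclusion_margin)
  )
}

#' Label map from synthetic ground truth
#'
#' Convenience for validation workflows: turns the exact truth masks of a
#' rendered scene into a [region_label_map()] (provenance `"truth"`).
#'
#' @param truth A `synthetic_truth`.
#' @return A [region_label_map()].
#' @export
truth_labels <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth_label_map(truth)
}
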