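#' Per-pixel region label maps
#'
#' A region label map assigns every pixel of a projected image to one of
#' three semantic classes: `0` background, `1` core (the cohesive central
#' cell mass of the spheroid) and `2` outgrowth (everything cell-covered
#' outside the core — sprouts still attached to it as well as detached
#' single cells). Raw classifier output may contain several core fragments
#' or speckle; [refine_regions()] enforces the single-core convention.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @param provenance `"classifier"`, `"fallback"` or `"truth"`.
#' @param qc_flags Character vector of warnings accumulated so far.
#' @return An object of class `region_label_map`.
#' @export
region_label_map <- function(labels, provenance = "classifier",
                             qc_flags = character(0)) {
  stopifnot(is.matrix(labels))
  if (!all(labels %in% 0:2)) stop("labels must be 0 (background), 1 (core) or 2 (outgrowth)")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, provenance = provenance, qc_flags = qc_flags),
    class = "region_label_map"
  )
}

#' @export
print.region_label_map <- function(x, ...) {
  tb <- tabulate(x$labels + 1L, 3L)
  cat("<region_label_map> ", paste0(REGION_NAMES, "=", tb, collapse = ", "),
      " (", x$provenance, ")",
      if (length(x$qc_flags)) paste0("; qc: ", paste(x$qc_flags, collapse = "; ")),
      "\n", sep = "")
  invisible(x)
}

# Label map from a synthetic truth partition (provenance "truth").
truth_label_map <- function(truth) {
  labels <- matrix(0L, nrow(truth$core_mask), ncol(truth$core_mask))
  labels[truth$core_mask] <- 1L
  labels[truth$outgrowth_mask] <- 2L
  region_label_map(labels, provenance = "truth")
}

#' Refine raw pixel labels into one coherent core plus outgrowth
#'
#' Enforces the definition of the measured regions: exactly one cohesive
#' core, and outgrowth as all remaining cell-covered pixels. Core
#' candidates are the 4-connected components of the core class after
#' morphological opening (radius `r_open`) and hole filling; the largest
#' candidate wins, ties broken by centroid proximity to the image centre.
#' The final core is the 4-connected component of the original core class
#' containing the winning candidate, hole-filled — so a clean map passes
#' through unchanged. All other core-labeled pixels are relabeled
#' outgrowth, and outgrowth objects smaller than `min_object_area` are
#' dropped to background as speckle.
#'
#' QC flags are set for an empty core, multiple core candidates, and a core
#' touching the image border (its area is then only a lower bound). An
#' empty core is not an error; downstream the outgrowth/core ratio is
#' reported as missing.
#'
#' @param x A [region_label_map()].
#' @param r_open Opening radius in pixels for candidate detection.
#' @param min_object_area Minimum outgrowth object area in px².
#' @return A refined [region_label_map()].
#' @export
refine_regions <- function(x, r_open = 3L, min_object_area = 9L) {
  stopifnot(inherits(x, "region_label_map"))
  labels <- x$labels
  qc <- x$qc_flags
  core_raw <- labels == 1L
  core_final <- matrix(FALSE, nrow(labels), ncol(labels))

  if (any(core_raw)) {
    opened <- EBImage::fillHull(EBImage::opening(core_raw + 0, disc_brush(r_open)))
    cand <- label_components(opened > 0)
    n_cand <- max(cand)
    if (n_cand == 0) {
      qc <- qc_add(qc, "empty core")
    } else {
      if (n_cand > 1) qc <- qc_add(qc, "multiple core candidates")
      sel <- select_component(cand, c(nrow(labels), ncol(labels)))
      # final core: original-class component containing the candidate
      orig <- label_components(core_raw)
      lab_sel <- unique(orig[cand == sel & orig > 0])
      core_final <- EBImage::fillHull((orig == lab_sel[1]) + 0) > 0
    }
  } else {
    qc <- qc_add(qc, "empty core")
  }

  cellish <- (labels != 0L) | core_final
  outgrowth <- cellish & !core_final
  outgrowth <- remove_small_objects(outgrowth, min_object_area)
  new_labels <- matrix(0L, nrow(labels), ncol(labels))
  new_labels[outgrowth] <- 2L
  new_labels[core_final] <- 1L
  if (any(core_final) && core_touches_border(core_final)) {
    qc <- qc_add(qc, "core touching border")
  }
  region_label_map(new_labels, provenance = x$provenance, qc_flags = qc)
}

# Pick the largest component; break area ties by centroid distance to the
# image centre.
select_component <- function(comp, shape) {
  sizes <- tabulate(comp[comp > 0])
  best <- which(sizes == max(sizes))
  if (length(best) == 1) return(best)
  ctr <- (shape + 1) / 2
  d <- vapply(best, function(k) {
    idx <- which(comp == k, arr.ind = TRUE)
    sqrt((mean(idx[, 1]) - ctr[1])^2 + (mean(idx[, 2]) - ctr[2])^2)
  }, numeric(1))
  best[which.min(d)]
}

core_touches_border <- function(core) {
  any(core[1, ]) || any(core[nrow(core), ]) || any(core[, 1]) || any(core[, ncol(core)])
}

#' Split a binary cell mask into core and outgrowth
#'
#' The second segmentation pathway, for a two-class (cell/background)
#' classifier or the [threshold_fallback()]: thin sprouts are removed by
#' erosion with radius `r_core`, the largest surviving 4-connected
#' component is dilated back, hole-filled and intersected with the mask to
#' give the core; outgrowth is the rest of the mask, after small-object
#' removal. A mask whose every component is thinner than `2 * r_core`
#' erodes away entirely and yields an empty core with a QC flag.
#'
#' @param cell_mask Logical matrix (cell vs background), e.g. from
#'   [threshold_fallback()].
#' @param r_core Erosion radius in pixels; should exceed half the sprout
#'   width and be well below the core radius.
#' @param min_object_area Minimum outgrowth object area in px².
#' @return A [region_label_map()] with provenance `"fallback"`.
#' @export
derive_regions_from_cellmask <- function(cell_mask, r_core = 5L,
                                         min_object_area = 9L) {
  stopifnot(is.logical(cell_mask), is.matrix(cell_mask))
  qc <- attr(cell_mask, "qc_flags") %||% character(0)
  shape <- dim(cell_mask)
  core <- matrix(FALSE, shape[1], shape[2])
  eroded <- if (any(cell_mask)) EBImage::erode(cell_mask + 0, disc_brush(r_core)) > 0
            else cell_mask
  if (any(eroded)) {
    comp <- label_components(eroded)
    if (max(comp) > 1) qc <- qc_add(qc, "multiple core candidates")
    sel <- select_component(comp, shape)
    dil <- EBImage::dilate((comp == sel) + 0, disc_brush(r_core)) > 0
    core <- (EBImage::fillHull(dil) > 0) & cell_mask
  } else {
    qc <- qc_add(qc, "empty core")
  }
  outgrowth <- remove_small_objects(cell_mask & !core, min_object_area)
  labels <- matrix(0L, shape[1], shape[2])
  labels[outgrowth] <- 2L
  labels[core] <- 1L
  if (any(core) && core_touches_border(core)) {
    qc <- qc_add(qc, "core touching border")
  }
  region_label_map(labels, provenance = "fallback", qc_flags = qc)
}

#' Read or write a region label map as an 8-bit TIFF
#'
#' The fixed palette is 0 = background, 1 = core, 2 = outgrowth; QC flags
#' and provenance go to a JSON sidecar (`<path>.json`).
#'
#' @param x A [region_label_map()].
#' @param path TIFF file path.
#' @return `path` / the label map.
#' @export
write_label_map <- function(x, path) {
  stopifnot(inherits(x, "region_label_map"))
  tiff::writeTIFF(x$labels / 255, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(provenance = x$provenance, qc_flags = x$qc_flags),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else
    list(provenance = "file", qc_flags = character(0))
  region_label_map(m, provenance = meta$provenance,
                   qc_flags = as.character(meta$qc_flags))
}
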