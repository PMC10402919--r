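#' Read and validate a condition manifest
#'
#' The manifest maps images to experimental conditions: a CSV with columns
#' `path`, `condition`, optionally `batch` (donor / experiment id shared
#' across conditions for paired summaries) and `model_override` (path to a
#' per-image classifier archive, for pictures where the pooled classifier
#' needs re-adjustment). Every condition must have at least two images
#' (biological replicates).
#'
#' @param path CSV file path, or a data frame already in manifest form.
#' @return A validated tibble.
#' @export
read_manifest <- function(path) {
  m <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("path", "condition") %in% names(m))) {
    stop("manifest needs at least the columns 'path' and 'condition'")
  }
  if (!"batch" %in% names(m)) m$batch <- NA_character_
  if (!"model_override" %in% names(m)) m$model_override <- NA_character_
  m$condition <- as.character(m$condition)
  if (any(!nzchar(m$condition) | is.na(m$condition))) {
    stop("condition labels must be non-empty")
  }
  n_per <- table(m$condition)
  if (any(n_per < 2)) {
    stop("every condition needs >= 2 images (replicates); too few for: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  m
}

#' Run the full quantification pipeline over a manifest
#'
#' For every image: read the stack, project it, label pixels with the
#' trained classifier (or the threshold fallback when `model` is `NULL`),
#' refine the labels into core and outgrowth, measure areas, ratio and
#' integrated densities, and count cells outside the core. Per-image
#' failures are recorded and skipped, never aborting the batch. Everything
#' is deterministic given the model and the inputs, so reruns produce
#' byte-identical outputs.
#'
#' Images flagged `"empty core"` are excluded from ratio and percentage
#' condition summaries (their other metrics are kept); exclusions are
#' listed in the returned object and in the exclusion log.
#'
#' @param manifest A manifest (path, data frame, or [read_manifest()]
#'   output).
#' @param model A [pixel_classifier][train_pixel_classifier()], a path to a
#'   saved one, or `NULL` for the threshold fallback.
#' @param reference Reference condition for fold changes; defaults to the
#'   first condition in the manifest.
#' @param detect_channel Channel searched by
#'   [detect_cells_outside_core()]; default macrophage.
#' @param projection Projection method passed to [project()].
#' @param out_dir Optional directory for the per-image CSV
#'   (`per_image_metrics.csv`), summary CSV (`condition_summary.csv`),
#'   exclusion log (`exclusions.csv`) and run-config snapshot
#'   (`run_config.json`).
#' @param r_open,min_object_area Passed to [refine_regions()].
#' @param r_core Passed to [derive_regions_from_cellmask()] on the fallback
#'   path.
#' @return A `cohort_result` list: `per_image` tibble, `summary` tibble
#'   (from [condition_summary()]), `exclusions` tibble, `reference`.
#' @export
run_pipeline <- function(manifest, model = NULL, reference = NULL,
                         detect_channel = NULL, projection = "max",
                         out_dir = NULL, r_open = 3L, min_object_area = 9L,
                         r_core = 5L) {
  manifest <- read_manifest(manifest)
  reference <- reference %||% manifest$condition[1]
  if (!reference %in% manifest$condition) {
    stop("reference condition '", reference, "' not present in the manifest")
  }
  if (is.character(model)) model <- load_classifier(model)

  rows <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    row <- tryCatch({
      mdl <- model
      if (!is.na(rec$model_override) && nzchar(rec$model_override)) {
        mdl <- load_classifier(rec$model_override)
      }
      st <- read_stack(rec$path)
      img <- project(st, method = projection)
      labels <- if (!is.null(mdl)) {
        refine_regions(apply_pixel_classifier(mdl, img)$labels,
                       r_open = r_open, min_object_area = min_object_area)
      } else {
        derive_regions_from_cellmask(threshold_fallback(img),
                                     r_core = r_core,
                                     min_object_area = min_object_area)
      }
      metrics <- measure_regions(img, labels)
      det <- detect_cells_outside_core(img, labels, channel = detect_channel)
      dplyr::bind_cols(
        tibble::tibble(image = basename(rec$path), path = rec$path,
                       condition = rec$condition, batch = rec$batch),
        metrics_row(metrics),
        tibble::tibble(cells_outside_core = attr(det, "count"))
      )
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- tibble::tibble(
        image = basename(rec$path), condition = rec$condition,
        reason = conditionMessage(e)
      )
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  per_image <- dplyr::bind_rows(rows)
  if (nrow(per_image) == 0) stop("every image in the batch failed")
  left <- table(per_image$condition)
  gone <- setdiff(unique(manifest$condition), names(left))
  if (length(gone) > 0) {
    stop("condition(s) empty after per-image failures: ",
         paste(gone, collapse = ", "))
  }

  exclusions <- dplyr::bind_rows(
    dplyr::bind_rows(failures),
    dplyr::transmute(
      dplyr::filter(per_image, grepl("empty core", .data$qc_flags)),
      image = .data$image, condition = .data$condition,
      reason = "empty core: excluded from ratio and percentage summaries"
    )
  )
  summary <- condition_summary(per_image, reference = reference)

  result <- structure(
    list(per_image = per_image, summary = summary, exclusions = exclusions,
         reference = reference),
    class = "cohort_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(per_image, file.path(out_dir, "per_image_metrics.csv"))
    readr::write_csv(summary, file.path(out_dir, "condition_summary.csv"))
    readr::write_csv(exclusions, file.path(out_dir, "exclusions.csv"))
    jsonlite::write_json(
      list(reference = reference, projection = projection,
           classifier = if (is.null(model)) "threshold_fallback" else "pixel_classifier",
           r_open = r_open, min_object_area = min_object_area,
           r_core = r_core),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  result
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", nrow(x$per_image), " image(s), ",
      length(unique(x$per_image$condition)), " condition(s), reference '",
      x$reference, "', ", nrow(x$exclusions), " exclusion(s)\n", sep = "")
  invisible(x)
}

#' Per-condition means, spreads and fold changes
#'
#' Aggregates a per-image metrics table into per-condition `n`, `mean`,
#' `sd`, `sem` for every numeric metric, plus the fold change of the
#' condition mean over the reference-condition mean (so the reference's
#' fold change is exactly 1). Images with an empty core contribute no ratio
#' or percentage values (those are `NA` and dropped metric-wise); `n`
#' counts the images that contributed to each metric.
#'
#' @param per_image Per-image metrics tibble (from [run_pipeline()], or any
#'   tibble with a `condition` column and numeric metric columns).
#' @param reference Reference condition label.
#' @param metrics Optional character vector restricting the summarised
#'   columns.
#' @return A tibble with columns `condition`, `metric`, `n`, `mean`, `sd`,
#'   `sem`, `fold_change`.
#' @export
condition_summary <- function(per_image, reference = NULL, metrics = NULL) {
  stopifnot(is.data.frame(per_image), "condition" %in% names(per_image))
  reference <- reference %||% per_image$condition[1]
  num_cols <- names(per_image)[vapply(per_image, is.numeric, logical(1))]
  if (!is.null(metrics)) num_cols <- intersect(num_cols, metrics)
  long <- tidyr::pivot_longer(
    per_image[, c("condition", num_cols)],
    cols = dplyr::all_of(num_cols), names_to = "metric", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$metric),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop"
  )
  ref <- dplyr::select(
    dplyr::filter(out, .data$condition == reference),
    "metric", ref_mean = "mean"
  )
  out <- dplyr::left_join(out, ref, by = "metric")
  out$fold_change <- ifelse(out$ref_mean != 0, out$mean / out$ref_mean, NA_real_)
  out$ref_mean <- NULL
  out
}

#' Per-batch paired comparison of one metric
#'
#' For repeated-measures designs where each batch (donor) contributes one
#' image per condition: returns the reference and condition values side by
#' side with their per-batch ratio. No inferential statistics are computed;
#' the table is ready for any statistics environment.
#'
#' @param result A `cohort_result` from [run_pipeline()], or a per-image
#'   tibble with `condition`, `batch` and the metric column.
#' @param metric Name of the metric column, e.g.
#'   `"outgrowth_core_ratio"`.
#' @param condition Condition to compare against the reference.
#' @param reference Reference condition; defaults to the result's.
#' @return A tibble (`batch`, `reference_value`, `condition_value`,
#'   `ratio`).
#' @export
paired_summary <- function(result, metric, condition, reference = NULL) {
  per_image <- if (inherits(result, "cohort_result")) result$per_image else result
  reference <- reference %||%
    (if (inherits(result, "cohort_result")) result$reference else
       per_image$condition[1])
  stopifnot(metric %in% names(per_image), "batch" %in% names(per_image))
  ref <- per_image[per_image$condition == reference, c("batch", metric)]
  cmp <- per_image[per_image$condition == condition, c("batch", metric)]
  names(ref)[2] <- "reference_value"
  names(cmp)[2] <- "condition_value"
  unmatched <- union(setdiff(cmp$batch, ref$batch), setdiff(ref$batch, cmp$batch))
  if (length(unmatched) > 0) {
    stop("batch(es) not present in both conditions: ",
         paste(unmatched, collapse = ", "))
  }
  out <- dplyr::inner_join(ref, cmp, by = "batch")
  out$ratio <- out$condition_value / out$reference_value
  tibble::as_tibble(out)
}
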