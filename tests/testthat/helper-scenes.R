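# Shared fixtures, built in code. Heavy objects (trained classifier, the
# segmentation sweep) are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small, fast scene family for unit tests
small_scene <- function(...) {
  args <- list(...)
  defaults <- list(
    image_shape = c(128L, 128L), core_radius = 22, n_sprouts = 6,
    sprout_length_mean = 28, sprout_length_sd = 5, sprout_width = 3,
    n_detached_cells = 10, detached_cell_radius = 3, detached_ring = c(30, 58)
  )
  do.call(spheroid_scene, utils::modifyList(defaults, args))
}

# classifier trained on a pool of two representative full-size scenes
# (one near-noiseless, one at 20% of the nominal intensity)
shared_model <- function() cache_get("model", function() {
  pool <- lapply(c(10, 40), function(ns) {
    render_scene(spheroid_scene(seed = 77 + ns, noise_sigma = ns))
  })
  train_pixel_classifier(
    images = lapply(pool, function(r) project(r$stack)),
    annotations = lapply(pool, function(r) {
      annotate_from_truth(r$truth, fraction = 0.02, seed = 1)
    }),
    seed = 1
  )
})

# 20-scene segmentation sweep at noise up to 20% of the nominal intensity;
# returns per-scene IoU and relative area errors
segmentation_sweep <- function() cache_get("sweep", function() {
  model <- shared_model()
  noise_levels <- rep(c(0, 10, 20, 30, 40), 4)
  rows <- lapply(seq_along(noise_levels), function(i) {
    r <- render_scene(spheroid_scene(seed = 1000 + i,
                                     noise_sigma = noise_levels[i]))
    img <- project(r$stack)
    lm <- refine_regions(apply_pixel_classifier(model, img)$labels)
    tibble::tibble(
      scene = i, noise_sigma = noise_levels[i],
      iou_core = iou(lm$labels == 1, r$truth$core_mask),
      iou_outgrowth = iou(lm$labels == 2, r$truth$outgrowth_mask),
      core_rel_err = abs(sum(lm$labels == 1) - r$truth$true_core_area) /
        r$truth$true_core_area,
      outgrowth_rel_err = abs(sum(lm$labels == 2) - r$truth$true_outgrowth_area) /
        r$truth$true_outgrowth_area,
      measured_ratio = sum(lm$labels == 2) / sum(lm$labels == 1),
      true_ratio = r$truth$true_outgrowth_area / r$truth$true_core_area
    )
  })
  dplyr::bind_rows(rows)
})

# two-condition synthetic cohort (written to TIFF) with a 2x expected
# outgrowth contrast, quantified twice for the determinism check
cohort_fixture <- function() cache_get("cohort", function() {
  dir <- file.path(tempdir(), "outgrowthr-cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- spheroid_scene(seed = 3, noise_sigma = 20)
  rows <- list()
  for (cond in c("UNSTIM", "STIM")) {
    fold <- if (cond == "UNSTIM") 1 else 2
    cs <- make_condition_set(base, fold, n_replicates = 8,
                             seed = if (fold == 1) 11 else 22)
    for (i in seq_len(nrow(cs))) {
      p <- file.path(dir, paste0(cond, "_", i, ".tif"))
      write_stack(cs$stack[[i]], p)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = p, condition = cond, batch = paste0("b", i)
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  res1 <- run_pipeline(manifest, model = shared_model(),
                       reference = "UNSTIM", out_dir = out1)
  res2 <- run_pipeline(manifest, model = shared_model(),
                       reference = "UNSTIM", out_dir = out2)
  list(manifest = manifest, res1 = res1, res2 = res2,
       out1 = out1, out2 = out2)
})

iou <- function(a, b) sum(a & b) / sum(a | b)

# distance from each detection to its nearest planted centre
match_distances <- function(detections, centers) {
  vapply(seq_len(nrow(detections)), function(i) {
    min(sqrt((centers$row - detections$row[i])^2 +
               (centers$col - detections$col[i])^2))
  }, numeric(1))
}
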