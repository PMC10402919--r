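test_that("training on subsampled truth reaches high held-out accuracy", {
  model <- shared_model()
  expect_gt(glance(model)$holdout_accuracy, 0.95)
  expect_identical(tidy(model)$class, c("background", "core", "outgrowth"))
  expect_true(all(tidy(model)$n_labeled > 0))
})

test_that("training and inference are deterministic for a fixed seed", {
  r <- render_scene(small_scene(seed = 21, noise_sigma = 20))
  img <- project(r$stack)
  ann <- annotate_from_truth(r$truth, fraction = 0.01, seed = 2)
  m1 <- train_pixel_classifier(img, ann, seed = 9, num_trees = 30)
  m2 <- train_pixel_classifier(img, ann, seed = 9, num_trees = 30)
  probe <- project(render_scene(small_scene(seed = 22, noise_sigma = 20))$stack)
  p1 <- apply_pixel_classifier(m1, probe)
  p2 <- apply_pixel_classifier(m2, probe)
  expect_identical(p1$labels$labels, p2$labels$labels)
  expect_identical(p1$probabilities, p2$probabilities)
})

test_that("a classifier trained on one scene transfers to another from the same distribution", {
  model <- shared_model()
  te <- render_scene(spheroid_scene(seed = 555, noise_sigma = 20))
  res <- apply_pixel_classifier(model, project(te$stack))
  lm <- refine_regions(res$labels)
  expect_gt(iou(lm$labels == 1, te$truth$core_mask), 0.8)
  expect_gt(iou(lm$labels == 2, te$truth$outgrowth_mask), 0.8)
})

test_that("probability maps are normalised and degenerate input is all background", {
  model <- shared_model()
  zero <- projected_image(array(0, c(3, 48, 48)),
                          channel_names = model$channel_names)
  res <- apply_pixel_classifier(model, zero)
  expect_true(all(res$labels$labels == 0L))
  sums <- apply(res$probabilities, c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("channel mismatches and missing classes are reported by name", {
  model <- shared_model()
  one_ch <- projected_image(array(0, c(1, 32, 32)))
  expect_error(apply_pixel_classifier(model, one_ch), "channel mismatch")

  r <- render_scene(small_scene(seed = 30))
  img <- project(r$stack)
  ann <- annotate_from_truth(r$truth, fraction = 0.01, seed = 1)
  ann[ann == 2L] <- 0L   # drop every core label
  expect_error(train_pixel_classifier(img, ann), "core")
})

test_that("a fixed sub-quantisation threshold recovers the noiseless cell mask exactly", {
  r <- render_scene(small_scene(seed = 31, noise_sigma = 0))
  img <- project(r$stack)
  mask <- threshold_fallback(img, threshold = 0.5)
  expect_identical(as.vector(mask),
                   as.vector(r$truth$core_mask | r$truth$outgrowth_mask))
  expect_identical(dim(mask), dim(r$truth$core_mask))
})

test_that("otsu picks a threshold between the modes, matching a brute-force search", {
  vals <- withr::with_seed(13, c(rnorm(600, 40, 6), rnorm(400, 200, 12)))
  vals <- pmax(vals, 0)
  img <- projected_image(array(vals, c(1, 25, 40)))
  mask <- threshold_fallback(img)
  thr <- attr(mask, "threshold")
  expect_gt(thr, 60); expect_lt(thr, 180)
  # oracle: exhaustive between-class variance over every candidate split
  cand <- sort(unique(vals))
  bcv <- vapply(cand[-length(cand)], function(t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  best <- cand[which.max(bcv)]
  expect_lt(abs(thr - best), diff(range(vals)) / 256 * 2 + 1e-9)
})

test_that("a threshold above the maximum yields an empty, flagged mask", {
  img <- projected_image(array(runif(32 * 32, 0, 10), c(1, 32, 32)))
  mask <- threshold_fallback(img, threshold = 100)
  expect_false(any(mask))
  expect_identical(attr(mask, "qc_flags"), "empty cell mask")
})

test_that("annotation files round-trip: label masks and polygons", {
  ann <- matrix(0L, 16, 16)
  ann[2:4, 2:4] <- 1L; ann[8:10, 8:10] <- 2L; ann[14, 1:5] <- 3L
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(ann / 255, f, bits.per.sample = 8L)
  expect_identical(read_label_mask(f), ann)

  poly <- list(list(
    class = "core",
    vertices = list(c(9.5, 14.5), c(9.5, 25.5), c(20.5, 25.5), c(20.5, 14.5))
  ))
  pf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(poly, pf, auto_unbox = TRUE)
  got <- read_polygon_annotations(pf, shape = c(30, 30))
  expect_identical(sum(got == 2L), 11L * 11L)
  expect_true(all(got[10:20, 15:25] == 2L))
})

test_that("a saved classifier archive reloads and predicts identically", {
  model <- shared_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, f)
  back <- load_classifier(f)
  probe <- project(render_scene(small_scene(seed = 23, noise_sigma = 10))$stack)
  expect_identical(apply_pixel_classifier(back, probe)$labels$labels,
                   apply_pixel_classifier(model, probe)$labels$labels)
})
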