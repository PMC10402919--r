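test_that("refinement is a no-op on an exact truth partition", {
  r <- render_scene(small_scene(seed = 40))
  lm <- truth_labels(r$truth)
  ref <- refine_regions(lm)
  expect_identical(ref$labels, lm$labels)
  expect_identical(ref$qc_flags, character(0))
})

test_that("the largest core blob wins and stray core islands become outgrowth", {
  labels <- matrix(0L, 64, 64)
  labels[20:44, 20:39] <- 1L           # 25 x 20 = 500 px core
  labels[5:12, 50:59] <- 1L            # 8 x 10 = 80 px stray island
  labels[50:55, 10:30] <- 2L           # some outgrowth
  ref <- refine_regions(region_label_map(labels))
  expect_identical(sum(ref$labels == 1L), 500L)
  expect_true(all(ref$labels[20:44, 20:39] == 1L))
  expect_true(all(ref$labels[5:12, 50:59] == 2L))  # relabeled, 80 >= min area
  expect_true("multiple core candidates" %in% ref$qc_flags)
})

test_that("maps without core pixels are flagged, not errors", {
  labels <- matrix(0L, 32, 32)
  labels[5:8, 5:28] <- 2L
  ref <- refine_regions(region_label_map(labels))
  expect_identical(sum(ref$labels == 1L), 0L)
  expect_true("empty core" %in% ref$qc_flags)
})

test_that("refinement is idempotent and always yields a partition", {
  model <- shared_model()
  te <- render_scene(spheroid_scene(seed = 60, noise_sigma = 30))
  raw <- apply_pixel_classifier(model, project(te$stack))$labels
  once <- refine_regions(raw)
  twice <- refine_regions(once)
  expect_identical(twice$labels, once$labels)
  expect_true(all(once$labels %in% 0:2))
  # exactly one 4-connected core component
  comp <- EBImage::bwlabel((once$labels == 1L) + 0)
  expect_equal(max(comp), 1)
})

test_that("speckle below the minimum object area is dropped from outgrowth", {
  labels <- matrix(0L, 48, 48)
  labels[20:29, 20:29] <- 1L
  labels[5, 5] <- 2L                   # 1 px speck
  labels[40:41, 40:43] <- 2L           # 8 px < 9
  labels[10:12, 35:40] <- 2L           # 18 px survives
  ref <- refine_regions(region_label_map(labels))
  expect_identical(sum(ref$labels == 2L), 18L)
})

test_that("erosion splits a thresholded mask into disk core and sprout outgrowth", {
  sc <- small_scene(seed = 41, n_detached_cells = 0)
  r <- render_scene(sc)
  mask <- r$truth$core_mask | r$truth$outgrowth_mask
  lm <- derive_regions_from_cellmask(mask, min_object_area = 1)
  core_area <- sum(lm$labels == 1L)
  perim <- 2 * pi * (sc$core_radius + 1)
  expect_lt(abs(core_area - r$truth$true_core_area), perim)
  # with no small-object removal, every cell pixel stays cell-labeled
  expect_identical(sum(lm$labels > 0L), sum(mask))
})

test_that("a bare disk yields no outgrowth and bare sprouts yield no core", {
  disk <- render_scene(small_scene(seed = 42, n_sprouts = 0,
                                   n_detached_cells = 0))
  lm <- derive_regions_from_cellmask(disk$truth$core_mask)
  expect_identical(sum(lm$labels == 2L), 0L)
  expect_identical(lm$qc_flags, character(0))

  thin <- matrix(FALSE, 64, 64)        # stripes thinner than 2 * r_core
  thin[c(10:12, 30:32, 50:52), 5:60] <- TRUE
  lm2 <- derive_regions_from_cellmask(thin, r_core = 5)
  expect_identical(sum(lm2$labels == 1L), 0L)
  expect_true("empty core" %in% lm2$qc_flags)
})

test_that("label maps round-trip through 8-bit TIFF with their QC sidecar", {
  labels <- withr::with_seed(17, matrix(sample(0:2, 36 * 36, replace = TRUE), 36, 36))
  lm <- region_label_map(labels, provenance = "fallback",
                         qc_flags = "core touching border")
  f <- withr::local_tempfile(fileext = ".tif")
  write_label_map(lm, f)
  back <- read_label_map(f)
  expect_identical(back$labels, lm$labels)
  expect_identical(back$qc_flags, lm$qc_flags)
  expect_identical(back$provenance, "fallback")
})
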