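test_that("the ratio and integrated density follow their definitions on constructed input", {
  labels <- matrix(0L, 30, 30)
  labels[1:10, 1:10] <- 1L             # core: 100 px
  labels[21:30, 1:20] <- 2L            # outgrowth: 200 px
  px <- array(0, c(1, 30, 30))
  px[1, 1:10, 1:10] <- 10              # mean 10 over the core
  img <- projected_image(px, channel_names = "A")
  m <- measure_regions(img, region_label_map(labels))
  expect_equal(glance(m)$outgrowth_core_ratio, 2.0)
  tab <- tidy(m)
  core_row <- tab[tab$region == "core", ]
  expect_equal(core_row$integrated_density, 1000)
  expect_equal(core_row$mean_intensity * core_row$area_px, 1000)
  expect_equal(core_row$pct_total_integrated_density, 100)
})

test_that("calibrated areas use the squared pixel size", {
  labels <- matrix(0L, 10, 10); labels[1:5, 1:4] <- 1L
  img <- projected_image(array(1, c(1, 10, 10)), pixel_size = 0.91)
  m <- measure_regions(img, region_label_map(labels))
  expect_equal(glance(m)$core_area_um2, 20 * 0.91^2)
})

test_that("noiseless measurements on truth masks equal brute-force sums of the planted signal", {
  r <- render_scene(small_scene(seed = 50))
  img <- project(r$stack)
  m <- measure_regions(img, truth_labels(r$truth))
  tab <- tidy(m)
  for (ch in seq_along(img$channel_names)) {
    for (rg in c("core", "outgrowth")) {
      mask <- if (rg == "core") r$truth$core_mask else r$truth$outgrowth_mask
      oracle <- sum(r$truth$per_channel_truth[ch, , ][mask])
      got <- tab$integrated_density[tab$channel == img$channel_names[ch] &
                                      tab$region == rg]
      expect_equal(got, oracle)
    }
  }
})

test_that("regional percentages sum to 100 and empty channels report missing", {
  r <- render_scene(small_scene(seed = 51, noise_sigma = 10))
  img <- project(r$stack)
  lm <- derive_regions_from_cellmask(threshold_fallback(img))
  tab <- tidy(measure_regions(img, lm))
  sums <- tapply(
    tab$pct_total_integrated_density[tab$region != "background"],
    tab$channel[tab$region != "background"], sum
  )
  expect_true(all(abs(sums - 100) < 1e-6))

  # a channel with zero signal: percentages are missing, not 0/0
  px <- r$stack$pixels; px[1, 2, , ] <- 0
  img0 <- project(channel_stack(px, channel_names = img$channel_names))
  tab0 <- tidy(measure_regions(img0, lm))
  expect_true(all(is.na(tab0$pct_total_integrated_density[tab0$channel == "EC"])))
})

test_that("integrated density is conserved across the three regions", {
  r <- render_scene(small_scene(seed = 52, noise_sigma = 30))
  img <- project(r$stack)
  lm <- derive_regions_from_cellmask(threshold_fallback(img))
  tab <- tidy(measure_regions(img, lm))
  for (ch in seq_along(img$channel_names)) {
    total <- sum(img$pixels[ch, , ])
    by_region <- sum(tab$integrated_density[tab$channel == img$channel_names[ch]])
    expect_equal(by_region, total, tolerance = 1e-6)
  }
})

test_that("planted detached cells are counted exactly and matched to their centres", {
  r <- render_scene(small_scene(seed = 53, n_detached_cells = 10))
  img <- project(r$stack)
  det <- detect_cells_outside_core(img, truth_labels(r$truth))
  expect_identical(attr(det, "count"), 10L)
  expect_identical(attr(det, "channel"), "MACROPHAGE")
  expect_true(all(match_distances(det, r$truth$detached_cell_centers) <= 2))

  none <- render_scene(small_scene(seed = 54, n_detached_cells = 0))
  det0 <- detect_cells_outside_core(project(none$stack), truth_labels(none$truth))
  expect_identical(attr(det0, "count"), 0L)
})

test_that("two blobs closer than the minimum separation collapse to one detection", {
  m <- matrix(0, 48, 48)
  for (ctr in list(c(24, 24), c(24, 25))) {   # 1 px apart
    d <- sqrt((row(m) - ctr[1])^2 + (col(m) - ctr[2])^2)
    m <- pmax(m, round(160 * pmin(1, pmax(0, 3.5 - d))))
  }
  img <- projected_image(array(m, c(1, 48, 48)), channel_names = "MACROPHAGE")
  labels <- region_label_map(matrix(0L, 48, 48))
  det <- detect_cells_outside_core(img, labels)
  expect_identical(attr(det, "count"), 1L)
})

test_that("detections never fall inside the (dilated) core", {
  r <- render_scene(small_scene(seed = 55, noise_sigma = 30,
                                n_detached_cells = 12))
  img <- project(r$stack)
  lm <- truth_labels(r$truth)
  det <- detect_cells_outside_core(img, lm)
  for (i in seq_len(nrow(det))) {
    expect_false(lm$labels[round(det$row[i]), round(det$col[i])] == 1L)
  }
})

test_that("shape mismatches and unknown channels raise informative errors", {
  img <- projected_image(array(0, c(1, 10, 10)))
  labels <- region_label_map(matrix(0L, 12, 12))
  expect_error(measure_regions(img, labels), "shapes differ")
  labels2 <- region_label_map(matrix(0L, 10, 10))
  expect_error(detect_cells_outside_core(img, labels2, channel = "GFP"),
               "unknown channel")
})
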