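test_that("a sprout- and cell-free scene is exactly a rasterised core disk", {
  sc <- spheroid_scene(core_radius = 40, n_sprouts = 0, n_detached_cells = 0)
  r <- render_scene(sc)
  # brute-force disk: count pixel centres within the radius
  ctr <- sc$core_center
  n_disk <- 0L
  for (row in seq_len(sc$image_shape[1])) {
    for (col in seq_len(sc$image_shape[2])) {
      if ((row - ctr[1])^2 + (col - ctr[2])^2 <= sc$core_radius^2) {
        n_disk <- n_disk + 1L
      }
    }
  }
  expect_identical(r$truth$true_core_area, n_disk)
  expect_identical(r$truth$true_outgrowth_area, 0L)
  expect_equal(sum(r$truth$core_mask), n_disk)
})

test_that("rendering is bit-identical for a fixed seed", {
  sc <- small_scene(seed = 7, noise_sigma = 15, photon_scale = 0.5)
  a <- render_scene(sc)
  b <- render_scene(sc)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$truth$core_mask, b$truth$core_mask)
  expect_identical(a$truth$detached_cell_centers, b$truth$detached_cell_centers)
})

test_that("detached-only outgrowth area matches a brute-force rasterisation of the placed disks", {
  sc <- spheroid_scene(core_radius = 30, n_sprouts = 0, n_detached_cells = 25,
                       detached_cell_radius = 3, detached_ring = c(40, 110),
                       seed = 5)
  r <- render_scene(sc)
  centers <- r$truth$detached_cell_centers
  expect_identical(nrow(centers), 25L)
  # oracle: per-pixel max coverage over all placed centres, quantised the
  # way the renderer quantises, counted outside the core
  amp <- sc$channel_intensity[["MACROPHAGE"]]
  H <- sc$image_shape[1]; W <- sc$image_shape[2]
  mask <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(centers))) {
    for (row in floor(centers$row[k] - 5):ceiling(centers$row[k] + 5)) {
      for (col in floor(centers$col[k] - 5):ceiling(centers$col[k] + 5)) {
        d <- sqrt((row - centers$row[k])^2 + (col - centers$col[k])^2)
        cov <- min(1, max(0, sc$detached_cell_radius + 0.5 - d))
        if (round(amp * cov) > 0) mask[row, col] <- TRUE
      }
    }
  }
  d_core <- sqrt((row(mask) - sc$core_center[1])^2 +
                   (col(mask) - sc$core_center[2])^2)
  mask[d_core <= sc$core_radius] <- FALSE
  expect_identical(r$truth$true_outgrowth_area, sum(mask))
  # no overlaps by construction: pairwise centre distances >= 2 * radius
  dm <- as.matrix(stats::dist(cbind(centers$row, centers$col)))
  expect_true(all(dm[upper.tri(dm)] >= 2 * sc$detached_cell_radius))
})

test_that("truth masks partition the image over a randomised parameter sweep", {
  params <- withr::with_seed(42, tibble::tibble(
    n_sprouts = sample(0:10, 8, replace = TRUE),
    n_detached_cells = sample(0:12, 8, replace = TRUE),
    core_radius = runif(8, 15, 28),
    noise_sigma = runif(8, 0, 40),
    n_planes = sample(1:3, 8, replace = TRUE)
  ))
  for (i in 1:8) {
    sc <- small_scene(
      seed = 100 + i,
      n_sprouts = params$n_sprouts[i], n_detached_cells = params$n_detached_cells[i],
      core_radius = params$core_radius[i], noise_sigma = params$noise_sigma[i],
      n_planes = params$n_planes[i]
    )
    r <- render_scene(sc)
    tot <- r$truth$core_mask + r$truth$outgrowth_mask + r$truth$background_mask
    expect_true(all(tot == 1), label = paste("partition, sweep scene", i))
    expect_identical(r$truth$true_core_area, sum(r$truth$core_mask))
    expect_identical(r$truth$true_outgrowth_area, sum(r$truth$outgrowth_mask))
  }
})

test_that("noiseless rendering equals the per-channel truth exactly", {
  r <- render_scene(small_scene(seed = 9, noise_sigma = 0, photon_scale = 0))
  for (ch in 1:3) {
    expect_identical(r$stack$pixels[1, ch, , ], r$truth$per_channel_truth[ch, , ])
  }
})

test_that("expected outgrowth area grows with sprout number and length", {
  area_mean <- function(n, len) {
    mean(vapply(1:4, function(s) {
      r <- render_scene(small_scene(seed = 200 + s, n_sprouts = n,
                                    sprout_length_mean = len,
                                    n_detached_cells = 0))
      as.numeric(r$truth$true_outgrowth_area)
    }, numeric(1)))
  }
  by_n <- vapply(c(2, 5, 9), area_mean, numeric(1), len = 25)
  by_len <- vapply(c(15, 25, 35), function(l) area_mean(5, l), numeric(1))
  expect_true(all(diff(by_n) > 0))
  expect_true(all(diff(by_len) > 0))
})

test_that("impossible detached-cell packing raises a placement error", {
  sc <- small_scene(n_detached_cells = 80, detached_cell_radius = 4,
                    detached_ring = c(23, 34), seed = 1)
  expect_error(render_scene(sc), class = "outgrowthr_placement_error")
})

test_that("condition sets have the requested size, distinct seeds and faithful folds", {
  base <- small_scene(seed = 3)
  cs <- make_condition_set(base, fold_outgrowth = 1, n_replicates = 2, seed = 5)
  expect_identical(nrow(cs), 2L)
  expect_identical(length(unique(cs$seed)), 2L)
  expect_error(make_condition_set(base, fold_outgrowth = -1, 4, seed = 1))

  area_at_fold <- function(fold, seed) {
    cs <- make_condition_set(base, fold, n_replicates = 8, seed = seed)
    mean(vapply(cs$truth, function(t) as.numeric(t$true_outgrowth_area),
                numeric(1)))
  }
  a1 <- area_at_fold(1, 11)
  a1b <- area_at_fold(1, 33)   # independent Monte-Carlo estimate of the base
  a2 <- area_at_fold(2, 22)
  expect_lt(abs(a1 - a1b) / a1b, 0.10)
  expect_lt(abs(a2 / a1 - 2), 0.2)
})
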