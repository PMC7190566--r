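fake_pool <- function(n_small, n_large, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      object_id = seq_len(n_small + n_large),
      tile_id = "t",
      centroid_x_um = runif(n_small + n_large, 0, 1000),
      centroid_y_um = runif(n_small + n_large, 0, 1000),
      area_um2 = c(runif(n_small, 25, 999), runif(n_large, 1000, 5000)),
      pixel_count = 1L, stratum = NA_character_, group = NA_integer_)
  })
}

test_that("stratify_sample draws the exact stratum counts", {
  pool <- fake_pool(2500, 400)
  s <- stratify_sample(pool, 1900, 300, seed = 7)
  expect_identical(sum(s$stratum == "small"), 1900L)
  expect_identical(sum(s$stratum == "large"), 300L)
  expect_true(all(s$area_um2[s$stratum == "small"] < 1000))
  expect_true(all(s$area_um2[s$stratum == "large"] >= 1000))
  expect_false(anyDuplicated(s$object_id) > 0)
  expect_true(all(s$object_id %in% pool$object_id))
  # reproducible per seed
  expect_identical(s, stratify_sample(pool, 1900, 300, seed = 7))
  expect_false(identical(s$object_id,
                         stratify_sample(pool, 1900, 300, seed = 8)$object_id))
})

test_that("stratify_sample edge cases and errors name the deficient stratum", {
  pool <- fake_pool(10, 5)
  expect_identical(nrow(stratify_sample(pool, 0, 0, seed = 1)), 0L)
  expect_error(stratify_sample(pool, 11, 2, seed = 1), "small stratum")
  expect_error(stratify_sample(pool, 2, 6, seed = 1), "large stratum")
})

test_that("an area exactly at the boundary falls in the large stratum", {
  pool <- data.frame(object_id = 1:2, tile_id = "t",
                     centroid_x_um = 0, centroid_y_um = 0,
                     area_um2 = c(999.9, 1000), pixel_count = 1L,
                     stratum = NA_character_, group = NA_integer_)
  s <- stratify_sample(pool, 1, 1, seed = 1)
  expect_identical(s$stratum[s$area_um2 == 1000], "large")
})

test_that("split_groups partitions exactly, disjointly, reproducibly", {
  pool <- fake_pool(2500, 400)
  s <- stratify_sample(pool, 1900, 300, seed = 7)
  g <- split_groups(s, c(1100, 1100), seed = 11)
  expect_identical(as.integer(table(g$group)), c(1100L, 1100L))
  expect_setequal(g$object_id, s$object_id)
  expect_identical(g, split_groups(s, c(1100, 1100), seed = 11))
  expect_error(split_groups(s, c(2000, 500), seed = 1), "sum to")
})

test_that("sampling frequencies are uniform across seeds", {
  pool <- fake_pool(10, 0)
  hits <- integer(10)
  for (s in 1:400) {
    pick <- stratify_sample(pool, 1, 0, seed = s)$object_id
    hits[pick] <- hits[pick] + 1L
  }
  expect_true(all(hits > 0)) # every candidate reachable
  expect_gt(stats::chisq.test(hits)$p.value, 1e-3)
})

test_that("patch geometry: side, centering, padding, marker", {
  tile <- array(200, dim = c(512, 512, 3))
  obj <- list(object_id = 1L, centroid_x_um = 256 * 0.24 / 2,
              centroid_y_um = 256 * 0.24 / 2)
  p <- extract_patch(tile, obj, pixel_size_um = 0.24, side_um = 256)
  expect_identical(dim(p$image), c(1067L, 1067L, 3L)) # round(256/0.24)
  expect_equal(p$marker_side_um, sqrt(0.03) * 1000) # ~173.2 um
  # CoM at patch center within half a pixel
  com_px <- obj$centroid_x_um / 0.24
  x_start <- p$offset_um[["x"]] / 0.24
  expect_lte(abs((com_px - x_start) - 1067 / 2), 0.5)
})

test_that("corner objects are padded with background, CoM still centered", {
  tile <- array(100, dim = c(128, 128, 3))
  obj <- list(object_id = 1L, centroid_x_um = 0.5, centroid_y_um = 0.5)
  p <- extract_patch(tile, obj, pixel_size_um = 0.24, side_um = 24,
                     marker_area_mm2 = 0, background_intensity = c(255, 255, 255))
  side <- dim(p$image)[1]
  expect_identical(side, 100L)
  com_rel <- obj$centroid_x_um / 0.24 - p$offset_um[["x"]] / 0.24
  expect_lte(abs(com_rel - side / 2), 0.5)
  expect_true(any(p$image == 255)) # padding present
  expect_true(any(p$image == 100)) # tile content present
})

test_that("patches only alter marker outline pixels inside the tile", {
  withr::with_seed(4, {
    tile <- array(runif(64 * 64 * 3, 0, 255), dim = c(64, 64, 3))
  })
  obj <- list(object_id = 1L, centroid_x_um = 32 * 0.24,
              centroid_y_um = 32 * 0.24)
  marker_area <- (20 * 0.24 / 1000)^2 # 20-px marker
  p <- extract_patch(tile, obj, pixel_size_um = 0.24, side_um = 64 * 0.24,
                     marker_area_mm2 = marker_area,
                     marker_intensity = c(-1, -1, -1))
  changed <- which(p$image != tile)
  expect_gt(length(changed), 0)
  expect_true(all(p$image[changed] == -1))
  # marker is an outline: interior pixel untouched
  expect_identical(p$image[32, 32, ], tile[32, 32, ])
})

test_that("coordinate transfer applies and inverts affine maps exactly", {
  obj <- data.frame(object_id = 1:2, centroid_x_um = c(10, 250),
                    centroid_y_um = c(20, 40), area_um2 = c(100, 200))
  ident <- cbind(diag(2), c(0, 0))
  expect_identical(transfer_coordinates(obj, ident), obj)
  shift <- cbind(diag(2), c(5, -3))
  moved <- transfer_coordinates(obj, shift)
  expect_equal(moved$centroid_x_um, obj$centroid_x_um + 5)
  expect_equal(moved$centroid_y_um, obj$centroid_y_um - 3)
  expect_identical(moved$area_um2, obj$area_um2)
  # forward then inverse round trip
  theta <- 0.3
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2) * 1.1
  fwd <- cbind(A, c(12, -7))
  inv <- cbind(solve(A), -solve(A) %*% c(12, -7))
  back <- transfer_coordinates(transfer_coordinates(obj, fwd), inv)
  expect_lt(max(abs(back$centroid_x_um - obj$centroid_x_um)), 1e-9)
  expect_lt(max(abs(back$centroid_y_um - obj$centroid_y_um)), 1e-9)
  expect_error(transfer_coordinates(obj, cbind(matrix(1, 2, 2), c(0, 0))),
               "singular")
})
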