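test_that("rgb_to_od maps background to zero and decades to unit OD", {
  mk <- function(val) array(val, dim = c(2, 2, 3))
  od_bg <- rgb_to_od(mk(255), c(255, 255, 255), epsilon = 1)
  expect_true(all(od_bg == 0)) # slight negative from epsilon clips to 0
  od_dec <- rgb_to_od(mk(25.5), c(255, 255, 255), epsilon = 1)
  expect_equal(as.vector(od_dec), rep(-log10(26.5 / 255), 12))
  expect_lt(max(abs(od_dec - 1)), 0.02) # within epsilon tolerance of 1
  # exact decade with epsilon = 0
  expect_equal(as.vector(rgb_to_od(mk(25.5), epsilon = 0)), rep(1, 12))
  expect_error(rgb_to_od(matrix(1, 3, 3)), "RGB")
})

test_that("OD of a synthetic pixel equals the stain mixture M c", {
  sm <- stain_model()
  M <- cbind(sm$od_hematoxylin, sm$od_dab)
  conc <- c(0.3, 0.8)
  intensity <- 255 * 10^(-(M %*% conc))
  tile <- array(rep(intensity, each = 1), dim = c(1, 1, 3))
  od <- rgb_to_od(tile, epsilon = 0)
  expect_lt(max(abs(as.vector(od) - M %*% conc)), 1e-6)
})

test_that("deconvolution solves the two-stain projection", {
  sm <- stain_model()
  # OD exactly along the DAB vector with magnitude m
  m <- 0.73
  od <- array(rep(m * sm$od_dab, each = 4), dim = c(2, 2, 3))
  maps <- deconvolve(od, sm)
  expect_equal(as.vector(maps$c_dab), rep(m, 4), tolerance = 1e-12)
  expect_equal(as.vector(maps$c_hematoxylin), rep(0, 4), tolerance = 1e-12)
  # null input
  maps0 <- deconvolve(array(0, dim = c(2, 2, 3)), sm)
  expect_true(all(maps0$c_dab == 0) && all(maps0$c_hematoxylin == 0))
  # collinear stains rejected at model construction
  expect_error(stain_model(od_dab = c(0.650, 0.704, 0.286)), "collinear")
})

test_that("segment_dab thresholds and optionally closes gaps", {
  img <- matrix(0.05, 32, 32)
  expect_true(all(!segment_dab(img, threshold = 0.15)))
  img[10:20, 10:20] <- 0.9
  mask <- segment_dab(img, threshold = 0.15)
  expect_identical(unname(which(mask)), unname(which(img >= 0.15)))
  # two blocks separated by a 1-px gap merge downstream once closed
  img2 <- matrix(0, 32, 32)
  img2[10:15, 5:14] <- 0.9
  img2[10:15, 16:25] <- 0.9
  open_objs <- extract_objects(segment_dab(img2, 0.15), 0.24)
  closed_objs <- extract_objects(
    segment_dab(img2, 0.15, closing_radius_um = 0.3, pixel_size_um = 0.24),
    0.24)
  expect_identical(nrow(open_objs), 2L)
  expect_identical(nrow(closed_objs), 1L)
})

test_that("extract_objects measures components under 8-connectivity", {
  expect_identical(nrow(extract_objects(matrix(FALSE, 8, 8), 0.24)), 0L)
  # one 10x10 square at 0.24 um/px -> 5.76 um^2
  m <- matrix(FALSE, 32, 32)
  m[5:14, 7:16] <- TRUE
  obj <- extract_objects(m, 0.24)
  expect_identical(obj$pixel_count, 100L)
  expect_equal(obj$area_um2, 5.76)
  # centroid: columns 7..16 -> 0-based centers 6.5..15.5, mean 11 -> 2.64 um
  expect_equal(obj$centroid_x_um, 11 * 0.24)
  expect_equal(obj$centroid_y_um, 9 * 0.24)
  expect_identical(c(obj$bbox_x0, obj$bbox_y0, obj$bbox_x1, obj$bbox_y1),
                   c(6L, 4L, 15L, 13L))
  # diagonally touching pixels form one object
  d <- matrix(FALSE, 5, 5)
  d[2, 2] <- d[3, 3] <- TRUE
  expect_identical(nrow(extract_objects(d, 1)), 1L)
})

test_that("object ids follow raster-scan order of first pixels", {
  m <- matrix(FALSE, 20, 20)
  m[15:16, 2:3] <- TRUE   # lower-left, planted first
  m[2:3, 10:11] <- TRUE   # top, should get id 1
  m[8:9, 5:6] <- TRUE     # middle
  obj <- extract_objects(m, 1)
  expect_identical(obj$object_id, 1:3)
  expect_identical(obj$centroid_y_um, c(2, 8, 15))
})

test_that("filter_by_area keeps the closed interval [25, 5000]", {
  objs <- data.frame(object_id = 1:5, area_um2 = c(24.9, 25, 999, 5000, 5000.1))
  kept <- filter_by_area(objs)
  expect_identical(kept$area_um2, c(25, 999, 5000))
  expect_identical(filter_by_area(kept), kept) # idempotent
  expect_identical(nrow(filter_by_area(objs[0, ])), 0L)
  expect_error(filter_by_area(objs, 10, 5), "min")
})

test_that("detection + area filter recovers exactly the in-range planted objects", {
  sm <- stain_model()
  for (seed in c(31, 32, 33)) {
    g <- generate_tile(small_scene(seed), sm)
    gt <- g$ground_truth$objects
    truth <- gt[gt$area_um2 >= 25 & gt$area_um2 <= 5000, ]
    cand <- detect_candidates(g$tile, sm, epsilon = 0)
    expect_identical(nrow(cand), nrow(truth))
    # match by centroid (detection order is raster-scan, truth is size order)
    for (i in seq_len(nrow(truth))) {
      d <- sqrt((cand$centroid_x_um - truth$centroid_x_um[i])^2 +
                  (cand$centroid_y_um - truth$centroid_y_um[i])^2)
      j <- which.min(d)
      expect_lt(d[j], 0.24)
      expect_lte(abs(cand$area_um2[j] - truth$area_um2[i]), 0.24^2)
    }
  }
})

test_that("ROI restriction reports coordinates in the full-tile frame", {
  sm <- stain_model()
  g <- generate_tile(small_scene(31), sm)
  full <- detect_candidates(g$tile, sm, epsilon = 0)
  roi <- c(0, 0, 512 * 0.24, 512 * 0.24)
  within <- detect_candidates(g$tile, sm, epsilon = 0, roi = roi)
  expect_equal(within, full)
  # a quarter-tile ROI keeps only candidates whose pixels lie inside it
  quarter <- detect_candidates(g$tile, sm, epsilon = 0,
                               roi = c(0, 0, 256 * 0.24, 256 * 0.24))
  expect_lte(nrow(quarter), nrow(full))
  if (nrow(quarter) > 0) {
    expect_true(all(quarter$centroid_x_um <= 256 * 0.24 + 0.24))
  }
})
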