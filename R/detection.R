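#' Convert transmitted RGB intensities to optical density
#'
#' Per channel, `OD_c = -log10((I_c + epsilon) / I0_c)`, clipped at 0 from
#' below. The default `epsilon = 1` guards the logarithm for 8-bit integer
#' counts (so a pixel equal to background maps to OD 0 after clipping); for
#' unquantized synthetic tiles pass `epsilon = 0` to make the transform an
#' exact inverse of the Beer-Lambert forward model.
#'
#' @param tile Numeric `h x w x 3` RGB array of transmitted intensities.
#' @param background_intensity Positive per-channel blank-field intensity
#'   `I0`.
#' @param epsilon Additive intensity offset before the log.
#'
#' @return Numeric `h x w x 3` array of optical densities (>= 0).
#' @export
rgb_to_od <- function(tile, background_intensity = c(255, 255, 255),
                      epsilon = 1) {
  if (length(dim(tile)) != 3L || dim(tile)[3] != 3L) {
    stop("tile must be an h x w x 3 RGB array")
  }
  stopifnot(length(background_intensity) == 3L, all(background_intensity > 0),
            epsilon >= 0)
  od <- array(0, dim = dim(tile))
  for (ch in 1:3) {
    od[, , ch] <- -log10((tile[, , ch] + epsilon) / background_intensity[ch])
  }
  pmax(od, 0)
}

#' Unmix an optical-density image into stain concentration maps
#'
#' Solves, per pixel, the least-squares projection of the OD 3-vector onto
#' the two stain vectors (the residual direction orthogonal to both is
#' discarded); negative concentrations are clipped to 0.
#'
#' @param od Numeric `h x w x 3` optical-density array from [rgb_to_od()].
#' @param stain A [stain_model()]; its two OD vectors must be linearly
#'   independent.
#' @param pixel_size_um Physical pixel size carried into the result.
#'
#' @return Object of class `concentration_maps`: list with matrices
#'   `c_hematoxylin` and `c_dab` (non-negative, same shape as the tile) and
#'   `pixel_size_um`.
#' @export
deconvolve <- function(od, stain, pixel_size_um = 0.24) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L) {
    stop("od must be an h x w x 3 array")
  }
  stopifnot(inherits(stain, "stain_model"), pixel_size_um > 0)
  M <- stain_matrix(stain)
  sv <- svd(M)$d
  if (sv[2] / sv[1] < 1e-6) {
    stop("stain vectors are (near-)collinear; system is ill-conditioned")
  }
  pinv <- solve(crossprod(M), t(M)) # 2 x 3 Moore-Penrose pseudoinverse
  h <- dim(od)[1]; w <- dim(od)[2]
  od_flat <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
                   as.vector(od[, , 3]))
  conc <- od_flat %*% t(pinv)
  conc[conc < 0] <- 0
  structure(list(c_hematoxylin = matrix(conc[, 1], h, w),
                 c_dab = matrix(conc[, 2], h, w),
                 pixel_size_um = pixel_size_um),
            class = "concentration_maps")
}

#' Segment DAB-positive pixels
#'
#' Thresholds the DAB concentration map at a fixed concentration (default
#' convention of the pipeline: 0.15 OD units) or, with
#' `threshold = "otsu"`, at an Otsu threshold computed from the map.
#' Optional morphological closing with a disc of the given physical radius
#' bridges small gaps; radius 0 disables it.
#'
#' @param c_dab Numeric matrix of DAB concentrations, or a
#'   `concentration_maps` object.
#' @param threshold Non-negative concentration threshold, or `"otsu"`.
#' @param closing_radius_um Disc radius for morphological closing, in
#'   micrometres (0 = off).
#' @param pixel_size_um Pixel size; taken from `c_dab` when it is a
#'   `concentration_maps` object.
#'
#' @return Logical matrix: `TRUE` where DAB-positive.
#' @export
segment_dab <- function(c_dab, threshold = 0.15, closing_radius_um = 0,
                        pixel_size_um = 0.24) {
  if (inherits(c_dab, "concentration_maps")) {
    pixel_size_um <- c_dab$pixel_size_um
    c_dab <- c_dab$c_dab
  }
  stopifnot(is.matrix(c_dab), closing_radius_um >= 0, pixel_size_um > 0)
  if (identical(threshold, "otsu")) {
    rng <- range(c_dab)
    threshold <- if (diff(rng) == 0) rng[1] + 1 else {
      EBImage::otsu(EBImage::Image((c_dab - rng[1]) / diff(rng))) *
        diff(rng) + rng[1]
    }
  }
  stopifnot(is.numeric(threshold), threshold >= 0)
  mask <- c_dab >= threshold
  if (closing_radius_um > 0) {
    r_px <- max(1L, as.integer(round(closing_radius_um / pixel_size_um)))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  mask
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged afterwards with a union-find over the label set.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n == 0L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])), # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))  # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Extract candidate objects from a binary mask
#'
#' Groups `TRUE` pixels into 8-connected components and measures each one.
#' Object ids are assigned in raster-scan order of each component's first
#' pixel (top-most, then left-most). Centroids are unweighted pixel-center
#' means ("center of mass" of the binary mask) in micrometres, in an image
#' frame with origin at the tile's top-left pixel corner, x along columns.
#'
#' @param mask Logical matrix from [segment_dab()].
#' @param pixel_size_um Positive pixel edge length.
#' @param tile_id Identifier recorded with every object.
#' @param keep_masks Attach each object's binary mask crop (list column
#'   `mask`, aligned with the bounding box).
#'
#' @return A `data.frame` (one row per object) with columns `object_id`,
#'   `tile_id`, `pixel_count`, `area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   bounding box `bbox_x0`, `bbox_y0`, `bbox_x1`, `bbox_y1` (0-based pixel
#'   indices, inclusive), `stratum` and `group` (both `NA` until assigned),
#'   and optionally a `mask` list column.
#' @export
extract_objects <- function(mask, pixel_size_um, tile_id = "tile",
                            keep_masks = FALSE) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  lab <- label_components_8(mask)
  n <- max(lab)
  empty <- data.frame(object_id = integer(), tile_id = character(),
                      pixel_count = integer(), area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      bbox_x0 = integer(), bbox_y0 = integer(),
                      bbox_x1 = integer(), bbox_y1 = integer(),
                      stratum = character(), group = integer())
  if (n == 0L) {
    if (keep_masks) empty$mask <- list()
    return(empty)
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  fids <- factor(ids, levels = seq_len(n)) # keep numeric label order
  # raster-scan key: row-major (top-most first, ties left-most)
  key <- (rows - 1) * ncol(lab) + (cols - 1)
  first_key <- tapply(key, fids, min)

  count <- tabulate(ids, n)
  cx <- tapply(cols - 0.5, fids, mean) * pixel_size_um
  cy <- tapply(rows - 0.5, fids, mean) * pixel_size_um
  x0 <- tapply(cols, fids, min) - 1L; x1 <- tapply(cols, fids, max) - 1L
  y0 <- tapply(rows, fids, min) - 1L; y1 <- tapply(rows, fids, max) - 1L

  ord <- order(first_key)
  out <- data.frame(
    object_id = seq_len(n),
    tile_id = tile_id,
    pixel_count = count[ord],
    area_um2 = count[ord] * pixel_size_um^2,
    centroid_x_um = as.numeric(cx[ord]), centroid_y_um = as.numeric(cy[ord]),
    bbox_x0 = as.integer(x0[ord]), bbox_y0 = as.integer(y0[ord]),
    bbox_x1 = as.integer(x1[ord]), bbox_y1 = as.integer(y1[ord]),
    stratum = NA_character_, group = NA_integer_)
  if (keep_masks) {
    out$mask <- lapply(seq_len(n), function(i) {
      k <- ord[i]
      lab[(out$bbox_y0[i] + 1L):(out$bbox_y1[i] + 1L),
          (out$bbox_x0[i] + 1L):(out$bbox_x1[i] + 1L), drop = FALSE] == k
    })
  }
  out
}

#' Filter candidate objects by physical area
#'
#' Retains objects whose surface area lies in `[min_um2, max_um2]`
#' (inclusive on both ends), removing small artifacts and large tumor-cell
#' clusters. Order is preserved; the result is a subset of the input, and
#' the operation is idempotent.
#'
#' @param objects Candidate data.frame from [extract_objects()].
#' @param min_um2,max_um2 Area bounds in square micrometres
#'   (default 25-5000).
#'
#' @return The retained rows of `objects`.
#' @export
filter_by_area <- function(objects, min_um2 = 25, max_um2 = 5000) {
  stopifnot(is.data.frame(objects), min_um2 < max_um2)
  objects[objects$area_um2 >= min_um2 & objects$area_um2 <= max_um2, ,
          drop = FALSE]
}

#' Run the full candidate-selection algorithm on one tile
#'
#' Convenience composition: OD transform, color deconvolution, DAB
#' thresholding (with optional closing), 8-connected grouping and the area
#' filter — the automated candidate-selection chain applied to each
#' pan-cytokeratin tile.
#'
#' @param tile RGB intensity array.
#' @param stain A [stain_model()].
#' @param pixel_size_um Pixel size in micrometres.
#' @param dab_threshold DAB concentration threshold (or `"otsu"`).
#' @param closing_radius_um Closing disc radius (0 = off).
#' @param min_um2,max_um2 Area-filter bounds.
#' @param epsilon OD offset, see [rgb_to_od()].
#' @param tile_id Tile identifier for the output table.
#' @param roi Optional region of interest `c(x_um, y_um, width_um,
#'   height_um)`; detection is restricted to it (e.g. a 0.785 mm^2
#'   hotspot).
#' @param keep_masks Attach per-object mask crops.
#'
#' @return Candidate data.frame as from [extract_objects()], area-filtered.
#'   Centroids and bounding boxes are in the frame of the full tile even
#'   when an ROI is given.
#' @export
detect_candidates <- function(tile, stain = stain_model(),
                              pixel_size_um = 0.24, dab_threshold = 0.15,
                              closing_radius_um = 0, min_um2 = 25,
                              max_um2 = 5000, epsilon = 1,
                              tile_id = "tile", roi = NULL,
                              keep_masks = FALSE) {
  od <- rgb_to_od(tile, stain$background_intensity, epsilon = epsilon)
  maps <- deconvolve(od, stain, pixel_size_um = pixel_size_um)
  mask <- segment_dab(maps, threshold = dab_threshold,
                      closing_radius_um = closing_radius_um)
  off_px <- c(0L, 0L) # (x, y) offset of the analyzed region, 0-based
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4L, all(roi[3:4] > 0))
    x0 <- max(0L, as.integer(floor(roi[1] / pixel_size_um)))
    y0 <- max(0L, as.integer(floor(roi[2] / pixel_size_um)))
    x1 <- min(ncol(mask) - 1L,
              as.integer(ceiling((roi[1] + roi[3]) / pixel_size_um)) - 1L)
    y1 <- min(nrow(mask) - 1L,
              as.integer(ceiling((roi[2] + roi[4]) / pixel_size_um)) - 1L)
    if (x1 < x0 || y1 < y0) stop("ROI does not intersect the tile")
    mask <- mask[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
    off_px <- c(x0, y0)
  }
  objs <- extract_objects(mask, pixel_size_um, tile_id = tile_id,
                          keep_masks = keep_masks)
  if (nrow(objs) > 0L && any(off_px != 0L)) {
    objs$centroid_x_um <- objs$centroid_x_um + off_px[1] * pixel_size_um
    objs$centroid_y_um <- objs$centroid_y_um + off_px[2] * pixel_size_um
    objs$bbox_x0 <- objs$bbox_x0 + off_px[1]
    objs$bbox_x1 <- objs$bbox_x1 + off_px[1]
    objs$bbox_y0 <- objs$bbox_y0 + off_px[2]
    objs$bbox_y1 <- objs$bbox_y1 + off_px[2]
  }
  filter_by_area(objs, min_um2, max_um2)
}
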