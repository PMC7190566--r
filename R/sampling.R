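#' Stratified sampling of candidates by area
#'
#' Splits the candidate pool at `boundary_um2` into a small stratum
#' (area < boundary, mostly tumor buds) and a large stratum
#' (area >= boundary, mostly PDCs), then samples uniformly without
#' replacement within each stratum. The study design draws 1900 small and
#' 300 large candidates, the small stratum oversampled to ensure sufficient
#' presence of buds.
#'
#' @param objects Candidate data.frame (needs `area_um2`).
#' @param n_small,n_large Stratum sample sizes.
#' @param boundary_um2 Stratum boundary; an area exactly equal to it falls
#'   in the large stratum.
#' @param seed Integer seed.
#'
#' @return The sampled rows with `stratum` set to `"small"`/`"large"`,
#'   small stratum first; sampling order within stratum. Attributes `seed`
#'   and `boundary_um2` record provenance.
#' @export
stratify_sample <- function(objects, n_small = 1900, n_large = 300,
                            boundary_um2 = 1000, seed = 1L) {
  stopifnot(is.data.frame(objects), n_small >= 0, n_large >= 0,
            boundary_um2 > 0)
  small_idx <- which(objects$area_um2 < boundary_um2)
  large_idx <- which(objects$area_um2 >= boundary_um2)
  if (length(small_idx) < n_small) {
    stop("small stratum has only ", length(small_idx),
         " candidates; ", n_small, " requested")
  }
  if (length(large_idx) < n_large) {
    stop("large stratum has only ", length(large_idx),
         " candidates; ", n_large, " requested")
  }
  with_seed(seed, {
    take_small <- if (n_small > 0) sample(small_idx, n_small) else integer()
    take_large <- if (n_large > 0) sample(large_idx, n_large) else integer()
    out <- objects[c(take_small, take_large), , drop = FALSE]
    out$stratum <- rep(c("small", "large"), c(n_small, n_large))
    rownames(out) <- NULL
    attr(out, "seed") <- as.integer(seed)
    attr(out, "boundary_um2") <- boundary_um2
    out
  })
}

#' Randomly split a candidate set into review groups
#'
#' Uniform random partition into groups of exactly the requested sizes
#' (study design: two groups of 1500), disjoint and exhaustive.
#'
#' @param candidates Candidate data.frame.
#' @param sizes Integer vector of group sizes; must sum to
#'   `nrow(candidates)`.
#' @param seed Integer seed.
#'
#' @return `candidates` with the `group` column set to `1, 2, ...`
#'   (row order preserved).
#' @export
split_groups <- function(candidates, sizes = c(1500, 1500), seed = 1L) {
  stopifnot(is.data.frame(candidates), all(sizes >= 0))
  if (sum(sizes) != nrow(candidates)) {
    stop("group sizes (", sum(sizes), ") must sum to the candidate count (",
         nrow(candidates), ")")
  }
  with_seed(seed, {
    perm <- sample.int(nrow(candidates))
    grp <- integer(nrow(candidates))
    grp[perm] <- rep(seq_along(sizes), sizes)
    candidates$group <- grp
    candidates
  })
}

#' Extract a review patch centered on a candidate's center of mass
#'
#' Crops a square patch of physical side `side_um` (default 256 um, i.e.
#' 0.25 x 0.25 mm as shown to the observers) centered on the candidate's
#' center of mass; regions falling outside the tile are padded with the
#' background intensity. A square outline marker of fixed physical area
#' `marker_area_mm2` (default 0.03 mm^2), 2 pixels thick, is drawn centered
#' on the same point so the object of interest is unambiguous. No pixel
#' inside the tile bounds other than the marker outline is altered.
#'
#' @param tile RGB intensity array the candidate was detected in.
#' @param object One-row candidate data.frame (or list) with
#'   `centroid_x_um`, `centroid_y_um` and `object_id`.
#' @param pixel_size_um Pixel size of the tile.
#' @param side_um Patch side length in micrometres.
#' @param marker_area_mm2 Area of the square marker, in square millimetres
#'   (side = sqrt(area)).
#' @param background_intensity Padding intensity per channel.
#' @param marker_intensity Marker color per channel (default black).
#'
#' @return Object of class `review_patch`: list with `image` (side x side
#'   x 3 array), `object_id`, `side_um`, `marker_side_um`, `offset_um`
#'   (µm position of the patch's top-left corner in the tile frame) and
#'   `pixel_size_um`.
#' @export
extract_patch <- function(tile, object, pixel_size_um = 0.24, side_um = 256,
                          marker_area_mm2 = 0.03,
                          background_intensity = c(255, 255, 255),
                          marker_intensity = c(0, 0, 0)) {
  stopifnot(side_um > 0, marker_area_mm2 >= 0, pixel_size_um > 0)
  side_px <- max(1L, as.integer(round(side_um / pixel_size_um)))
  h <- dim(tile)[1]; w <- dim(tile)[2]
  com_px_x <- object$centroid_x_um / pixel_size_um
  com_px_y <- object$centroid_y_um / pixel_size_um
  # 0-based index of the patch's first pixel: centers the CoM within half a
  # pixel of the patch midpoint for either side parity
  x_start <- as.integer(round(com_px_x - side_px / 2))
  y_start <- as.integer(round(com_px_y - side_px / 2))

  patch <- array(rep(background_intensity, each = side_px * side_px),
                 dim = c(side_px, side_px, 3L))
  src_x <- (max(0L, x_start)):(min(w - 1L, x_start + side_px - 1L))
  src_y <- (max(0L, y_start)):(min(h - 1L, y_start + side_px - 1L))
  if (length(src_x) > 0L && length(src_y) > 0L &&
      src_x[1] <= src_x[length(src_x)] && src_y[1] <= src_y[length(src_y)]) {
    patch[src_y - y_start + 1L, src_x - x_start + 1L, ] <-
      tile[src_y + 1L, src_x + 1L, , drop = FALSE]
  }

  marker_side_um <- sqrt(marker_area_mm2) * 1000
  if (marker_area_mm2 > 0) {
    m_px <- max(3L, as.integer(round(marker_side_um / pixel_size_um)))
    mx0 <- as.integer(round(com_px_x - m_px / 2)) - x_start
    my0 <- as.integer(round(com_px_y - m_px / 2)) - y_start
    mx1 <- mx0 + m_px - 1L; my1 <- my0 + m_px - 1L
    in_x <- function(v) v[v >= 0L & v <= side_px - 1L]
    in_y <- in_x
    band_x <- in_x(c(mx0, mx0 + 1L, mx1 - 1L, mx1))
    band_y <- in_y(c(my0, my0 + 1L, my1 - 1L, my1))
    span_x <- in_x(mx0:mx1); span_y <- in_y(my0:my1)
    for (ch in 1:3) {
      if (length(band_y) && length(span_x)) {
        patch[band_y + 1L, span_x + 1L, ch] <- marker_intensity[ch]
      }
      if (length(band_x) && length(span_y)) {
        patch[span_y + 1L, band_x + 1L, ch] <- marker_intensity[ch]
      }
    }
  }

  structure(list(image = patch,
                 object_id = object$object_id,
                 side_um = side_px * pixel_size_um,
                 marker_side_um = marker_side_um,
                 offset_um = c(x = x_start, y = y_start) * pixel_size_um,
                 pixel_size_um = pixel_size_um),
            class = "review_patch")
}

#' Map a candidate into a co-registered image frame
#'
#' Applies a 2x3 affine transform (micrometre to micrometre) to the
#' candidate's center of mass, e.g. to trace IHC-detected candidates into
#' the equivalent restained H&E image. Area and pixel data are carried
#' unchanged: registration fidelity is the caller's responsibility.
#'
#' @param object Candidate data.frame (any number of rows).
#' @param affine Numeric 2x3 matrix `[A | t]`: new = A %*% (x, y) + t.
#'   `A` must be invertible.
#'
#' @return `object` with transformed `centroid_x_um` / `centroid_y_um`.
#' @export
transfer_coordinates <- function(object, affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(2L, 3L)))
  A <- affine[, 1:2]
  if (abs(det(A)) < 1e-12) stop("affine transform is singular")
  xy <- rbind(object$centroid_x_um, object$centroid_y_um)
  new_xy <- A %*% xy + affine[, 3]
  object$centroid_x_um <- new_xy[1, ]
  object$centroid_y_um <- new_xy[2, ]
  object
}
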