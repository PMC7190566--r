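#' Describe one class of planted objects in a synthetic scene
#'
#' @param name Class name (e.g. `"bud"`, `"pdc"`, `"artifact"`, `"cluster"`).
#' @param count Number of objects of this class to plant (>= 0).
#' @param area_range_um2 Length-1 or length-2 numeric: fixed area, or the
#'   bounds of a uniform area distribution, in square micrometres.
#' @param dab_range Length-2 numeric, uniform range of the per-object DAB
#'   concentration (OD units along the DAB stain vector).
#'
#' @return A list of class `object_class`.
#' @export
object_class <- function(name, count, area_range_um2, dab_range = c(0.6, 1.2)) {
  stopifnot(is.character(name), length(name) == 1L,
            count >= 0, count == round(count),
            length(area_range_um2) %in% c(1L, 2L), all(area_range_um2 > 0),
            length(dab_range) == 2L, all(dab_range >= 0))
  if (length(area_range_um2) == 1L) area_range_um2 <- rep(area_range_um2, 2L)
  stopifnot(area_range_um2[1] <= area_range_um2[2],
            dab_range[1] <= dab_range[2])
  structure(list(name = name, count = as.integer(count),
                 area_range_um2 = as.numeric(area_range_um2),
                 dab_range = as.numeric(dab_range)),
            class = "object_class")
}

#' Default object classes spanning the bud size spectrum
#'
#' Four keratin-positive object classes covering the size strata that the
#' 25-5000 um^2 area filter separates: sub-threshold artifacts (< 25 um^2),
#' tumor-bud-scale objects (25-1000 um^2), PDC-scale objects
#' (1000-5000 um^2) and oversize tumor-cell clusters (> 5000 um^2). Area
#' ranges are kept at least one pixel-area away from the filter bounds so
#' that planted class membership is unambiguous after rasterization.
#'
#' @param n_artifact,n_bud,n_pdc,n_cluster Object counts per class.
#' @return List of [object_class()] specifications.
#' @export
default_object_classes <- function(n_artifact = 3, n_bud = 6, n_pdc = 2,
                                   n_cluster = 1) {
  list(
    object_class("artifact", n_artifact, c(5, 20),     c(0.4, 0.9)),
    object_class("bud",      n_bud,      c(30, 600),   c(0.6, 1.2)),
    object_class("pdc",      n_pdc,      c(1100, 3000), c(0.6, 1.2)),
    object_class("cluster",  n_cluster,  c(5500, 6500), c(0.6, 1.2))
  )
}

#' Specify a synthetic IHC scene
#'
#' A scene is a single rectangular brightfield tile with keratin-positive
#' (DAB-stained) objects planted on a uniformly hematoxylin-counterstained
#' background. Physical scale follows the study default of 0.24 um/pixel
#' (40x objective).
#'
#' @param tile_size_px Integer pair `(height, width)` in pixels.
#' @param pixel_size_um Positive pixel edge length in micrometres.
#' @param object_classes List of [object_class()] specs.
#' @param background_hematoxylin Non-negative hematoxylin concentration of
#'   the background (OD units along the hematoxylin vector).
#' @param noise_sd Non-negative sd of additive Gaussian noise on transmitted
#'   intensity (8-bit scale), applied after the Beer-Lambert forward model.
#' @param seed Integer seed; all randomness of [generate_tile()] flows from
#'   it.
#'
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(tile_size_px = c(1024L, 1024L),
                       pixel_size_um = 0.24,
                       object_classes = default_object_classes(),
                       background_hematoxylin = 0.3,
                       noise_sd = 0,
                       seed = 1L) {
  stopifnot(length(tile_size_px) == 2L, all(tile_size_px >= 1),
            pixel_size_um > 0, background_hematoxylin >= 0, noise_sd >= 0,
            is.list(object_classes),
            all(vapply(object_classes, inherits, logical(1), "object_class")))
  structure(list(tile_size_px = as.integer(tile_size_px),
                 pixel_size_um = as.numeric(pixel_size_um),
                 object_classes = object_classes,
                 background_hematoxylin = as.numeric(background_hematoxylin),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Rasterize one blob of exactly n_px pixels: the n_px pixel centers with the
# smallest values of the rotated-ellipse quadratic form around (cx, cy)
# (pixel units, 0-based frame). Returns a 2-column matrix of 1-based
# (row, col) indices. The level sets of the form are convex, so the selected
# set is connected.
rasterize_blob <- function(cx, cy, a, b, theta, n_px, height, width) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(height, ceiling(cy + a + 1))
  c0 <- max(1L, floor(cx - a)); c1 <- min(width, ceiling(cx + a + 1))
  rows <- r0:r1; cols <- c0:c1
  # pixel centers in the 0-based px frame
  py <- rows - 0.5; px <- cols - 0.5
  dx <- rep(px - cx, each = length(py))
  dy <- rep(py - cy, times = length(px))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  f <- (u / a)^2 + (v / b)^2
  if (length(f) < n_px) return(NULL)
  sel <- order(f)[seq_len(n_px)]
  ri <- rows[(sel - 1L) %% length(rows) + 1L]
  ci <- cols[(sel - 1L) %/% length(rows) + 1L]
  cbind(row = ri, col = ci)
}

#' Generate a synthetic H-DAB tile with ground truth
#'
#' Plants non-overlapping elliptical blobs with uniform per-object DAB
#' concentration on a hematoxylin background, then renders transmitted
#' intensity per channel c by the Beer-Lambert forward model
#' `I_c = I0_c * 10^-(c_H * M_H,c + c_D * M_D,c) + noise`, clipped to
#' `[0, I0_c]`. Each object is rasterized to exactly
#' `round(area_um2 / pixel_size_um^2)` pixels, so ground-truth areas are
#' within half a pixel-area of the requested area. Placement uses rejection
#' sampling with a bounded retry count and keeps a one-pixel gap between
#' objects so they remain distinct 8-connected components.
#'
#' @param spec A [scene_spec()].
#' @param stain A [stain_model()].
#' @param max_retries Placement attempts per object before failing.
#'
#' @return List with elements:
#' \describe{
#'   \item{tile}{numeric `height x width x 3` array of transmitted
#'     intensities on the `I0` scale (unquantized; see [write_tile()]).}
#'   \item{ground_truth}{list with `label_mask` (integer matrix, 0 =
#'     background, k = object id, ids contiguous from 1), `objects`
#'     (data.frame: `id`, `class`, `pixel_count`, `area_um2`,
#'     `centroid_x_um`, `centroid_y_um`, `dab_concentration`) and
#'     `pixel_size_um`.}
#' }
#' Identical `spec` and `stain` yield bit-identical output.
#' @export
generate_tile <- function(spec, stain = stain_model(), max_retries = 1000L) {
  stopifnot(inherits(spec, "scene_spec"), inherits(stain, "stain_model"))
  h <- spec$tile_size_px[1]; w <- spec$tile_size_px[2]
  psz <- spec$pixel_size_um

  # expand per-object draws
  draws <- do.call(rbind, lapply(spec$object_classes, function(cl) {
    if (cl$count == 0L) return(NULL)
    data.frame(class = rep(cl$name, cl$count),
               area_lo = cl$area_range_um2[1], area_hi = cl$area_range_um2[2],
               dab_lo = cl$dab_range[1], dab_hi = cl$dab_range[2])
  }))

  label_mask <- matrix(0L, h, w)
  cd_map <- matrix(0, h, w)
  objects <- data.frame(id = integer(), class = character(),
                        pixel_count = integer(), area_um2 = numeric(),
                        centroid_x_um = numeric(), centroid_y_um = numeric(),
                        dab_concentration = numeric())

  with_seed(spec$seed, {
    if (!is.null(draws) && nrow(draws) > 0L) {
      draws$area <- runif(nrow(draws), draws$area_lo, draws$area_hi)
      draws$dab <- runif(nrow(draws), draws$dab_lo, draws$dab_hi)
      draws$q <- runif(nrow(draws), 0.65, 1)
      draws$theta <- runif(nrow(draws), 0, pi)
      # place large objects first: rejection sampling then succeeds at
      # realistic fill fractions
      draws <- draws[order(-draws$area), , drop = FALSE]

      occupied <- matrix(FALSE, h, w)
      next_id <- 1L
      for (i in seq_len(nrow(draws))) {
        n_px <- max(1L, as.integer(round(draws$area[i] / psz^2)))
        a <- sqrt(n_px / (pi * draws$q[i]))
        b <- draws$q[i] * a
        margin <- a + 2
        if (2 * margin >= min(h, w)) {
          stop("tile too small for a ", draws$class[i], " object of ",
               round(draws$area[i]), " um^2 (placement failure)")
        }
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          cx <- runif(1, margin, w - margin)
          cy <- runif(1, margin, h - margin)
          px <- rasterize_blob(cx, cy, a, b, draws$theta[i], n_px, h, w)
          if (is.null(px)) next
          # require a clear one-pixel halo so objects stay separate
          # 8-connected components
          clear <- TRUE
          for (dr in -1:1) for (dc in -1:1) {
            idx <- cbind(px[, 1] + dr, px[, 2] + dc)
            ok <- idx[, 1] >= 1 & idx[, 1] <= h & idx[, 2] >= 1 & idx[, 2] <= w
            if (any(occupied[idx[ok, , drop = FALSE]])) { clear <- FALSE; break }
          }
          if (!clear) next
          occupied[px] <- TRUE
          label_mask[px] <- next_id
          cd_map[px] <- draws$dab[i]
          objects <- rbind(objects, data.frame(
            id = next_id, class = draws$class[i],
            pixel_count = n_px, area_um2 = n_px * psz^2,
            centroid_x_um = mean(px[, 2] - 0.5) * psz,
            centroid_y_um = mean(px[, 1] - 0.5) * psz,
            dab_concentration = draws$dab[i]))
          next_id <- next_id + 1L
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("failed to place ", draws$class[i], " object of ",
               round(draws$area[i]), " um^2 after ", max_retries,
               " retries (placement failure)")
        }
      }
    }

    M <- stain_matrix(stain)
    tile <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      od <- spec$background_hematoxylin * M[ch, 1] + cd_map * M[ch, 2]
      intensity <- stain$background_intensity[ch] * 10^(-od)
      if (spec$noise_sd > 0) {
        intensity <- intensity + rnorm(h * w, sd = spec$noise_sd)
      }
      tile[, , ch] <- pmin(pmax(intensity, 0), stain$background_intensity[ch])
    }
    list(tile = tile,
         ground_truth = list(label_mask = label_mask, objects = objects,
                             pixel_size_um = psz))
  })
}
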