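#' Two-stain optical-density model for H-DAB brightfield images
#'
#' Bundles the unit optical-density (OD) vectors of hematoxylin and DAB with
#' the per-channel background (blank-field) intensity `I0`. The same model
#' parameterizes both the Beer-Lambert forward simulation
#' ([generate_tile()]) and color deconvolution ([deconvolve()]).
#'
#' The default vectors are the standard published H-DAB pair
#' (hematoxylin (0.650, 0.704, 0.286), DAB (0.268, 0.570, 0.776)); both are
#' renormalized to unit Euclidean norm on construction.
#'
#' @param od_hematoxylin Numeric 3-vector, OD direction of hematoxylin.
#' @param od_dab Numeric 3-vector, OD direction of DAB.
#' @param background_intensity Positive numeric 3-vector `I0`, the
#'   transmitted intensity of unstained background per RGB channel
#'   (8-bit scale by default).
#'
#' @return An object of class `stain_model` with elements `od_hematoxylin`,
#'   `od_dab` (unit norm) and `background_intensity`.
#' @examples
#' sm <- stain_model()
#' sum(sm$od_dab^2) # 1
#' @export
stain_model <- function(od_hematoxylin = c(0.650, 0.704, 0.286),
                        od_dab = c(0.268, 0.570, 0.776),
                        background_intensity = c(255, 255, 255)) {
  stopifnot(length(od_hematoxylin) == 3L, length(od_dab) == 3L,
            length(background_intensity) == 3L,
            all(is.finite(od_hematoxylin)), all(is.finite(od_dab)),
            all(background_intensity > 0))
  h <- od_hematoxylin / sqrt(sum(od_hematoxylin^2))
  d <- od_dab / sqrt(sum(od_dab^2))
  # linear independence: reject (near-)collinear vectors outright
  if (abs(abs(sum(h * d)) - 1) < 1e-8) {
    stop("stain vectors are collinear; deconvolution would be ill-posed")
  }
  structure(
    list(od_hematoxylin = h, od_dab = d,
         background_intensity = as.numeric(background_intensity)),
    class = "stain_model"
  )
}

# 3 x 2 stain matrix M = [m_H | m_D]
stain_matrix <- function(stain) {
  stopifnot(inherits(stain, "stain_model"))
  cbind(H = stain$od_hematoxylin, D = stain$od_dab)
}

#' @export
print.stain_model <- function(x, ...) {
  cat("H-DAB stain model\n")
  cat("  hematoxylin OD vector:", sprintf("%.4f", x$od_hematoxylin), "\n")
  cat("  DAB OD vector:        ", sprintf("%.4f", x$od_dab), "\n")
  cat("  background intensity: ", x$background_intensity, "\n")
  invisible(x)
}
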