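#' Construct the oocyte nuclear geometry
#'
#' Builds the spatial world of the congression simulation: a spherical
#' nuclear region (70 µm diameter by default), two static centrosomes near
#' the cortex at the animal pole (AP), and the AP convergence point `p` on
#' the nuclear boundary toward which the F-actin velocity field points.
#'
#' The centrosomes are placed symmetrically about the center-to-`p` axis:
#' both at depth `cortex_offset` from the boundary along that axis, separated
#' by `centrosome_gap` perpendicular to it. `p` is the boundary point on the
#' outward ray through the centrosome midpoint.
#'
#' @param nucleus_radius Nuclear radius in µm (default 35, i.e. a 70-µm
#'   diameter germinal vesicle).
#' @param centrosome_gap Distance between the two centrosomes in µm
#'   (default 6).
#' @param cortex_offset Depth of each centrosome below the cortex/boundary in
#'   µm (default 3).
#' @param nucleus_center 3-vector, center of the nuclear sphere in µm
#'   (default the origin).
#' @return An object of class `oocyte_geometry`: a list with
#'   `nucleus_center`, `nucleus_radius`, `ap_point` (the point `p`), and
#'   `centrosomes` (2 x 3 matrix, one row per centrosome), all in µm.
#' @examples
#' geom <- oocyte_geometry()
#' sqrt(sum((geom$centrosomes[1, ] - geom$nucleus_center)^2)) # 32 um
#' @export
oocyte_geometry <- function(nucleus_radius = 35,
                            centrosome_gap = 6,
                            cortex_offset = 3,
                            nucleus_center = c(0, 0, 0)) {
  if (!is.numeric(nucleus_radius) || length(nucleus_radius) != 1 ||
      !is.finite(nucleus_radius) || nucleus_radius <= 0) {
    stop("`nucleus_radius` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(cortex_offset) || length(cortex_offset) != 1 ||
      !is.finite(cortex_offset) || cortex_offset <= 0) {
    stop("`cortex_offset` must be a single positive number", call. = FALSE)
  }
  if (cortex_offset >= nucleus_radius) {
    stop("`cortex_offset` must be smaller than `nucleus_radius`",
         call. = FALSE)
  }
  if (!is.numeric(centrosome_gap) || length(centrosome_gap) != 1 ||
      !is.finite(centrosome_gap) || centrosome_gap < 0) {
    stop("`centrosome_gap` must be a single nonnegative number",
         call. = FALSE)
  }
  if (centrosome_gap >= 2 * nucleus_radius) {
    stop("`centrosome_gap` must be smaller than the nuclear diameter",
         call. = FALSE)
  }
  if (!is.numeric(nucleus_center) || length(nucleus_center) != 3 ||
      anyNA(nucleus_center)) {
    stop("`nucleus_center` must be a numeric 3-vector", call. = FALSE)
  }
  nucleus_center <- as.numeric(nucleus_center)

  # AP axis: unit vector from center to p; conventionally +x.
  axis <- c(1, 0, 0)
  perp <- c(0, 1, 0)
  p <- nucleus_center + nucleus_radius * axis
  depth <- nucleus_radius - cortex_offset
  half_gap <- centrosome_gap / 2
  # Centrosomes sit at |c - center| = nucleus_radius - cortex_offset,
  # symmetric about the AP axis, `centrosome_gap` apart.
  along <- sqrt(depth^2 - half_gap^2)
  if (!is.finite(along)) {
    stop("`centrosome_gap` too large for the requested `cortex_offset`",
         call. = FALSE)
  }
  centrosomes <- rbind(
    nucleus_center + along * axis + half_gap * perp,
    nucleus_center + along * axis - half_gap * perp
  )
  rownames(centrosomes) <- NULL

  structure(
    list(
      nucleus_center = nucleus_center,
      nucleus_radius = nucleus_radius,
      ap_point = p,
      centrosomes = centrosomes
    ),
    class = "oocyte_geometry"
  )
}

#' @export
print.oocyte_geometry <- function(x, ...) {
  cat("<oocyte_geometry>\n")
  cat(sprintf("  nucleus: radius %.1f um, center (%.1f, %.1f, %.1f)\n",
              x$nucleus_radius, x$nucleus_center[1], x$nucleus_center[2],
              x$nucleus_center[3]))
  cat(sprintf("  AP point p: (%.2f, %.2f, %.2f)\n",
              x$ap_point[1], x$ap_point[2], x$ap_point[3]))
  d <- sqrt(sum((x$centrosomes[1, ] - x$centrosomes[2, ])^2))
  cat(sprintf("  centrosomes: %.2f um apart, %.2f um below the cortex\n", d,
              x$nucleus_radius -
                sqrt(sum((x$centrosomes[1, ] - x$nucleus_center)^2))))
  invisible(x)
}
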