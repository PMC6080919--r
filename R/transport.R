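#' F-actin network velocity field
#'
#' The contracting F-actin network is represented by a velocity field
#' advecting free chromosomes toward the AP point `p`:
#' v(x, t) = (p - x) / (t_x - t) for t in \[0, t_m\], and 0 for t > t_m.
#' Under pure advection every chromosome moves at the constant speed
#' d0 / t_x (d0 its distance to `p` at NEBD) and all chromosomes would reach
#' `p` simultaneously at t_x, but the transport stops earlier, at t_m.
#'
#' @param p AP convergence point, 3-vector in µm (e.g.
#'   `oocyte_geometry()$ap_point`).
#' @param t_x Convergence time in minutes (default 15).
#' @param t_m Transport stop time in minutes (default 12.5; < t_x).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(p, t_x = 15, t_m = 12.5) {
  if (!is.numeric(p) || length(p) != 3 || anyNA(p)) {
    stop("`p` must be a numeric 3-vector", call. = FALSE)
  }
  if (t_m >= t_x) stop("`t_m` must be smaller than `t_x`", call. = FALSE)
  if (t_m <= 0 || t_x <= 0) stop("times must be positive", call. = FALSE)
  structure(list(p = as.numeric(p), t_x = t_x, t_m = t_m),
            class = "velocity_field")
}

#' Evaluate the F-actin velocity field
#'
#' @param x Position(s) in µm: a 3-vector or an n x 3 matrix.
#' @param t Time in minutes after NEBD (scalar, >= 0).
#' @param field A [velocity_field()].
#' @return Velocity in µm/min with the same shape as `x`. The zero vector
#'   for `t > t_m`.
#' @examples
#' f <- velocity_field(p = c(35, 0, 0))
#' velocity_at(c(5, 0, 0), 0, f) # 2 um/min toward p
#' @export
velocity_at <- function(x, t, field) {
  stopifnot(inherits(field, "velocity_field"))
  if (length(t) != 1 || t < 0) stop("`t` must be a scalar >= 0",
                                    call. = FALSE)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 3) else as.matrix(x)
  if (ncol(xm) != 3) stop("`x` must have 3 coordinates", call. = FALSE)
  if (t > field$t_m) {
    v <- xm * 0
  } else {
    if (t >= field$t_x) {
      # unreachable when t_m < t_x; rejected defensively
      stop("`t` must be below the convergence time t_x", call. = FALSE)
    }
    v <- sweep(-xm, 2, -field$p) / (field$t_x - t)
  }
  if (vec) drop(v) else v
}

#' One Euler-Maruyama step for free chromosomes
#'
#' x <- x + v(x, t) dt + xi, with xi a zero-mean isotropic Gaussian
#' displacement of per-axis variance 2 D dt (Stokes-Einstein D from
#' [diffusion_coefficient()]). In model variant 1 the advective term is
#' omitted. Chromosome centers are reflected at the nuclear boundary
#' (at radius `nucleus_radius - chromosome_radius`).
#'
#' Normal draws are consumed chromosome-by-chromosome (3 per free
#' chromosome, x/y/z order).
#'
#' @param pos n x 3 matrix of free-chromosome centers (µm).
#' @param t Time in minutes after NEBD.
#' @param field A [velocity_field()].
#' @param params A [sim_params()].
#' @param geometry An [oocyte_geometry()].
#' @param z Optional 3n vector of standard-normal draws (testing hook).
#' @return Updated n x 3 matrix.
#' @export
step_chromosomes_free <- function(pos, t, field, params, geometry,
                                  z = NULL) {
  stopifnot(inherits(params, "sim_params"),
            inherits(geometry, "oocyte_geometry"))
  pos <- as.matrix(pos)
  n <- nrow(pos)
  dt_min <- params$dt / 60
  if (params$model_variant >= 2) {
    pos <- pos + velocity_at(pos, t, field) * dt_min
  }
  d_um2s <- diffusion_coefficient(params)
  sd_axis <- sqrt(2 * d_um2s * params$dt)
  if (is.null(z)) z <- stats::rnorm(3L * n)
  pos <- pos + matrix(z, ncol = 3, byrow = TRUE) * sd_axis
  reflect_in_sphere(pos, geometry$nucleus_center,
                    geometry$nucleus_radius - params$chromosome_radius)
}

# Radial reflection of points that stepped outside the sphere.
reflect_in_sphere <- function(pos, center, radius) {
  rel <- sweep(pos, 2, center)
  r <- sqrt(rowSums(rel^2))
  out <- r > radius
  if (any(out)) {
    scale <- (2 * radius - r[out]) / r[out]
    scale <- pmax(scale, 0) # degenerate overshoot past the mirror image
    rel[out, ] <- rel[out, , drop = FALSE] * scale
    pos[out, ] <- sweep(rel[out, , drop = FALSE], 2, center, `+`)
  }
  pos
}

#' Initial chromosome placement
#'
#' Draws `n` positions uniformly over the nuclear volume, rejection-sampled
#' to lie at least `margin` µm inside the boundary and at least
#' `min_separation` µm apart pairwise. There are no excluded-volume
#' interactions afterwards.
#'
#' @param geometry An [oocyte_geometry()].
#' @param n Number of chromosomes (default 22).
#' @param margin Minimum distance from the boundary, µm (default 1).
#' @param min_separation Minimum pairwise distance, µm (default 2).
#' @return n x 3 matrix of positions (µm).
#' @export
place_chromosomes <- function(geometry, n = 22, margin = 1,
                              min_separation = 2) {
  stopifnot(inherits(geometry, "oocyte_geometry"))
  r_max <- geometry$nucleus_radius - margin
  out <- matrix(NA_real_, n, 3)
  k <- 0L
  tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 100000L) stop("chromosome placement failed", call. = FALSE)
    cand <- stats::runif(3, -r_max, r_max)
    if (sum(cand^2) > r_max^2) next
    cand <- cand + geometry$nucleus_center
    if (k > 0L) {
      d2 <- rowSums(sweep(out[seq_len(k), , drop = FALSE], 2, cand)^2)
      if (min(d2) < min_separation^2) next
    }
    k <- k + 1L
    out[k, ] <- cand
  }
  out
}
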