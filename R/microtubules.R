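#' Length-dependent catastrophe rate
#'
#' Linear form k(L) = k0 + k1 L, with "distance" interpreted as filament
#' length (tip distance from its nucleating centrosome). Monotone
#' nondecreasing for k1 >= 0; alternate monotone forms can be swapped in by
#' passing a function for `form`.
#'
#' @param length Filament length(s) in µm (vectorized, >= 0).
#' @param params A [sim_params()] supplying `catastrophe_base` (k0, 1/min)
#'   and `catastrophe_slope` (k1, 1/(min µm)); alternatively give `k0`/`k1`
#'   directly.
#' @param k0,k1 Rate parameters used when `params` is `NULL`.
#' @param form Optional function `(length, k0, k1) -> rate` replacing the
#'   linear form.
#' @return Catastrophe rate(s) in 1/min.
#' @examples
#' catastrophe_rate(10, k0 = 1, k1 = 0.1) # 2 per min
#' @export
catastrophe_rate <- function(length, params = NULL, k0 = 1, k1 = 0.1,
                             form = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "sim_params"))
    k0 <- params$catastrophe_base
    k1 <- params$catastrophe_slope
  }
  if (any(length < 0)) stop("`length` must be >= 0", call. = FALSE)
  if (is.null(form)) k0 + k1 * length else form(length, k0, k1)
}

#' Initialize a microtubule population
#'
#' Nucleates `n_mt_per_aster` microtubules of length 0, state "growing",
#' with directions uniform on the unit sphere, from each of the two
#' centrosomes.
#'
#' @param geometry An [oocyte_geometry()].
#' @param params A [sim_params()].
#' @return A tibble with one row per microtubule: `aster` (1 or 2), unit
#'   direction `dx, dy, dz`, `length` (µm) and `state` ("growing" or
#'   "shrinking").
#' @export
init_microtubules <- function(geometry, params) {
  stopifnot(inherits(geometry, "oocyte_geometry"),
            inherits(params, "sim_params"))
  n <- 2L * params$n_mt_per_aster
  dir <- random_unit_vectors(n)
  tibble::tibble(
    aster = rep(1:2, each = params$n_mt_per_aster),
    dx = dir[, 1], dy = dir[, 2], dz = dir[, 3],
    length = rep(0, n),
    state = rep("growing", n)
  )
}

# Uniform directions via z = 2u1 - 1, phi = 2 pi u2; consumes 2 draws each
# (same convention as the engine).
random_unit_vectors <- function(n, u = NULL) {
  if (is.null(u)) u <- stats::runif(2L * n)
  z <- 2 * u[seq(1L, by = 2L, length.out = n)] - 1
  phi <- 2 * pi * u[seq(2L, by = 2L, length.out = n)]
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Advance a microtubule population one time step
#'
#' Growing filaments extend by v_g dt and undergo catastrophe with
#' probability 1 - exp(-k(L) dt); a tip reaching the nuclear boundary is
#' clamped to it and switched to shrinking in the same step. Shrinking
#' filaments retract by v_s dt; a filament reaching length 0 renucleates
#' immediately (growing, fresh uniformly random direction). Rescue rate is
#' zero. The population size per aster is conserved.
#'
#' Random draws are consumed in microtubule index order based on the state
#' at step entry (1 uniform per growing filament; 2 uniforms per shrinking
#' filament that will hit length 0 this step), so the vectorized update is
#' bit-identical to a per-filament loop using the same stream.
#'
#' @param mts Tibble from [init_microtubules()] (or a previous step).
#' @param geometry An [oocyte_geometry()].
#' @param params A [sim_params()].
#' @param u Optional vector of uniform draws to consume (for testing);
#'   defaults to `runif()` on the current RNG stream.
#' @return Updated microtubule tibble.
#' @export
step_microtubules <- function(mts, geometry, params, u = NULL) {
  stopifnot(inherits(geometry, "oocyte_geometry"),
            inherits(params, "sim_params"))
  dt_min <- params$dt / 60
  grow <- mts$state == "growing"
  shrink <- !grow
  will_renuc <- shrink & (mts$length - params$mt_shrink_speed * dt_min <= 0)

  # draw bookkeeping: growing -> 1, renucleating -> 2, others -> 0
  need <- ifelse(grow, 1L, ifelse(will_renuc, 2L, 0L))
  total <- sum(need)
  if (is.null(u)) u <- stats::runif(total)
  if (length(u) < total) stop("not enough uniform draws supplied",
                              call. = FALSE)
  offset <- cumsum(c(0L, need))[seq_len(nrow(mts))]

  len <- mts$length
  state <- mts$state
  dirm <- cbind(mts$dx, mts$dy, mts$dz)

  # --- growing filaments ---
  if (any(grow)) {
    len_g <- len[grow] + params$mt_growth_speed * dt_min
    # boundary: solve |o + L d - c| = R along each direction
    og <- geometry$centrosomes[mts$aster[grow], , drop = FALSE]
    rel <- sweep(og, 2, geometry$nucleus_center)
    dg <- dirm[grow, , drop = FALSE]
    b <- rowSums(rel * dg)
    c0 <- rowSums(rel * rel) - geometry$nucleus_radius^2
    l_max <- -b + sqrt(pmax(0, b^2 - c0)) # positive root; origin is inside
    hit <- len_g >= l_max
    u_cat <- u[offset[grow] + 1L]
    p_cat <- 1 - exp(-catastrophe_rate(pmin(len_g, l_max),
                                       k0 = params$catastrophe_base,
                                       k1 = params$catastrophe_slope) *
                       dt_min)
    cat_now <- hit | (u_cat < p_cat)
    len[grow] <- pmin(len_g, l_max)
    state[grow][cat_now] <- "shrinking"
  }

  # --- shrinking filaments ---
  if (any(shrink)) {
    len_s <- len[shrink] - params$mt_shrink_speed * dt_min
    len[shrink] <- pmax(len_s, 0)
  }
  if (any(will_renuc)) {
    idx <- which(will_renuc)
    udraw <- as.vector(t(cbind(u[offset[idx] + 1L], u[offset[idx] + 2L])))
    dirm[idx, ] <- random_unit_vectors(length(idx), u = udraw)
    len[idx] <- 0
    state[idx] <- "growing"
  }

  mts$dx <- dirm[, 1]; mts$dy <- dirm[, 2]; mts$dz <- dirm[, 3]
  mts$length <- len
  mts$state <- state
  mts
}
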