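#' Simulation parameters for the congression model
#'
#' Collects and validates every tunable of the two-step congression
#' simulation. Internal units are µm and seconds; user-facing times are
#' minutes after nuclear envelope breakdown (NEBD), which is time zero.
#'
#' Model variants: 1 = classic search-and-capture only (no velocity field,
#' binding gate constant at 1); 2 = adds the F-actin-network velocity field
#' advecting free chromosomes toward the AP; 3 = additionally gates the
#' kinetochore binding rate with [gate_schedule()] emulating F-actin patches.
#'
#' The microtubule parameters (`mt_growth_speed`, `mt_shrink_speed`,
#' `catastrophe_base`, `catastrophe_slope`, `n_mt_per_aster`,
#' `capture_radius`, `base_binding_rate`) were calibrated once on variant 1
#' against the Latrunculin-condition capture statistics (mean capture time
#' of in-range chromosomes and the ~30 µm capture range) and then frozen for
#' all variants; see the package vignette for the calibration protocol.
#'
#' @param dt Time step in seconds (default 0.05; must be <= 0.1).
#' @param t_end Total simulated time in minutes (default 25).
#' @param t_x Convergence time of the velocity field in minutes (default 15).
#' @param t_m Time at which F-actin transport stops, minutes (default 12.5;
#'   must be < `t_x`).
#' @param chromosome_radius Chromosome radius in µm (default 0.8).
#' @param viscosity Nucleoplasm viscosity in Pa s (default 0.1).
#' @param temperature Temperature in K (default 293, matching 19-21 degC
#'   imaging).
#' @param n_chromosomes Number of chromosomes (default 22).
#' @param mt_growth_speed Microtubule growth speed v_g, µm/min.
#' @param mt_shrink_speed Microtubule shrinkage speed v_s, µm/min.
#' @param n_mt_per_aster Number of microtubules per centrosomal aster.
#' @param catastrophe_base Catastrophe rate at zero length k0, 1/min.
#' @param catastrophe_slope Length dependence of the catastrophe rate k1,
#'   1/(min µm).
#' @param capture_radius Capture distance rho_c between a microtubule
#'   segment and the chromosome surface, µm.
#' @param base_binding_rate Kinetochore-microtubule binding rate k_on at an
#'   open gate, 1/s.
#' @param transport_speed Poleward (dynein) transport speed v_dyn, µm/min
#'   (default 9.22).
#' @param arrival_radius Distance from the centrosome at which a transported
#'   chromosome counts as arrived, µm (default 2).
#' @param model_variant Integer 1, 2 or 3 (see Details).
#' @param gate Gate schedule from [gate_schedule()]; used only by variant 3.
#' @param report_interval Trajectory sampling interval in seconds (default 3,
#'   the experimental frame interval).
#' @param stabilize_on_capture Logical; if `TRUE` (default) the microtubule
#'   hosting a captured chromosome pauses its dynamic instability until the
#'   chromosome arrives, so poleward motion occurs at `transport_speed`. If
#'   `FALSE`, the host microtubule keeps its dynamics, a shrinking tip drags
#'   the lateral attachment with it, and full depolymerization releases the
#'   chromosome back to the free state.
#' @param seed Integer seed; every random draw in the simulation derives
#'   from it (same seed, same build => bit-identical results).
#' @return A validated list of class `sim_params`.
#' @examples
#' p <- sim_params(model_variant = 3, seed = 1)
#' p$dt
#' @export
sim_params <- function(dt = 0.05,
                       t_end = 25,
                       t_x = 15,
                       t_m = 12.5,
                       chromosome_radius = 0.8,
                       viscosity = 0.1,
                       temperature = 293,
                       n_chromosomes = 22,
                       mt_growth_speed = 15,
                       mt_shrink_speed = 25,
                       n_mt_per_aster = 750,
                       catastrophe_base = 1,
                       catastrophe_slope = 0.22,
                       capture_radius = 0.8,
                       base_binding_rate = 0.1,
                       transport_speed = 9.22,
                       arrival_radius = 2,
                       model_variant = 3,
                       gate = gate_schedule(),
                       report_interval = 3,
                       stabilize_on_capture = TRUE,
                       seed = 1L) {
  p <- list(
    dt = dt, t_end = t_end, t_x = t_x, t_m = t_m,
    chromosome_radius = chromosome_radius, viscosity = viscosity,
    temperature = temperature, n_chromosomes = n_chromosomes,
    mt_growth_speed = mt_growth_speed, mt_shrink_speed = mt_shrink_speed,
    n_mt_per_aster = n_mt_per_aster, catastrophe_base = catastrophe_base,
    catastrophe_slope = catastrophe_slope, capture_radius = capture_radius,
    base_binding_rate = base_binding_rate, transport_speed = transport_speed,
    arrival_radius = arrival_radius, model_variant = model_variant,
    gate = gate, report_interval = report_interval,
    stabilize_on_capture = isTRUE(stabilize_on_capture),
    seed = as.integer(seed)
  )
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  pos <- c("dt", "t_end", "t_x", "t_m", "chromosome_radius", "viscosity",
           "mt_growth_speed", "mt_shrink_speed", "base_binding_rate",
           "capture_radius", "transport_speed", "arrival_radius",
           "report_interval")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", f),
           call. = FALSE)
    }
  }
  nonneg <- c("temperature", "catastrophe_base", "catastrophe_slope")
  for (f in nonneg) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single nonnegative number", f),
           call. = FALSE)
    }
  }
  counts <- c("n_chromosomes", "n_mt_per_aster")
  for (f in counts) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop(sprintf("`%s` must be a positive integer", f), call. = FALSE)
    }
    p[[f]] <- as.integer(v)
  }
  if (p$dt > 0.1) stop("`dt` must be <= 0.1 s", call. = FALSE)
  if (p$t_m >= p$t_x) stop("`t_m` must be smaller than `t_x`", call. = FALSE)
  if (!p$model_variant %in% 1:3) {
    stop("`model_variant` must be 1, 2 or 3", call. = FALSE)
  }
  p$model_variant <- as.integer(p$model_variant)
  if (!inherits(p$gate, "gate_schedule")) {
    stop("`gate` must be a gate_schedule object", call. = FALSE)
  }
  if (is.na(p$seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  variant %d | dt %.3g s | t_end %g min | seed %d\n",
              x$model_variant, x$dt, x$t_end, x$seed))
  cat(sprintf("  field: t_x %g min, t_m %g min | v_dyn %.3g um/min\n",
              x$t_x, x$t_m, x$transport_speed))
  cat(sprintf(
    "  MTs: %d/aster, v_g %.3g, v_s %.3g um/min, k0 %.3g, k1 %.3g\n",
    x$n_mt_per_aster, x$mt_growth_speed, x$mt_shrink_speed,
    x$catastrophe_base, x$catastrophe_slope))
  cat(sprintf("  capture: rho_c %.3g um, k_on %.3g /s, arrival %.3g um\n",
              x$capture_radius, x$base_binding_rate, x$arrival_radius))
  invisible(x)
}

#' Stokes-Einstein diffusion coefficient of a chromosome
#'
#' D = kT / (6 pi eta r) for a sphere of radius `r` in a fluid of viscosity
#' `eta`, returned in µm^2/s. Defaults describe a 0.8-µm-radius chromosome
#' in 0.1 Pa s nucleoplasm at 293 K (D approx 2.7e-3 µm^2/s).
#'
#' @param params Optional `sim_params`; if supplied, radius, viscosity and
#'   temperature are taken from it.
#' @param radius Sphere radius in µm.
#' @param viscosity Fluid viscosity in Pa s.
#' @param temperature Temperature in K.
#' @return Diffusion coefficient in µm^2/s.
#' @examples
#' diffusion_coefficient(radius = 0.8, viscosity = 0.1, temperature = 293)
#' @export
diffusion_coefficient <- function(params = NULL, radius = 0.8,
                                  viscosity = 0.1, temperature = 293) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "sim_params"))
    radius <- params$chromosome_radius
    viscosity <- params$viscosity
    temperature <- params$temperature
  }
  if (radius <= 0 || viscosity <= 0 || temperature < 0) {
    stop("radius and viscosity must be positive, temperature nonnegative",
         call. = FALSE)
  }
  k_b <- 1.380649e-23 # J/K
  # SI: m^2/s, then to um^2/s (1 m^2 = 1e12 um^2); radius um -> m.
  d_si <- k_b * temperature / (6 * pi * viscosity * radius * 1e-6)
  d_si * 1e12
}
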