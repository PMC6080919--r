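#' Run one congression simulation (one oocyte)
#'
#' Full stochastic loop from NEBD (t = 0) to `t_end` at step `dt`:
#' microtubule dynamic instability from the two centrosomes, free-chromosome
#' motion (velocity field in variants 2-3 plus Brownian noise), gated
#' capture attempts (variant 3), and poleward dynein transport of captured
#' chromosomes. Chromosomes still free at `t_end` are marked lost.
#' Trajectories are sampled every `report_interval` seconds (3 s by
#' default, the experimental frame interval).
#'
#' @param params A [sim_params()].
#' @param geometry An [oocyte_geometry()] (default geometry if omitted).
#' @return An object of class `congression_sim`: a list with
#'   \describe{
#'     \item{trajectories}{tibble: `chromosome`, `t_s`, `x_um`, `y_um`,
#'       `z_um`, `state`}
#'     \item{events}{tibble: `chromosome`, `initial_distance_um` (to the
#'       AP), `capture_time_min`, `arrival_time_min`, `final_state`}
#'     \item{params, geometry, seed}{run inputs, echoed}
#'   }
#' @examples
#' \donttest{
#' res <- run_simulation(sim_params(model_variant = 2, seed = 7))
#' glance(res)
#' }
#' @export
run_simulation <- function(params = sim_params(), geometry = oocyte_geometry()) {
  stopifnot(inherits(params, "sim_params"),
            inherits(geometry, "oocyte_geometry"))
  report_every <- as.integer(round(params$report_interval / params$dt))
  if (report_every < 1) stop("`report_interval` must be >= dt",
                             call. = FALSE)
  res <- withr::with_seed(params$seed, {
    chrom0 <- place_chromosomes(geometry, n = params$n_chromosomes)
    eng <- run_engine_cpp(
      center = geometry$nucleus_center,
      nucleus_radius = geometry$nucleus_radius,
      centrosomes = geometry$centrosomes,
      p_ap = geometry$ap_point,
      chrom0 = chrom0,
      par = list(
        dt = params$dt, t_end = params$t_end, t_x = params$t_x,
        t_m = params$t_m, mt_growth_speed = params$mt_growth_speed,
        mt_shrink_speed = params$mt_shrink_speed,
        catastrophe_base = params$catastrophe_base,
        catastrophe_slope = params$catastrophe_slope,
        n_mt_per_aster = params$n_mt_per_aster,
        capture_radius = params$capture_radius,
        base_binding_rate = params$base_binding_rate,
        transport_speed = params$transport_speed,
        arrival_radius = params$arrival_radius,
        chromosome_radius = params$chromosome_radius,
        model_variant = params$model_variant,
        diffusion = diffusion_coefficient(params),
        report_every = report_every,
        stabilize_on_capture = params$stabilize_on_capture
      ),
      gate_time = if (params$model_variant == 3) params$gate$time else 0,
      gate_frac = if (params$model_variant == 3) params$gate$fraction else 1
    )
    list(chrom0 = chrom0, eng = eng)
  })
  chrom0 <- res$chrom0
  eng <- res$eng

  n_chrom <- params$n_chromosomes
  n_frames <- length(eng$frame_t)
  state_codes <- c("free", "captured", "arrived")
  traj <- tibble::tibble(
    chromosome = rep(seq_len(n_chrom), each = n_frames),
    t_s = rep(eng$frame_t, times = n_chrom),
    x_um = as.vector(eng$traj[, , 1]),
    y_um = as.vector(eng$traj[, , 2]),
    z_um = as.vector(eng$traj[, , 3]),
    state = state_codes[as.vector(eng$states) + 1L]
  )
  final <- state_codes[eng$final_state + 1L]
  final[final == "free"] <- "lost"
  d0 <- sqrt(rowSums(sweep(chrom0, 2, geometry$ap_point)^2))
  events <- tibble::tibble(
    chromosome = seq_len(n_chrom),
    initial_distance_um = d0,
    capture_time_min = eng$capture_time,
    arrival_time_min = eng$arrival_time,
    final_state = final
  )
  structure(
    list(trajectories = traj, events = events, params = params,
         geometry = geometry, seed = params$seed),
    class = "congression_sim"
  )
}

#' Run a cohort of independent simulated oocytes
#'
#' `n_oocytes` independent runs with seeds `base_seed + 0:(n-1)`;
#' trajectories and event tables are pooled with an `oocyte` column.
#'
#' @param n_oocytes Number of oocytes (default 13, matching the
#'   experimental cohorts).
#' @param params A [sim_params()]; its `seed` is ignored in favor of
#'   `base_seed + i`.
#' @param base_seed Integer seed for the first oocyte.
#' @param geometry An [oocyte_geometry()].
#' @return An object of class `congression_cohort` with pooled
#'   `trajectories` and `events` tibbles (first column `oocyte`).
#' @export
run_cohort <- function(n_oocytes = 13, params = sim_params(),
                       base_seed = params$seed,
                       geometry = oocyte_geometry()) {
  stopifnot(n_oocytes >= 1)
  runs <- purrr::map(seq_len(n_oocytes), function(i) {
    p <- params
    p$seed <- as.integer(base_seed + i - 1L)
    run_simulation(p, geometry)
  })
  traj <- purrr::map2_dfr(runs, seq_len(n_oocytes), function(r, i) {
    dplyr::mutate(r$trajectories, oocyte = i, .before = 1)
  })
  events <- purrr::map2_dfr(runs, seq_len(n_oocytes), function(r, i) {
    dplyr::mutate(r$events, oocyte = i, .before = 1)
  })
  structure(
    list(trajectories = traj, events = events, params = params,
         geometry = geometry, base_seed = base_seed,
         n_oocytes = n_oocytes),
    class = "congression_cohort"
  )
}

#' @export
print.congression_sim <- function(x, ...) {
  cat("<congression_sim>\n")
  cat(sprintf("  variant %d, seed %d, %d chromosomes\n",
              x$params$model_variant, x$seed, x$params$n_chromosomes))
  print(table(x$events$final_state))
  invisible(x)
}

#' @export
print.congression_cohort <- function(x, ...) {
  cat(sprintf("<congression_cohort> %d oocytes, variant %d, base seed %d\n",
              x$n_oocytes, x$params$model_variant, x$base_seed))
  print(table(x$events$final_state))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-chromosome event table of a simulation
#' @param x A `congression_sim` or `congression_cohort`.
#' @param ... Unused.
#' @return The events tibble (one row per chromosome).
#' @export
tidy.congression_sim <- function(x, ...) x$events

#' @rdname tidy.congression_sim
#' @export
tidy.congression_cohort <- function(x, ...) x$events

#' One-row summary of a simulation run or cohort
#' @param x A `congression_sim` or `congression_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: counts by final state, mean/SD capture time
#'   (min), and the number of oocytes.
#' @export
glance.congression_sim <- function(x, ...) {
  glance_events(x$events, n_oocytes = 1L, variant = x$params$model_variant)
}

#' @rdname glance.congression_sim
#' @export
glance.congression_cohort <- function(x, ...) {
  glance_events(x$events, n_oocytes = x$n_oocytes,
                variant = x$params$model_variant)
}

glance_events <- function(ev, n_oocytes, variant) {
  ct <- ev$capture_time_min[!is.na(ev$capture_time_min)]
  tibble::tibble(
    n_oocytes = n_oocytes,
    model_variant = variant,
    n_chromosomes = nrow(ev),
    n_captured = sum(ev$final_state %in% c("captured", "arrived")),
    n_lost = sum(ev$final_state == "lost"),
    mean_capture_time_min = if (length(ct)) mean(ct) else NA_real_,
    sd_capture_time_min = if (length(ct) > 1) stats::sd(ct) else NA_real_
  )
}
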