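#' Specification for synthetic ground-truth data
#'
#' Defines the statistical structure of synthetic chromosome trajectories
#' and patch-intensity traces for the two experimental conditions:
#' `"control"` (two-phase motion: F-actin advection, then dynein transport;
#' patch kinetics onset 1.5 / peak 5 / background return 8 min) and
#' `"latrunculin"` (no advection; chromosomes beyond the capture range stay
#' diffusive and are lost; premature patch disassembly at 4 min). Switch
#' times and post-switch speeds are drawn from the measured distributions
#' (control switch 9.21 +/- 2.36 min, Latrunculin 6.16 +/- 3.92 min,
#' truncated >= 0; speed 9.22 +/- 2.86 µm/min, truncated > 0).
#'
#' @param condition `"control"` or `"latrunculin"`.
#' @param n_oocytes Number of synthetic oocytes (default 13).
#' @param n_chromosomes Chromosomes per oocyte (default 22).
#' @param frame_interval_s Frame interval in seconds (default 3).
#' @param duration_min Track duration in minutes (default 20).
#' @param speed_mean,speed_sd Post-switch speed distribution, µm/min.
#' @param switch_mean,switch_sd Switch-time distribution, min; defaults
#'   depend on `condition`.
#' @param capture_range_um Maximal initial AP distance with a switch in the
#'   Latrunculin condition (default 30).
#' @param diffusion Diffusion coefficient, µm^2/s (Stokes-Einstein default).
#' @param t_x,t_m Velocity-field convergence/stop times, min.
#' @param patch_onset_min,patch_peak_min,patch_return_min Patch kinetics;
#'   defaults 1.5/5/8 (control) or 1.5/2.5/4 (latrunculin).
#' @param amplitude_range Peak normalized amplitude range (default
#'   `c(2, 6)`).
#' @param intensity_noise_sd SD of the multiplicative Gaussian noise on
#'   traces (default 0.05).
#' @param phase2_jitter_um Isotropic per-frame positional jitter during
#'   directed transport, µm (default 0.1).
#' @param seed Integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(condition = c("control", "latrunculin"),
                           n_oocytes = 13,
                           n_chromosomes = 22,
                           frame_interval_s = 3,
                           duration_min = 20,
                           speed_mean = 9.22, speed_sd = 2.86,
                           switch_mean = NULL, switch_sd = NULL,
                           capture_range_um = 30,
                           diffusion = diffusion_coefficient(),
                           t_x = 15, t_m = 12.5,
                           patch_onset_min = NULL,
                           patch_peak_min = NULL,
                           patch_return_min = NULL,
                           amplitude_range = c(2, 6),
                           intensity_noise_sd = 0.05,
                           phase2_jitter_um = 0.1,
                           seed = 1L) {
  condition <- match.arg(condition)
  ctrl <- condition == "control"
  spec <- list(
    condition = condition,
    n_oocytes = as.integer(n_oocytes),
    n_chromosomes = as.integer(n_chromosomes),
    frame_interval_s = frame_interval_s,
    duration_min = duration_min,
    speed_mean = speed_mean, speed_sd = speed_sd,
    switch_mean = switch_mean %||% if (ctrl) 9.21 else 6.16,
    switch_sd = switch_sd %||% if (ctrl) 2.36 else 3.92,
    capture_range_um = capture_range_um,
    diffusion = diffusion,
    t_x = t_x, t_m = t_m,
    patch_onset_min = patch_onset_min %||% 1.5,
    patch_peak_min = patch_peak_min %||% if (ctrl) 5 else 2.5,
    patch_return_min = patch_return_min %||% if (ctrl) 8 else 4,
    amplitude_range = amplitude_range,
    intensity_noise_sd = intensity_noise_sd,
    phase2_jitter_um = phase2_jitter_um,
    seed = as.integer(seed)
  )
  if (spec$speed_sd < 0 || spec$switch_sd < 0 || intensity_noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (spec$patch_onset_min >= spec$patch_peak_min ||
      spec$patch_peak_min >= spec$patch_return_min) {
    stop("patch kinetics must satisfy onset < peak < return",
         call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lower)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate labeled synthetic chromosome trajectories
#'
#' Phase 1 is velocity-field advection toward the AP (control) or pure
#' diffusion (latrunculin), plus Brownian noise; at each chromosome's drawn
#' switch time the track turns into straight-line motion toward the AP at
#' its drawn speed until within 2 µm of the AP, then stays stationary.
#' Latrunculin chromosomes starting beyond the capture range get no switch
#' (they are "lost" and stay diffusive).
#'
#' @param spec A [synthetic_spec()].
#' @param geometry An [oocyte_geometry()] supplying the AP point and
#'   initial-placement volume.
#' @return List of class `synthetic_trajectories`:
#'   `trajectories` (tibble `oocyte`, `chromosome`, `t_s`, `x_um`, `y_um`,
#'   `z_um`) and `truth` (tibble `oocyte`, `chromosome`,
#'   `initial_distance_um`, `switch_time_min` (NA if lost),
#'   `speed_um_min`).
#' @export
make_trajectories <- function(spec, geometry = oocyte_geometry()) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(geometry, "oocyte_geometry"))
  p <- geometry$ap_point
  dt_s <- spec$frame_interval_s
  t_s <- seq(0, spec$duration_min * 60, by = dt_s)
  n_frames <- length(t_s)
  sd_axis <- sqrt(2 * spec$diffusion * dt_s)

  withr::with_seed(spec$seed, {
    out <- purrr::map(seq_len(spec$n_oocytes), function(oo) {
      pos0 <- place_chromosomes(geometry, n = spec$n_chromosomes)
      d0 <- sqrt(rowSums(sweep(pos0, 2, p)^2))
      switch_t <- rtrunc_norm(spec$n_chromosomes, spec$switch_mean,
                              spec$switch_sd, 0)
      speed <- rtrunc_norm(spec$n_chromosomes, spec$speed_mean,
                           spec$speed_sd, .Machine$double.eps)
      lost <- spec$condition == "latrunculin" & d0 > spec$capture_range_um
      switch_t[lost] <- NA_real_

      tracks <- purrr::map(seq_len(spec$n_chromosomes), function(ch) {
        pos <- matrix(NA_real_, n_frames, 3)
        pos[1, ] <- pos0[ch, ]
        arrived <- FALSE
        for (f in 2:n_frames) {
          t0_min <- t_s[f - 1] / 60
          x <- pos[f - 1, ]
          in_phase2 <- !is.na(switch_t[ch]) && t0_min >= switch_t[ch]
          if (arrived) {
            pos[f, ] <- x
          } else if (in_phase2) {
            to_p <- p - x
            d <- sqrt(sum(to_p^2))
            step <- speed[ch] * dt_s / 60
            if (d - step <= 2) {
              pos[f, ] <- p - to_p / d * 2
              arrived <- TRUE
            } else {
              pos[f, ] <- x + to_p / d * step +
                stats::rnorm(3, 0, spec$phase2_jitter_um / sqrt(3))
            }
          } else {
            adv <- if (spec$condition == "control" && t0_min <= spec$t_m) {
              (p - x) / (spec$t_x - t0_min) * dt_s / 60
            } else {
              c(0, 0, 0)
            }
            pos[f, ] <- reflect_in_sphere(
              matrix(x + adv + stats::rnorm(3, 0, sd_axis), 1, 3),
              geometry$nucleus_center, geometry$nucleus_radius - 0.8)[1, ]
          }
        }
        pos
      })

      list(
        traj = tibble::tibble(
          oocyte = oo,
          chromosome = rep(seq_len(spec$n_chromosomes), each = n_frames),
          t_s = rep(t_s, times = spec$n_chromosomes),
          x_um = unlist(purrr::map(tracks, ~ .x[, 1])),
          y_um = unlist(purrr::map(tracks, ~ .x[, 2])),
          z_um = unlist(purrr::map(tracks, ~ .x[, 3]))
        ),
        truth = tibble::tibble(
          oocyte = oo,
          chromosome = seq_len(spec$n_chromosomes),
          initial_distance_um = d0,
          switch_time_min = switch_t,
          speed_um_min = speed
        )
      )
    })
    structure(list(
      trajectories = purrr::map_dfr(out, "traj"),
      truth = purrr::map_dfr(out, "truth"),
      spec = spec, geometry = geometry
    ), class = "synthetic_trajectories")
  })
}

# Normalized-intensity template: 1 before onset, linear rise to the peak
# amplitude, linear fall back to 1 at the return time, 1 afterwards.
intensity_template <- function(t_min, onset, peak, ret, amplitude) {
  y <- rep(1, length(t_min))
  rise <- t_min >= onset & t_min < peak
  fall <- t_min >= peak & t_min < ret
  y[rise] <- 1 + (amplitude - 1) * (t_min[rise] - onset) / (peak - onset)
  y[fall] <- amplitude - (amplitude - 1) * (t_min[fall] - peak) /
    (ret - peak)
  y
}

#' Generate synthetic patch-intensity traces
#'
#' Per chromosome: a normalized-shape template (flat at 1 before NEBD,
#' linear rise from the assembly onset to a random peak amplitude, linear
#' fall back to background at the return time), scaled by a per-chromosome
#' raw background level, with multiplicative Gaussian noise; sampled every
#' `frame_interval_s` from 2 min before NEBD.
#'
#' @param spec A [synthetic_spec()].
#' @param n_traces Number of traces (default `n_oocytes * n_chromosomes`
#'   collapsed into a single `chromosome` index).
#' @param pre_nebd_min Minutes of pre-NEBD baseline (default 2).
#' @return List of class `synthetic_traces`: `traces` (tibble `chromosome`,
#'   `t_s`, `t_min`, `raw`) and `truth` (tibble `chromosome`, `onset_min`,
#'   `peak_min`, `return_min`, `amplitude`, `background`).
#' @export
make_intensity_traces <- function(spec,
                                  n_traces = spec$n_oocytes *
                                    spec$n_chromosomes,
                                  pre_nebd_min = 2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t_min <- seq(-pre_nebd_min, spec$duration_min,
               by = spec$frame_interval_s / 60)
  withr::with_seed(spec$seed + 1L, {
    amp <- stats::runif(n_traces, spec$amplitude_range[1],
                        spec$amplitude_range[2])
    bg <- stats::runif(n_traces, 50, 500)
    traces <- purrr::map_dfr(seq_len(n_traces), function(i) {
      y <- intensity_template(t_min, spec$patch_onset_min,
                              spec$patch_peak_min, spec$patch_return_min,
                              amp[i])
      noise <- if (spec$intensity_noise_sd > 0) {
        stats::rnorm(length(t_min), 0, spec$intensity_noise_sd)
      } else 0
      tibble::tibble(chromosome = i, t_s = t_min * 60, t_min = t_min,
                     raw = bg[i] * y * (1 + noise))
    })
    structure(list(
      traces = traces,
      truth = tibble::tibble(
        chromosome = seq_len(n_traces),
        onset_min = spec$patch_onset_min,
        peak_min = spec$patch_peak_min,
        return_min = spec$patch_return_min,
        amplitude = amp, background = bg
      ),
      spec = spec
    ), class = "synthetic_traces")
  })
}

#' Render a synthetic two-channel 4D image stack
#'
#' Renders chromosomes as 3D Gaussian blobs moving along synthetic
#' trajectories (channel 1) and patches as Gaussian shells around each
#' chromosome whose integrated intensity follows the trace kinetics
#' (channel 2), over a constant background, with optional Poisson camera
#' noise. Ground-truth trajectories and per-frame integrated patch
#' intensities are returned alongside.
#'
#' @param spec A [synthetic_spec()] (its oocyte/chromosome counts are
#'   ignored; `n_chromosomes` chromosomes of one oocyte are rendered).
#' @param dims Voxel dimensions `c(nx, ny, nz)` of each frame.
#' @param voxel_size Voxel edge length, µm.
#' @param n_chromosomes Chromosomes rendered (default 3).
#' @param n_frames Number of frames (default 40; frames are
#'   `frame_interval_s` apart starting 2 min before NEBD).
#' @param frame_interval_s Stack frame interval in seconds (default 15,
#'   coarser than the 3-s trace raster so the default 40 frames span the
#'   full patch assembly/disassembly cycle: -2 to +7.75 min).
#' @param blob_sigma_um Gaussian sigma of the chromosome blob (default 0.6).
#' @param shell_radius_um,shell_sigma_um Patch shell geometry (defaults 1.0
#'   and 0.5).
#' @param background Constant per-voxel background level (default 10).
#' @param poisson_noise Add Poisson noise to both channels (default TRUE).
#' @return List of class `synthetic_stack`: `chromosomes` and `patches`
#'   (4D arrays x,y,z,frame), `frame_times_s`, `trajectories` (tibble, in
#'   stack coordinates), `truth` (per chromosome per frame integrated
#'   patch intensity above background), `voxel_size`.
#' @export
make_image_stack <- function(spec, dims = c(48, 48, 48), voxel_size = 1,
                             n_chromosomes = 3, n_frames = 40,
                             frame_interval_s = 15,
                             blob_sigma_um = 0.6, shell_radius_um = 1.0,
                             shell_sigma_um = 0.5, background = 10,
                             poisson_noise = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  extent <- dims * voxel_size
  center <- extent / 2
  # a reduced nuclear sphere fitting the field of view
  radius <- min(extent) / 2 - 4
  geom <- oocyte_geometry(nucleus_radius = radius, nucleus_center = center)
  spec2 <- spec
  spec2$n_oocytes <- 1L
  spec2$n_chromosomes <- as.integer(n_chromosomes)
  frame_times_s <- seq(-2 * 60, by = frame_interval_s,
                       length.out = n_frames)
  # simulate on the trace raster out to the last (post-NEBD) stack frame
  spec2$duration_min <- max(max(frame_times_s) / 60,
                            2 * spec$frame_interval_s / 60)

  withr::with_seed(spec$seed + 2L, {
    trj <- make_trajectories(spec2, geom)
    trc <- make_intensity_traces(spec2, n_traces = n_chromosomes,
                                 pre_nebd_min = 2)
    # trajectory clock starts at NEBD; hold the initial position before it
    ax <- (seq_len(dims[1]) - 0.5) * voxel_size
    ay <- (seq_len(dims[2]) - 0.5) * voxel_size
    az <- (seq_len(dims[3]) - 0.5) * voxel_size
    chrom_stack <- array(background, c(dims, n_frames))
    patch_stack <- array(background, c(dims, n_frames))
    truth <- list()
    clipped <- FALSE

    render_blob <- function(arr, pos, sigma, mass, shell = 0) {
      gx <- exp(-((ax - pos[1])^2) / (2 * sigma^2))
      gy <- exp(-((ay - pos[2])^2) / (2 * sigma^2))
      gz <- exp(-((az - pos[3])^2) / (2 * sigma^2))
      if (shell > 0) {
        dx2 <- outer(outer((ax - pos[1])^2, (ay - pos[2])^2, `+`),
                     (az - pos[3])^2, `+`)
        blob <- exp(-(sqrt(dx2) - shell)^2 / (2 * sigma^2))
      } else {
        blob <- outer(outer(gx, gy), gz)
      }
      s <- sum(blob)
      if (s <= 0) return(arr)
      arr + blob * (mass / s)
    }

    for (f in seq_len(n_frames)) {
      t_s_f <- frame_times_s[f]
      for (ch in seq_len(n_chromosomes)) {
        tr <- trj$trajectories[trj$trajectories$chromosome == ch, ]
        row <- tr[which.min(abs(tr$t_s - max(t_s_f, 0))), ]
        pos <- c(row$x_um, row$y_um, row$z_um)
        if (any(pos < 0 | pos > extent)) {
          clipped <- TRUE
          pos <- pmin(pmax(pos, 0), extent)
        }
        chrom_stack[, , , f] <- render_blob(chrom_stack[, , , f], pos,
                                            blob_sigma_um, 5000)
        # patch mass chosen so that (2.5-um-ROI sum)/(bg * n_voxels)
        # reproduces the trace's normalized value
        tr_row <- trc$traces[trc$traces$chromosome == ch, ]
        irow <- tr_row[which.min(abs(tr_row$t_s - t_s_f)), ]
        mass <- (irow$raw / trc$truth$background[ch] - 1) * background *
          sphere_voxel_count(2.5, voxel_size)
        if (mass > 0) {
          patch_stack[, , , f] <- render_blob(patch_stack[, , , f], pos,
                                              shell_sigma_um, mass,
                                              shell = shell_radius_um)
        }
        truth[[length(truth) + 1]] <- tibble::tibble(
          chromosome = ch, frame = f, t_s = t_s_f,
          x_um = pos[1], y_um = pos[2], z_um = pos[3],
          patch_mass = max(mass, 0),
          normalized = irow$raw / trc$truth$background[ch]
        )
      }
    }
    if (clipped) warning("some trajectory points fell outside the stack ",
                         "and were clipped", call. = FALSE)
    if (poisson_noise) {
      chrom_stack[] <- stats::rpois(length(chrom_stack), chrom_stack)
      patch_stack[] <- stats::rpois(length(patch_stack), patch_stack)
    }
    structure(list(
      chromosomes = chrom_stack, patches = patch_stack,
      frame_times_s = frame_times_s,
      trajectories = trj$trajectories,
      truth = dplyr::bind_rows(truth),
      voxel_size = voxel_size, background = background
    ), class = "synthetic_stack")
  })
}

# number of voxel centers inside a sphere of the given radius (far from
# any boundary), for calibrating rendered patch mass against ROI sums
sphere_voxel_count <- function(radius, voxel_size) {
  m <- ceiling(radius / voxel_size) + 1
  g <- (seq(-m, m) + 0.5) * voxel_size
  sum(outer(outer(g^2, g^2, `+`), g^2, `+`) <= radius^2)
}
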