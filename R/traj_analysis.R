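#' Distance to the animal pole along trajectories
#'
#' Adds the Euclidean chromosome-AP distance per frame to a trajectory
#' table.
#'
#' @param data Trajectory tibble with columns `t_s`, `x_um`, `y_um`, `z_um`
#'   (and optionally `oocyte`, `chromosome`).
#' @param p AP point, 3-vector in µm.
#' @return `data` with an added `distance_um` column.
#' @export
distance_to_ap <- function(data, p) {
  check_trajectory_cols(data)
  if (!is.numeric(p) || length(p) != 3) {
    stop("`p` must be a numeric 3-vector", call. = FALSE)
  }
  dplyr::mutate(
    data,
    distance_um = sqrt((.data$x_um - p[1])^2 + (.data$y_um - p[2])^2 +
                         (.data$z_um - p[3])^2)
  )
}

check_trajectory_cols <- function(data) {
  need <- c("t_s", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("trajectory table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Default thresholds for capture-event detection
#'
#' A step qualifies when it is fast (instantaneous speed >=
#' `fast_speed` µm/min), unidirectional (turning angle between consecutive
#' displacements <= `max_angle` degrees) and poleward (radial velocity
#' toward the AP negative). A capture event is the earliest frame starting
#' either (rule A) at least `min_run` consecutive qualifying steps, or
#' (rule B) at least `turn_run` qualifying steps coinciding with a reversal
#' of the smoothed overall direction of motion (sign change of the
#' `smooth_window`-frame moving-average radial velocity).
#'
#' `fast_speed` = 5 µm/min sits between the advective regime (<= ~4.7
#' µm/min for any starting position in a 70-µm nucleus with t_x = 15 min)
#' and the ~9.2 µm/min microtubule transport regime.
#'
#' @param fast_speed Fast-step speed threshold, µm/min.
#' @param max_angle Maximum turning angle, degrees.
#' @param min_run Steps required by rule A.
#' @param turn_run Steps required by rule B.
#' @param smooth_window Frames in the moving average defining the overall
#'   direction.
#' @param sustain_window Frames over which the candidate must sustain a
#'   mean poleward radial velocity below `-fast_speed` (see Details).
#' @param sustain_ratio Required ratio of the sustained window speed to the
#'   track's own pre-candidate baseline speed.
#' @return A named list of thresholds.
#' @export
detection_thresholds <- function(fast_speed = 5, max_angle = 60,
                                 min_run = 4, turn_run = 2,
                                 smooth_window = 5, sustain_window = 20,
                                 sustain_ratio = 1.5) {
  list(fast_speed = fast_speed, max_angle = max_angle,
       min_run = as.integer(min_run), turn_run = as.integer(turn_run),
       smooth_window = as.integer(smooth_window),
       sustain_window = as.integer(sustain_window),
       sustain_ratio = sustain_ratio)
}

moving_average <- function(x, w) {
  if (w <= 1 || length(x) < w) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) -> sm
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Detector core on one track. Returns NULL or a one-row tibble.
detect_one_track <- function(t_s, pos, p, thresholds) {
  n <- nrow(pos)
  if (n < 6) {
    warning("trajectory shorter than the detection window; no event",
            call. = FALSE)
    return(NULL)
  }
  dt_min <- diff(t_s) / 60
  disp <- diff(pos)
  step_len <- sqrt(rowSums(disp^2))
  speed <- step_len / dt_min # um/min, step i spans frame i -> i+1
  dist <- sqrt(rowSums(sweep(pos, 2, p)^2))
  rv <- diff(dist) / dt_min

  # turning angle between step i-1 and step i (degrees); first undefined
  dot <- rowSums(disp[-1, , drop = FALSE] * disp[-nrow(disp), , drop = FALSE])
  denom <- step_len[-1] * step_len[-length(step_len)]
  cosang <- ifelse(denom > 0, pmin(1, pmax(-1, dot / denom)), -1)
  angle <- c(Inf, acos(cosang) * 180 / pi)

  qual <- speed >= thresholds$fast_speed &
    angle <= thresholds$max_angle & rv < 0

  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  qruns <- which(runs$values)

  # The first step of a directed run changes direction relative to the
  # preceding slow phase, so its own turning angle (to the *previous*
  # step) may fail even though it is unidirectional with the rest of the
  # run (the next step's angle already links it to the run). Prepend such
  # a step so runs start at the true transition.
  ext <- integer(length(runs$lengths))
  for (q in qruns) {
    s <- starts[q]
    if (s > 1 && !qual[s - 1] && speed[s - 1] >= thresholds$fast_speed &&
        rv[s - 1] < 0) {
      starts[q] <- s - 1L
      ext[q] <- 1L
    }
  }
  runs$lengths[qruns] <- runs$lengths[qruns] + ext[qruns]

  # Both rules additionally require *sustained fast* poleward motion after
  # the candidate (mean radial velocity over the following window below
  # -fast_speed). Single fast-looking runs arise by chance on diffusive
  # tracks (localization-scale noise) and on fast advective tracks (drift
  # up to ~4.7 um/min plus noise), but neither sustains a window-mean
  # radial velocity beyond the fast threshold, while transport does.
  # The window (default 20 frames = 1 min) is long enough that the fastest
  # advective drift (~4.7 um/min) plus genuine Brownian radial fluctuation
  # of the window mean (sd ~0.6 um/min over 1 min at the default diffusivity)
  # rarely reaches -fast_speed, while transport at ~9 um/min always does.
  sw <- if (is.null(thresholds$sustain_window)) 20L else
    thresholds$sustain_window
  # lag-5 displacement speed per step (suppresses frame-to-frame noise)
  lag5 <- 5L
  sp_lag <- rep(NA_real_, length(rv))
  i_lag <- seq_len(max(0, n - lag5))
  if (length(i_lag)) {
    sp_lag[i_lag] <- sqrt(rowSums((pos[i_lag + lag5, , drop = FALSE] -
                                     pos[i_lag, , drop = FALSE])^2)) /
      ((t_s[i_lag + lag5] - t_s[i_lag]) / 60)
  }
  # The window's speed must also clearly exceed the track's own baseline
  # (median lag speed over the 2 min before the candidate): transport is
  # at least ~1.5x faster than advection from any starting position,
  # whereas an advective stretch moves at ~1x its own baseline however
  # close to the absolute threshold it runs.
  ratio <- if (is.null(thresholds$sustain_ratio)) 1.5 else
    thresholds$sustain_ratio
  sustained <- function(i) {
    win <- i:min(length(rv), i + sw - 1L)
    sp_win <- sp_lag[win]
    sp_win <- sp_win[!is.na(sp_win)]
    base_win <- sp_lag[seq_len(max(0, i - 1))]
    base_win <- base_win[max(1, length(base_win) - 39L):length(base_win)]
    base_win <- base_win[!is.na(base_win)]
    floor_sp <- if (length(base_win) >= 5) {
      max(thresholds$fast_speed, ratio * stats::median(base_win))
    } else thresholds$fast_speed
    sp_ok <- if (length(sp_win)) mean(sp_win) >= floor_sp else TRUE
    mean(rv[win]) < -thresholds$fast_speed && sp_ok
  }

  # rule A: >= min_run consecutive qualifying steps
  cand_a <- starts[qruns[runs$lengths[qruns] >= thresholds$min_run]]
  cand_a <- cand_a[vapply(cand_a, sustained, logical(1))]

  # rule B: >= turn_run qualifying steps at a reversal of the smoothed
  # overall (radial) direction of motion
  smooth_rv <- moving_average(rv, thresholds$smooth_window)
  reversal <- c(FALSE, smooth_rv[-1] < 0 & smooth_rv[-length(smooth_rv)] >= 0)
  cand_b <- starts[qruns[runs$lengths[qruns] >= thresholds$turn_run]]
  cand_b <- cand_b[vapply(cand_b, function(i) {
    any(reversal[max(1, i - 2):min(length(reversal), i + 2)])
  }, logical(1))]
  cand_b <- cand_b[vapply(cand_b, sustained, logical(1))]

  if (!length(cand_a) && !length(cand_b)) return(NULL)
  best_a <- if (length(cand_a)) min(cand_a) else Inf
  best_b <- if (length(cand_b)) min(cand_b) else Inf
  i <- min(best_a, best_b)
  rule <- if (best_a <= best_b) "four-step" else "two-step+turn"
  tibble::tibble(
    capture_time_min = t_s[i] / 60,
    rule = rule,
    event_frame = as.integer(i)
  )
}

#' Detect capture events on chromosome trajectories
#'
#' Segments each track into the slow advective/diffusive phase and the fast
#' directed microtubule-transport phase; the transition is the capture
#' event. See [detection_thresholds()] for the step-qualification rules.
#' Per-phase speeds are estimated with [phase_speeds()].
#'
#' @param data Trajectory tibble (`t_s`, `x_um`, `y_um`, `z_um`, plus
#'   optional `oocyte`/`chromosome` identifying tracks).
#' @param p AP point, 3-vector in µm.
#' @param thresholds From [detection_thresholds()].
#' @return Tibble with one row per detected event: track ids,
#'   `capture_time_min`, `rule`, `pre_speed_um_min`, `post_speed_um_min`.
#'   Tracks without a detected event are omitted.
#' @export
detect_capture_events <- function(data, p,
                                  thresholds = detection_thresholds()) {
  check_trajectory_cols(data)
  ids <- intersect(c("oocyte", "chromosome"), names(data))
  grouped <- if (length(ids)) dplyr::group_by(data, dplyr::across(
    dplyr::all_of(ids))) else dplyr::group_by(data)
  out <- dplyr::group_modify(grouped, function(df, key) {
    df <- dplyr::arrange(df, .data$t_s)
    pos <- cbind(df$x_um, df$y_um, df$z_um)
    ev <- detect_one_track(df$t_s, pos, p, thresholds)
    if (is.null(ev)) return(tibble::tibble())
    sp <- phase_speeds(df, ev$capture_time_min, p)
    ev$pre_speed_um_min <- sp$pre_speed_um_min
    ev$post_speed_um_min <- sp$post_speed_um_min
    ev
  })
  dplyr::ungroup(out)
}

#' Pre- and post-capture phase speeds of one track
#'
#' Mean speed before and after the event, from finite differences over
#' `lag` frames (15 s by default), which suppresses the upward bias that
#' localization noise adds to single-frame instantaneous speeds. Frames in
#' the arrival plateau (`lag`-frame displacement speed < `plateau_speed`
#' µm/min while within `plateau_distance` µm of the AP) are excluded from
#' the post-event estimate. The plateau speed is judged on the lag-frame
#' displacement for the same reason the phase speeds are: frame-to-frame
#' jitter on a parked chromosome mimics several µm/min of instantaneous
#' speed. `plateau_distance` covers the arrival region: chromosomes park
#' about `arrival_radius` from a centrosome, which itself sits a few µm
#' from the AP.
#'
#' @param data One track: tibble with `t_s`, `x_um`, `y_um`, `z_um`.
#' @param event_time_min Event time in minutes.
#' @param p AP point (µm), used for plateau trimming.
#' @param lag Frames spanned by each finite difference.
#' @param plateau_speed,plateau_distance Arrival-plateau trimming rule.
#' @return One-row tibble: `pre_speed_um_min`, `post_speed_um_min` (NA when
#'   a side has no usable frames).
#' @export
phase_speeds <- function(data, event_time_min, p, lag = 5,
                         plateau_speed = 1, plateau_distance = 8) {
  check_trajectory_cols(data)
  df <- dplyr::arrange(data, .data$t_s)
  pos <- cbind(df$x_um, df$y_um, df$z_um)
  t_min <- df$t_s / 60
  n <- nrow(pos)
  dist <- sqrt(rowSums(sweep(pos, 2, p)^2))
  # centered lag-frame displacement speed per frame (jitter-robust)
  lo <- pmax(seq_len(n) - ceiling(lag / 2), 1L)
  hi <- pmin(lo + lag, n)
  lo <- pmax(hi - lag, 1L)
  disp_lag <- sqrt(rowSums((pos[hi, , drop = FALSE] -
                              pos[lo, , drop = FALSE])^2))
  speed_lag <- disp_lag / (t_min[hi] - t_min[lo])
  plateau <- speed_lag < plateau_speed & dist < plateau_distance
  plateau[is.na(plateau)] <- TRUE

  lag_speed <- function(keep) {
    idx <- which(keep)
    if (length(idx) <= lag) return(NA_real_)
    # contiguous windows of `lag` frames fully inside the kept set
    i0 <- idx[seq_len(length(idx) - lag)]
    ok <- (idx[seq_len(length(idx) - lag) + lag] - i0) == lag
    i0 <- i0[ok]
    if (!length(i0)) return(NA_real_)
    d <- sqrt(rowSums((pos[i0 + lag, , drop = FALSE] -
                         pos[i0, , drop = FALSE])^2))
    mean(d / (t_min[i0 + lag] - t_min[i0]))
  }

  pre <- lag_speed(t_min < event_time_min)
  post <- lag_speed(t_min >= event_time_min & !plateau)
  tibble::tibble(pre_speed_um_min = pre, post_speed_um_min = post)
}

#' Summary statistics of capture events
#'
#' @param events Either a numeric vector of capture times (min) or an event
#'   tibble with a `capture_time_min` column (`NA`s dropped).
#' @param bin_width Histogram bin width in minutes (default 0.5).
#' @param range Histogram range in minutes (default `c(0, 20)`).
#' @return List of class `capture_stats`: `summary` (one-row tibble with
#'   `n`, `mean_min`, `sd_min`, `modal_bin_start_min`) and `histogram`
#'   (tibble `bin_start_min`, `bin_mid_min`, `count`). Empty input gives an
#'   empty summary, not an error.
#' @export
capture_statistics <- function(events, bin_width = 0.5, range = c(0, 20)) {
  times <- if (is.data.frame(events)) events$capture_time_min else events
  times <- times[!is.na(times)]
  breaks <- seq(range[1], range[2], by = bin_width)
  if (max(times, -Inf) > range[2]) {
    breaks <- c(breaks, seq(range[2] + bin_width,
                            max(times) + bin_width, by = bin_width))
  }
  counts <- if (length(times)) {
    graphics::hist(times, breaks = breaks, plot = FALSE,
                   right = FALSE)$counts
  } else {
    integer(length(breaks) - 1)
  }
  hist_tbl <- tibble::tibble(
    bin_start_min = breaks[-length(breaks)],
    bin_mid_min = breaks[-length(breaks)] + bin_width / 2,
    count = counts
  )
  summary <- tibble::tibble(
    n = length(times),
    mean_min = if (length(times)) mean(times) else NA_real_,
    sd_min = if (length(times) > 1) stats::sd(times) else NA_real_,
    modal_bin_start_min = if (length(times)) {
      hist_tbl$bin_start_min[which.max(hist_tbl$count)]
    } else NA_real_
  )
  structure(list(summary = summary, histogram = hist_tbl),
            class = "capture_stats")
}

#' @export
print.capture_stats <- function(x, ...) {
  cat("<capture_stats>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.capture_stats <- function(x, ...) x$histogram

#' @export
glance.capture_stats <- function(x, ...) x$summary
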