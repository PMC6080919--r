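#' Total intensity in a spherical ROI
#'
#' Sums the voxels of one 3D frame whose centers lie within `radius` of
#' `center` (the 2.5-µm-radius sphere used for patch quantification by
#' default). Voxels of the sphere falling outside the image are excluded;
#' the covered fraction of the sphere is reported alongside.
#'
#' @param frame 3D numeric array (x, y, z).
#' @param center Sphere center in µm, relative to the corner of the first
#'   voxel (voxel `[i,j,k]` has its center at `(i-0.5, j-0.5, k-0.5) *
#'   voxel_size`).
#' @param radius Sphere radius in µm (default 2.5); must exceed the largest
#'   voxel dimension.
#' @param voxel_size Voxel edge length(s) in µm; scalar or length-3.
#' @return List with `total` (sum of in-sphere voxel values), `n_voxels`,
#'   and `covered_fraction` (in-bounds share of the sphere's voxels).
#' @export
spherical_intensity <- function(frame, center, radius = 2.5,
                                voxel_size = 1) {
  if (length(dim(frame)) != 3) stop("`frame` must be a 3D array",
                                    call. = FALSE)
  vs <- rep_len(as.numeric(voxel_size), 3)
  if (radius <= max(vs)) {
    stop("`radius` must exceed the largest voxel dimension", call. = FALSE)
  }
  dims <- dim(frame)
  extent <- dims * vs
  if (any(center < 0 | center > extent)) {
    stop("sphere center lies outside the image bounds", call. = FALSE)
  }
  # candidate voxel index ranges (1-based), clipped to the image
  lo <- pmax(1L, floor((center - radius) / vs - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center + radius) / vs + 0.5))
  lo_u <- floor((center - radius) / vs - 0.5) + 1L # unclipped
  hi_u <- ceiling((center + radius) / vs + 0.5)

  in_sphere_count <- function(l, h) {
    ix <- seq(l[1], h[1]); iy <- seq(l[2], h[2]); iz <- seq(l[3], h[3])
    cxv <- (ix - 0.5) * vs[1] - center[1]
    cyv <- (iy - 0.5) * vs[2] - center[2]
    czv <- (iz - 0.5) * vs[3] - center[3]
    d2 <- outer(outer(cxv^2, cyv^2, `+`), czv^2, `+`)
    d2 <= radius^2
  }

  mask <- in_sphere_count(lo, hi)
  n_in <- sum(mask)
  total_sphere <- if (all(lo == lo_u) && all(hi == hi_u)) {
    n_in
  } else {
    sum(in_sphere_count(lo_u, hi_u))
  }
  if (total_sphere == 0 || n_in == 0) {
    stop("spherical ROI is entirely outside the image", call. = FALSE)
  }
  block <- frame[seq(lo[1], hi[1]), seq(lo[2], hi[2]), seq(lo[3], hi[3]),
                 drop = FALSE]
  list(total = sum(block[mask]), n_voxels = n_in,
       covered_fraction = n_in / total_sphere)
}

#' Quantify patch intensity along trajectories in a 4D stack
#'
#' Runs [spherical_intensity()] at every trajectory point of every
#' chromosome.
#'
#' @param stack 4D numeric array (x, y, z, frame).
#' @param trajectories Tibble with `chromosome`, `t_s`, `x_um`, `y_um`,
#'   `z_um`; one row per frame per chromosome, frames in `t_s` order
#'   matching the stack's 4th dimension.
#' @param frame_times_s Acquisition times (s) of the stack frames.
#' @param radius,voxel_size As in [spherical_intensity()].
#' @return Tibble: `chromosome`, `t_s`, `t_min`, `raw`,
#'   `covered_fraction`.
#' @export
quantify_stack <- function(stack, trajectories, frame_times_s,
                           radius = 2.5, voxel_size = 1) {
  if (length(dim(stack)) != 4) stop("`stack` must be a 4D array",
                                    call. = FALSE)
  check_trajectory_cols(trajectories)
  purrr::map_dfr(sort(unique(trajectories$chromosome)), function(ch) {
    tr <- dplyr::arrange(
      dplyr::filter(trajectories, .data$chromosome == ch), .data$t_s)
    purrr::map_dfr(seq_along(frame_times_s), function(f) {
      row <- tr[which.min(abs(tr$t_s - frame_times_s[f])), ]
      res <- tryCatch(
        spherical_intensity(stack[, , , f],
                            c(row$x_um, row$y_um, row$z_um),
                            radius, voxel_size),
        error = function(e) {
          stop(sprintf("chromosome %s, frame %d: %s", ch, f,
                       conditionMessage(e)), call. = FALSE)
        })
      tibble::tibble(chromosome = ch, t_s = frame_times_s[f],
                     t_min = frame_times_s[f] / 60, raw = res$total,
                     covered_fraction = res$covered_fraction)
    })
  })
}

#' Normalize an intensity trace to the pre-NEBD background
#'
#' Background is the mean raw intensity over samples strictly before
#' `nebd_time_min`; the normalized trace is raw / background, so it sits at
#' ~1 before NEBD by construction.
#'
#' @param data Tibble with `t_min` and `raw` (and optional id columns,
#'   which are preserved; normalization is per chromosome when a
#'   `chromosome` column is present).
#' @param nebd_time_min NEBD time in minutes on the trace's clock
#'   (default 0).
#' @param background Optional explicit background value, required when no
#'   pre-NEBD samples exist.
#' @return Input tibble with `background` and `normalized` columns.
#' @export
normalize_trace <- function(data, nebd_time_min = 0, background = NULL) {
  if (!all(c("t_min", "raw") %in% names(data))) {
    stop("trace needs columns `t_min` and `raw`", call. = FALSE)
  }
  norm_one <- function(df) {
    pre <- df$raw[df$t_min < nebd_time_min]
    bg <- if (!is.null(background)) {
      background
    } else {
      if (length(pre) < 2) {
        stop(paste("fewer than 2 pre-NEBD samples; supply an explicit",
                   "`background`"), call. = FALSE)
      }
      mean(pre)
    }
    if (bg <= 0) stop("background must be positive", call. = FALSE)
    dplyr::mutate(df, background = bg, normalized = .data$raw / bg)
  }
  if ("chromosome" %in% names(data)) {
    dplyr::ungroup(dplyr::group_modify(
      dplyr::group_by(data, .data$chromosome),
      function(df, key) norm_one(df)))
  } else {
    norm_one(data)
  }
}

#' Assembly, peak and disassembly timing of a patch-intensity trace
#'
#' A patch is detected when the normalized trace exceeds `1 + epsilon` for
#' at least `persistence` consecutive samples. Peak time is the argmax of a
#' `smooth_window`-sample moving average. Assembly onset and disassembly
#' (background return) are the times the trace crosses the background level
#' 1, estimated by a linear fit of the full supra-threshold rising /
#' falling flank (onset-to-peak and peak-to-end) solved at 1: a plain
#' `1 + epsilon` threshold crossing would systematically date the return
#' before the true background return by an amplitude-dependent margin, and
#' a fit restricted to the few samples nearest the threshold is dominated
#' by noise at typical 3-s sampling.
#'
#' @param data One normalized trace: tibble with `t_min` and `normalized`
#'   (from [normalize_trace()]).
#' @param epsilon Detection margin above background (default 0.2).
#' @param persistence Consecutive supra-threshold samples required
#'   (default 3).
#' @param smooth_window Samples in the peak-finding moving average
#'   (default 5).
#' @return One-row tibble: `onset_min`, `peak_min`, `disassembly_min`; all
#'   `NA` when no patch is detected.
#' @export
patch_timing <- function(data, epsilon = 0.2, persistence = 3,
                         smooth_window = 5) {
  if (!all(c("t_min", "normalized") %in% names(data))) {
    stop("trace needs columns `t_min` and `normalized`", call. = FALSE)
  }
  df <- dplyr::arrange(data, .data$t_min)
  t <- df$t_min
  y <- df$normalized
  thr <- 1 + epsilon
  above <- y > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= persistence)
  if (!length(keep)) {
    return(tibble::tibble(onset_min = NA_real_, peak_min = NA_real_,
                          disassembly_min = NA_real_))
  }
  # patch segment: from the first sustained excursion to the last
  i0 <- starts[keep[1]]
  i1 <- ends[keep[length(keep)]]

  sm <- moving_average(y, smooth_window)
  seg <- i0:i1
  peak_idx <- seg[which.max(sm[seg])]
  peak_min <- t[peak_idx]

  cross_background <- function(idx, side) {
    # linear fit of the segment flank, solved at normalized = 1
    idx <- idx[idx >= 1 & idx <= length(t)]
    if (length(idx) < 2) return(t[idx[1]])
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    if (!is.finite(b) || b == 0) return(t[idx[1]])
    tc <- (1 - a) / b
    lim <- range(t[idx])
    # crossing must extrapolate outward from the flank, not into it
    if (side == "onset") min(tc, lim[1]) else max(tc, lim[2])
  }
  onset_min <- cross_background(i0:peak_idx, "onset")
  disassembly_min <- cross_background(peak_idx:i1, "disassembly")
  tibble::tibble(onset_min = onset_min, peak_min = peak_min,
                 disassembly_min = disassembly_min)
}

#' Patch timings for a table of traces
#'
#' @param data Normalized trace tibble with a `chromosome` column.
#' @param ... Passed to [patch_timing()].
#' @return Tibble with one row per chromosome.
#' @export
patch_timings <- function(data, ...) {
  dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(data, .data$chromosome),
    function(df, key) patch_timing(df, ...)))
}

#' Per-chromosome lag between capture and patch disassembly
#'
#' @param events Capture-event tibble with `chromosome` and
#'   `capture_time_min`.
#' @param timings Patch-timing tibble with `chromosome` and
#'   `disassembly_min`.
#' @return List of class `capture_disassembly`: `lags` (per-chromosome
#'   `lag_min` = capture - disassembly), `summary` (mean/SD), and
#'   `unmatched` (ids present on only one side; reported, not fatal).
#' @export
correlate_capture_with_disassembly <- function(events, timings) {
  ev <- dplyr::select(events, "chromosome", "capture_time_min")
  tm <- dplyr::select(timings, "chromosome", "disassembly_min")
  joined <- dplyr::inner_join(ev, tm, by = "chromosome")
  unmatched <- union(
    setdiff(ev$chromosome, tm$chromosome),
    setdiff(tm$chromosome, ev$chromosome)
  )
  if (length(unmatched)) {
    warning("unmatched chromosome ids: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  lags <- dplyr::mutate(
    joined, lag_min = .data$capture_time_min - .data$disassembly_min)
  ok <- lags$lag_min[!is.na(lags$lag_min)]
  structure(list(
    lags = lags,
    summary = tibble::tibble(
      n = length(ok),
      mean_lag_min = if (length(ok)) mean(ok) else NA_real_,
      sd_lag_min = if (length(ok) > 1) stats::sd(ok) else NA_real_
    ),
    unmatched = unmatched
  ), class = "capture_disassembly")
}

#' @export
print.capture_disassembly <- function(x, ...) {
  cat("<capture_disassembly>\n")
  print(x$summary)
  invisible(x)
}
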