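geom <- oocyte_geometry()

test_that("synthetic_spec fills condition defaults and validates", {
  sc <- synthetic_spec("control")
  sl <- synthetic_spec("latrunculin")
  expect_equal(sc$switch_mean, 9.21)
  expect_equal(sc$switch_sd, 2.36)
  expect_equal(sl$switch_mean, 6.16)
  expect_equal(sl$switch_sd, 3.92)
  expect_equal(sc$speed_mean, 9.22)
  expect_equal(sc$speed_sd, 2.86)
  # patch kinetics: onset 1.5 both; peak/return 5/8 control, 2.5/4 latr
  expect_equal(c(sc$patch_onset_min, sc$patch_peak_min, sc$patch_return_min),
               c(1.5, 5, 8))
  expect_equal(c(sl$patch_onset_min, sl$patch_peak_min, sl$patch_return_min),
               c(1.5, 2.5, 4))
  expect_error(synthetic_spec(speed_sd = -1), ">= 0")
  expect_error(synthetic_spec(patch_peak_min = 1, patch_onset_min = 2),
               "onset < peak < return")
})

test_that("trajectory generation is seed-deterministic", {
  s1 <- make_trajectories(synthetic_spec(n_oocytes = 2, seed = 3L), geom)
  s2 <- make_trajectories(synthetic_spec(n_oocytes = 2, seed = 3L), geom)
  s3 <- make_trajectories(synthetic_spec(n_oocytes = 2, seed = 4L), geom)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$trajectories, s3$trajectories))
})

test_that("truth table is consistent with the rendered trajectories", {
  spec <- synthetic_spec(n_oocytes = 3, seed = 5L)
  out <- make_trajectories(spec, geom)
  tr <- out$trajectories
  truth <- out$truth
  expect_equal(nrow(truth), 3 * 22)
  expect_setequal(names(truth), c("oocyte", "chromosome",
                                  "initial_distance_um", "switch_time_min",
                                  "speed_um_min"))
  # control: every track switches to transport
  expect_true(all(!is.na(truth$switch_time_min)))
  expect_true(all(truth$speed_um_min > 0))
  # frame raster: 3-s frames over the full duration, per track
  n_fr <- spec$duration_min * 60 / spec$frame_interval_s + 1
  counts <- dplyr::count(tr, .data$oocyte, .data$chromosome)
  expect_true(all(counts$n == n_fr))
  # initial distance matches the first frame's distance to the AP
  first <- tr |>
    dplyr::group_by(.data$oocyte, .data$chromosome) |>
    dplyr::slice_min(.data$t_s, n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(d0 = sqrt((.data$x_um - geom$ap_point[1])^2 +
                              (.data$y_um - geom$ap_point[2])^2 +
                              (.data$z_um - geom$ap_point[3])^2))
  j <- dplyr::inner_join(first, truth, by = c("oocyte", "chromosome"))
  expect_equal(j$d0, j$initial_distance_um)
})

test_that("noiseless tracks follow advection then constant-speed transport", {
  spec <- synthetic_spec(n_oocytes = 1, seed = 6L, diffusion = 0,
                         phase2_jitter_um = 0)
  out <- make_trajectories(spec, geom)
  truth <- out$truth
  d_ap <- distance_to_ap(out$trajectories, geom$ap_point)
  for (ch in unique(truth$chromosome)) {
    ti <- truth[truth$chromosome == ch, ]
    d <- d_ap[d_ap$chromosome == ch, ]
    t_min <- d$t_s / 60
    pre <- t_min < ti$switch_time_min & t_min <= spec$t_m
    # phase 1: exact linear decay d(t) = d0 (t_x - t)/t_x
    expect_equal(d$distance_um[pre],
                 ti$initial_distance_um * (spec$t_x - t_min[pre]) /
                   spec$t_x,
                 tolerance = 1e-6)
    # phase 2: approach at the truth speed until parking at 2 um
    post <- t_min >= ti$switch_time_min & d$distance_um > 2 + 1e-6
    if (sum(post) > 3) {
      dd <- diff(d$distance_um[post])
      dt <- diff(t_min[post])
      expect_equal(-dd / dt, rep(ti$speed_um_min, length(dd)),
                   tolerance = 1e-6)
    }
    # parked exactly at the 2-um arrival radius at the end
    expect_equal(d$distance_um[length(t_min)], 2, tolerance = 1e-6)
  }
})

test_that("latrunculin condition loses tracks beyond the capture range", {
  spec <- synthetic_spec("latrunculin", n_oocytes = 6, seed = 8L)
  out <- make_trajectories(spec, geom)
  truth <- out$truth
  lost <- is.na(truth$switch_time_min)
  expect_gt(sum(lost), 0)
  expect_gt(sum(!lost), 0)
  # loss is exactly the initial-distance > capture-range rule
  expect_true(all(truth$initial_distance_um[lost] > spec$capture_range_um))
  expect_true(all(truth$initial_distance_um[!lost] <=
                    spec$capture_range_um))
})

test_that("switch-time and speed draws match the target distributions", {
  spec <- synthetic_spec(n_oocytes = 13, seed = 10L)
  truth <- make_trajectories(spec, geom)$truth
  # truncation bias is negligible at these means; 3 SE ~ 0.42 / 0.51
  expect_equal(mean(truth$switch_time_min), spec$switch_mean,
               tolerance = 0.45 / spec$switch_mean)
  expect_equal(mean(truth$speed_um_min), spec$speed_mean,
               tolerance = 0.55 / spec$speed_mean)
  expect_equal(stats::sd(truth$switch_time_min), spec$switch_sd,
               tolerance = 0.15)
  expect_true(all(truth$switch_time_min >= 0))
})

test_that("intensity template is piecewise linear with exact knots", {
  t <- c(-2, 0, 1.5, 3.25, 5, 6.5, 8, 12)
  y <- congressim:::intensity_template(t, onset = 1.5, peak = 5, ret = 8,
                                       amplitude = 4)
  expect_equal(y, c(1, 1, 1, (1 + 4) / 2, 4, (4 + 1) / 2, 1, 1))
})

test_that("intensity traces sit at background pre-onset and are seeded", {
  spec <- synthetic_spec(seed = 12L)
  tr1 <- make_intensity_traces(spec, n_traces = 20)
  tr2 <- make_intensity_traces(spec, n_traces = 20)
  expect_identical(tr1$traces, tr2$traces)
  expect_equal(nrow(tr1$truth), 20)
  expect_true(all(tr1$truth$background >= 50 & tr1$truth$background <= 500))
  expect_true(all(tr1$truth$amplitude >= spec$amplitude_range[1] &
                    tr1$truth$amplitude <= spec$amplitude_range[2]))
  # raw / background ~ 1 before onset (5% multiplicative noise)
  pre <- dplyr::inner_join(
    dplyr::filter(tr1$traces, .data$t_min < 1.5),
    dplyr::select(tr1$truth, "chromosome", "background"),
    by = "chromosome")
  expect_equal(mean(pre$raw / pre$background), 1, tolerance = 0.005)
  expect_lt(stats::sd(pre$raw / pre$background), 0.07)
  # traces start 2 min before NEBD for background estimation
  expect_lte(min(tr1$traces$t_min), -2 + 1e-9)
})

test_that("patch-timing truth is independent of amplitude and background", {
  spec <- synthetic_spec(seed = 13L)
  tr <- make_intensity_traces(spec, n_traces = 30)
  expect_true(all(tr$truth$onset_min == spec$patch_onset_min))
  expect_true(all(tr$truth$peak_min == spec$patch_peak_min))
  expect_true(all(tr$truth$return_min == spec$patch_return_min))
})

test_that("detector recovers switch times and speeds on a control cohort", {
  spec <- synthetic_spec(seed = 7L)
  out <- make_trajectories(spec, geom)
  det <- detect_capture_events(out$trajectories, geom$ap_point)
  m <- dplyr::inner_join(
    det,
    dplyr::select(out$truth, "oocyte", "chromosome",
                  true_min = "switch_time_min"),
    by = c("oocyte", "chromosome"))
  err_s <- (m$capture_time_min - m$true_min) * 60
  # slow draws (< 5 um/min) and very short transports are undetectable by
  # design, so recall is lower than on constant-speed engine output
  expect_gte(nrow(m) / nrow(out$truth), 0.65)
  expect_lte(stats::median(abs(err_s)), 6)
  expect_lte(abs(stats::median(err_s)), 3)
  expect_equal(mean(m$post_speed_um_min, na.rm = TRUE), spec$speed_mean,
               tolerance = 0.5 / spec$speed_mean)
})

test_that("image stack renders blobs at truth positions with patch mass", {
  spec <- synthetic_spec(seed = 14L)
  st <- make_image_stack(spec, dims = c(32, 32, 32), n_chromosomes = 2,
                         n_frames = 10, poisson_noise = FALSE)
  expect_s3_class(st, "synthetic_stack")
  expect_equal(dim(st$chromosomes), c(32, 32, 32, 10))
  expect_equal(dim(st$patches), c(32, 32, 32, 10))
  expect_equal(length(st$frame_times_s), 10)
  expect_equal(nrow(st$truth), 2 * 10)
  # per frame, chromosome channel total = background + rendered blob mass
  f <- 3
  expect_equal(sum(st$chromosomes[, , , f]),
               32^3 * st$background + 2 * 5000, tolerance = 1e-6)
  # patch channel total matches background + truth patch mass
  expect_equal(sum(st$patches[, , , f]),
               32^3 * st$background +
                 sum(st$truth$patch_mass[st$truth$frame == f]),
               tolerance = 1e-6)
  # the brightest voxel sits at one of the truth positions
  trf <- st$truth[st$truth$frame == f, ]
  idx <- arrayInd(which.max(st$chromosomes[, , , f]), c(32, 32, 32))
  peak_um <- (idx - 0.5) * st$voxel_size
  d_peak <- sqrt((trf$x_um - peak_um[1])^2 + (trf$y_um - peak_um[2])^2 +
                   (trf$z_um - peak_um[3])^2)
  expect_lte(min(d_peak), 1)
})
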