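test_that("spherical ROI sums a uniform field over the in-sphere voxels", {
  frame <- array(3, c(30, 30, 30))
  res <- spherical_intensity(frame, center = c(15, 15, 15), radius = 2.5)
  expect_equal(res$total, 3 * res$n_voxels)
  expect_equal(res$covered_fraction, 1)
  # voxel count approximates the sphere volume (4/3 pi 2.5^3 ~ 65.4)
  expect_equal(res$n_voxels, 4 / 3 * pi * 2.5^3, tolerance = 0.15)
  # center shifted off the voxel grid still covers the full sphere
  res2 <- spherical_intensity(frame, center = c(14.7, 15.2, 15.1))
  expect_equal(res2$covered_fraction, 1)
  expect_equal(res2$total, 3 * res2$n_voxels)
})

test_that("spherical ROI captures nearly all of a compact Gaussian blob", {
  dims <- c(24, 24, 24)
  ctr <- c(12.3, 11.8, 12.1)
  sigma <- 0.6
  ax <- (seq_len(dims[1]) - 0.5)
  g <- function(a, c0) exp(-(a - c0)^2 / (2 * sigma^2))
  frame <- outer(outer(g(ax, ctr[1]), g(ax, ctr[2])), g(ax, ctr[3]))
  res <- spherical_intensity(frame, ctr, radius = 2.5)
  expect_gt(res$total / sum(frame), 0.99)
  # a sphere on the blob's flank picks up less
  res_off <- spherical_intensity(frame, ctr + c(4, 0, 0), radius = 2.5)
  expect_lt(res_off$total, 0.5 * res$total)
})

test_that("spherical ROI handles boundaries, units and bad input", {
  frame <- array(1, c(20, 20, 20))
  expect_error(spherical_intensity(array(1, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(spherical_intensity(frame, c(25, 10, 10)), "outside")
  expect_error(spherical_intensity(frame, c(10, 10, 10), radius = 0.5),
               "radius")
  # sphere clipped by the image edge: covered fraction ~ a half sphere
  # (center 0.5 um from the x = 0 face)
  res_edge <- spherical_intensity(frame, c(0.5, 10, 10), radius = 2.5)
  expect_lt(res_edge$covered_fraction, 0.75)
  expect_gt(res_edge$covered_fraction, 0.4)
  # finer voxels: voxel count matches a brute-force count of voxel
  # centers inside the physical sphere, and the uniform total follows
  count_in <- function(dims, vs, ctr, r) {
    g1 <- (seq_len(dims) - 0.5) * vs
    sum(outer(outer((g1 - ctr[1])^2, (g1 - ctr[2])^2, `+`),
              (g1 - ctr[3])^2, `+`) <= r^2)
  }
  frame_h <- array(1, c(40, 40, 40))
  res_h <- spherical_intensity(frame_h, c(10, 10, 10), radius = 2.5,
                               voxel_size = 0.5)
  res_1 <- spherical_intensity(frame, c(10, 10, 10), radius = 2.5)
  expect_equal(res_h$n_voxels, count_in(40, 0.5, c(10, 10, 10), 2.5))
  expect_equal(res_1$n_voxels, count_in(20, 1, c(10, 10, 10), 2.5))
  expect_equal(res_h$total, res_h$n_voxels)
})

test_that("quantify_stack tracks a moving blob and reports errors by id", {
  dims <- c(20, 20, 20)
  n_fr <- 4
  ax <- seq_len(dims[1]) - 0.5
  stack <- array(0, c(dims, n_fr))
  centers <- cbind(6 + 2 * (seq_len(n_fr) - 1), 10, 10)
  g <- function(a, c0) exp(-(a - c0)^2 / (2 * 0.6^2))
  for (f in seq_len(n_fr)) {
    stack[, , , f] <- 100 *
      outer(outer(g(ax, centers[f, 1]), g(ax, centers[f, 2])),
            g(ax, centers[f, 3]))
  }
  times <- (seq_len(n_fr) - 1) * 3
  traj <- tibble::tibble(chromosome = 1L, t_s = times,
                         x_um = centers[, 1], y_um = centers[, 2],
                         z_um = centers[, 3])
  q <- quantify_stack(stack, traj, times)
  expect_equal(nrow(q), n_fr)
  expect_equal(q$t_min, times / 60)
  # every frame recovers the same blob integral
  expect_equal(q$raw, rep(q$raw[1], n_fr), tolerance = 1e-6)
  expect_gt(q$raw[1], 0.99 * sum(stack[, , , 1]))
  # ROI wandering off the stack names the chromosome and frame
  traj_bad <- dplyr::mutate(traj, x_um = .data$x_um + 30)
  expect_error(quantify_stack(stack, traj_bad, times), "chromosome 1")
  expect_error(quantify_stack(array(0, c(4, 4, 4)), traj, times), "4D")
})

test_that("normalize_trace divides by the pre-NEBD mean, per chromosome", {
  tr <- tibble::tibble(t_min = c(-2, -1, 0, 1, 2),
                       raw = c(100, 102, 202, 303, 101))
  out <- normalize_trace(tr)
  expect_equal(out$background, rep(101, 5))
  expect_equal(out$normalized, tr$raw / 101)
  # per-chromosome backgrounds
  tr2 <- dplyr::bind_rows(
    dplyr::mutate(tr, chromosome = 1L),
    dplyr::mutate(tr, raw = .data$raw * 2, chromosome = 2L))
  out2 <- normalize_trace(tr2)
  expect_equal(unique(out2$background[out2$chromosome == 2]), 202)
  expect_equal(out2$normalized[out2$chromosome == 1],
               out2$normalized[out2$chromosome == 2])
  # explicit background when no pre-NEBD samples exist
  tr3 <- tibble::tibble(t_min = 1:3, raw = c(2, 4, 6))
  expect_error(normalize_trace(tr3), "pre-NEBD")
  out3 <- normalize_trace(tr3, background = 2)
  expect_equal(out3$normalized, c(1, 2, 3))
  expect_error(normalize_trace(tr3, background = 0), "positive")
  expect_error(normalize_trace(tibble::tibble(t_min = 1)), "raw")
})

test_that("patch_timing is exact on a noiseless triangular trace", {
  t <- seq(-2, 12, by = 0.05)
  y <- congressim:::intensity_template(t, onset = 1.5, peak = 5, ret = 8,
                                       amplitude = 4)
  tm <- patch_timing(tibble::tibble(t_min = t, normalized = y))
  expect_equal(tm$onset_min, 1.5, tolerance = 1e-6)
  expect_equal(tm$peak_min, 5, tolerance = 0.15)
  expect_equal(tm$disassembly_min, 8, tolerance = 1e-6)
  # flat trace: no patch, NA row rather than an error
  flat <- tibble::tibble(t_min = t, normalized = rep(1, length(t)))
  tm0 <- patch_timing(flat)
  expect_true(is.na(tm0$onset_min) && is.na(tm0$peak_min) &&
                is.na(tm0$disassembly_min))
  # a 2-sample spike does not satisfy the 3-sample persistence rule
  spike <- flat
  spike$normalized[100:101] <- 3
  expect_true(is.na(patch_timing(spike)$peak_min))
  expect_false(is.na(patch_timing(spike, persistence = 2)$peak_min))
  expect_error(patch_timing(tibble::tibble(t_min = t)), "normalized")
})

test_that("patch timings recover generator kinetics on noisy traces", {
  ctrl <- synthetic_spec("control", seed = 9L)
  latr <- synthetic_spec("latrunculin", seed = 9L)
  tm_c <- patch_timings(normalize_trace(
    make_intensity_traces(ctrl, n_traces = 100)$traces))
  tm_l <- patch_timings(normalize_trace(
    make_intensity_traces(latr, n_traces = 100)$traces))
  expect_equal(nrow(tm_c), 100)
  expect_true(all(!is.na(tm_c$disassembly_min)))
  expect_equal(mean(tm_c$peak_min), 5, tolerance = 0.5 / 5)
  expect_equal(mean(tm_c$disassembly_min), 8, tolerance = 0.5 / 8)
  expect_equal(mean(tm_c$onset_min), 1.5, tolerance = 0.5 / 1.5)
  expect_equal(mean(tm_l$disassembly_min), 4, tolerance = 0.5 / 4)
  expect_equal(mean(tm_l$peak_min), 2.5, tolerance = 0.5 / 2.5)
})

test_that("stack quantification round-trips the rendered patch kinetics", {
  spec <- synthetic_spec(seed = 15L)
  st <- make_image_stack(spec, dims = c(32, 32, 32), n_chromosomes = 2,
                         n_frames = 30, poisson_noise = FALSE)
  q <- quantify_stack(st$patches, st$trajectories, st$frame_times_s)
  norm <- normalize_trace(q, nebd_time_min = 0)
  j <- dplyr::inner_join(
    dplyr::select(norm, "chromosome", "t_s", meas = "normalized"),
    dplyr::select(st$truth, "chromosome", "t_s", true = "normalized"),
    by = c("chromosome", "t_s"))
  # rendered shell mass was calibrated so the 2.5-um ROI reproduces the
  # trace's normalized value; only shell spill-over and background-mean
  # estimation separate measured from truth
  expect_gt(stats::cor(j$meas, j$true), 0.98)
  expect_lt(max(abs(j$meas - j$true) / pmax(j$true, 1)), 0.15)
})

test_that("capture/disassembly lags join by chromosome and summarize", {
  ev <- tibble::tibble(chromosome = c(1, 2, 3),
                       capture_time_min = c(9, 10, 11))
  tm <- tibble::tibble(chromosome = c(1, 2, 4),
                       disassembly_min = c(8, 8.5, 7))
  expect_warning(cd <- correlate_capture_with_disassembly(ev, tm),
                 "unmatched")
  expect_s3_class(cd, "capture_disassembly")
  expect_equal(cd$lags$lag_min, c(1, 1.5))
  expect_equal(cd$summary$n, 2)
  expect_equal(cd$summary$mean_lag_min, 1.25)
  expect_equal(cd$summary$sd_lag_min, stats::sd(c(1, 1.5)))
  expect_setequal(cd$unmatched, c(3, 4))
  expect_output(print(cd), "capture_disassembly")
  # clean join: no warning, no unmatched
  cd2 <- correlate_capture_with_disassembly(ev[1:2, ], tm[1:2, ])
  expect_equal(length(cd2$unmatched), 0)
})
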