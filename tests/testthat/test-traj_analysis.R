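p_ap <- c(35, 0, 0)
sd_frame <- sqrt(2 * diffusion_coefficient(radius = 0.8, viscosity = 0.1,
                                           temperature = 293) * 3)

# Two-phase track: advective (with Brownian-scale noise) until frame k,
# then straight transport toward p at `speed`, parking at 2 um with
# localization jitter. Frame interval 3 s.
make_two_phase <- function(k, speed = 9.22, d0 = 30, n_fr = 301,
                           noise = sd_frame, jitter = 0.1) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  start <- p_ap + d0 * (-abs(u[1]) * c(1, 0, 0) +
                          c(0, u[2], u[3]) * 0.3)
  start <- p_ap + (start - p_ap) / sqrt(sum((start - p_ap)^2)) * d0
  x <- start
  pos <- matrix(NA_real_, n_fr, 3)
  for (f in seq_len(n_fr)) {
    pos[f, ] <- x
    t_min <- (f - 1) * 3 / 60
    if (f < k) {
      v <- if (t_min <= 12.5) (p_ap - x) / (15 - t_min) else c(0, 0, 0)
      x <- x + v * 3 / 60 + stats::rnorm(3, sd = noise)
    } else {
      d <- p_ap - x
      dn <- sqrt(sum(d^2))
      if (dn > 2) x <- x + d / dn * min(speed * 3 / 60, dn - 2)
      x <- x + stats::rnorm(3, sd = jitter)
    }
  }
  tibble::tibble(t_s = (seq_len(n_fr) - 1) * 3, x_um = pos[, 1],
                 y_um = pos[, 2], z_um = pos[, 3])
}

test_that("distance_to_ap computes per-frame Euclidean distance", {
  tr <- tibble::tibble(t_s = c(0, 3, 6), x_um = 35, y_um = 0, z_um = 0)
  expect_equal(distance_to_ap(tr, p_ap)$distance_um, c(0, 0, 0))
  # noiseless advective track from 30 um: linear decay at 2 um/min
  t_s <- seq(0, 600, by = 3)
  d <- 30 * (15 - t_s / 60) / 15
  tr2 <- tibble::tibble(t_s = t_s, x_um = 35 - d, y_um = 0, z_um = 0)
  dd <- distance_to_ap(tr2, p_ap)$distance_um
  expect_equal(dd, d)
  fit <- stats::coef(stats::lm(dd ~ I(t_s / 60)))
  expect_equal(unname(fit[2]), -2)
  expect_error(distance_to_ap(tr2[, -2], p_ap), "x_um")
  expect_error(distance_to_ap(tr2, c(1, 2)), "3-vector")
})

test_that("no events on pure Brownian tracks (false-positive rate)", {
  withr::with_seed(21, {
    tracks <- purrr::map_dfr(1:40, function(id) {
      steps <- matrix(stats::rnorm(300 * 3, sd = sd_frame), ncol = 3)
      pos <- apply(rbind(c(10, 5, -4), steps), 2, cumsum)
      tibble::tibble(chromosome = id, t_s = (0:300) * 3,
                     x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
    })
    ev <- detect_capture_events(tracks, p_ap)
  })
  expect_lte(nrow(ev), 2) # <= 5% of 40 tracks
})

test_that("short trajectories warn and yield no event", {
  tr <- tibble::tibble(t_s = (0:4) * 3, x_um = 1:5, y_um = 0, z_um = 0)
  expect_warning(ev <- detect_capture_events(tr, p_ap), "shorter")
  expect_equal(nrow(ev), 0)
})

test_that("two-phase switch is recovered within 2 frames in >= 95%", {
  withr::with_seed(22, {
    hits <- vapply(1:200, function(i) {
      k <- sample(60:200, 1)
      tr <- make_two_phase(k)
      ev <- congressim:::detect_one_track(tr$t_s, cbind(tr$x_um, tr$y_um, tr$z_um),
                             p_ap, detection_thresholds())
      !is.null(ev) && abs(ev$event_frame - k) <= 2
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("detector is translation- and rotation-equivariant", {
  tr <- withr::with_seed(23, make_two_phase(100))
  ev0 <- congressim:::detect_one_track(tr$t_s, cbind(tr$x_um, tr$y_um, tr$z_um),
                          p_ap, detection_thresholds())
  # random rotation (QR of a Gaussian matrix) and translation
  withr::with_seed(24, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- stats::runif(3, -50, 50)
  })
  pos2 <- t(q %*% t(cbind(tr$x_um, tr$y_um, tr$z_um))) +
    matrix(shift, nrow(tr), 3, byrow = TRUE)
  ev1 <- congressim:::detect_one_track(tr$t_s, pos2, as.vector(q %*% p_ap) + shift,
                          detection_thresholds())
  expect_equal(ev1$event_frame, ev0$event_frame)
  expect_equal(ev1$capture_time_min, ev0$capture_time_min)
})

test_that("phase speeds recover advective and transport speeds", {
  # noiseless two-phase: advective from 30 um (2 um/min), switch at
  # frame 101 (5 min), transport at 9.22 um/min
  tr <- make_two_phase(101, noise = 0, jitter = 0)
  sp <- phase_speeds(tr, event_time_min = (101 - 1) * 3 / 60, p = p_ap)
  expect_equal(sp$pre_speed_um_min, 2, tolerance = 0.05)
  expect_equal(sp$post_speed_um_min, 9.22, tolerance = 0.02)
  # stationary track with an injected event: both speeds zero
  st <- tibble::tibble(t_s = (0:100) * 3, x_um = 20, y_um = 3, z_um = 0)
  sp0 <- phase_speeds(st, event_time_min = 2, p = p_ap)
  expect_equal(sp0$pre_speed_um_min, 0)
  expect_equal(sp0$post_speed_um_min, 0)
  # event at the very start: pre side undefined
  sp1 <- phase_speeds(tr, event_time_min = 0, p = p_ap)
  expect_true(is.na(sp1$pre_speed_um_min))
})

test_that("detected events match engine ground truth on a small cohort", {
  coh <- run_cohort(4, sim_params(model_variant = 3), base_seed = 101L)
  det <- detect_capture_events(coh$trajectories, p_ap)
  truth <- dplyr::filter(tidy(coh), !is.na(.data$capture_time_min))
  m <- dplyr::inner_join(
    det, dplyr::select(truth, "oocyte", "chromosome",
                       true_min = "capture_time_min"),
    by = c("oocyte", "chromosome"))
  err_s <- (m$capture_time_min - m$true_min) * 60
  expect_gte(nrow(m) / nrow(truth), 0.9) # recall
  expect_lte(stats::median(abs(err_s)), 6) # within 2 frames
  expect_lte(abs(stats::median(err_s)), 3) # no bias beyond 1 frame
  # post-event speed reflects transport, pre-event the slow phase
  expect_equal(stats::median(m$post_speed_um_min, na.rm = TRUE), 9.22,
               tolerance = 0.05)
  expect_lt(stats::median(m$pre_speed_um_min, na.rm = TRUE), 5)
})

test_that("capture_statistics matches hand-computed summaries", {
  cs <- capture_statistics(c(8, 9, 10))
  expect_equal(cs$summary$n, 3)
  expect_equal(cs$summary$mean_min, 9)
  expect_equal(cs$summary$sd_min, 1)
  expect_equal(sum(cs$histogram$count), 3)
  # histogram binning: 0.5-min bins anchored at 0, left-closed
  expect_equal(cs$histogram$count[cs$histogram$bin_start_min == 8], 1)
  expect_equal(cs$histogram$bin_mid_min[1], 0.25)
  # modal bin
  cs2 <- capture_statistics(c(1.1, 1.2, 1.4, 7))
  expect_equal(cs2$summary$modal_bin_start_min, 1)
  # values beyond the default range extend the histogram
  cs3 <- capture_statistics(c(1, 25.2))
  expect_equal(sum(cs3$histogram$count), 2)
  # empty input: empty summary, not an error
  cs4 <- capture_statistics(numeric(0))
  expect_equal(cs4$summary$n, 0)
  expect_true(is.na(cs4$summary$mean_min))
  # accepts event tibbles and drops NA
  cs5 <- capture_statistics(
    tibble::tibble(capture_time_min = c(4, NA, 6)))
  expect_equal(cs5$summary$n, 2)
  expect_equal(cs5$summary$mean_min, 5)
})
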