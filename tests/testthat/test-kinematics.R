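test_that("frame angles follow analytic geometry and rotate with the frame", {
  # collinear horizontal configuration
  expect_equal(frame_angles(c(-1, 0), c(0, 0), c(1, 0)),
               c(alpha = 0, beta = 0))
  # tip ray raised by 10 degrees
  ang <- frame_angles(c(-1, 0), c(0, 0), c(cos(10 * pi / 180),
                                           sin(10 * pi / 180)))
  expect_equal(ang, c(alpha = 0, beta = 10))
  # rigid rotation by 25 degrees adds 25 to both line angles
  rot <- function(p, th) {
    th <- th * pi / 180
    c(cos(th) * p[1] - sin(th) * p[2], sin(th) * p[1] + cos(th) * p[2])
  }
  p1 <- c(-1, 0); p2 <- c(0, 0); p3 <- c(cos(10 * pi / 180), sin(10 * pi / 180))
  ang25 <- frame_angles(rot(p1, 25), rot(p2, 25), rot(p3, 25))
  expect_equal(unname(ang25), unname(ang) + 25, tolerance = 1e-12)
  # degenerate geometry is rejected
  expect_error(frame_angles(c(0, 0), c(0, 0), c(1, 0)), "degenerate")
})

test_that("actual bending is the base-corrected angle and survives rotation", {
  expect_equal(actual_bending(0, 10), 10)
  expect_equal(actual_bending(25, 35), 10)   # rotated configuration
  expect_equal(actual_bending(42.5, 42.5), 0)
  # wrap: line angles are modulo 180
  expect_equal(actual_bending(-85, 85), -10)
})

test_that("relative bending is zero at the reference frame by definition", {
  expect_equal(relative_bending(c(3, 17))[2], 14)
  expect_equal(relative_bending(c(5.123, 7, 2))[1], 0)
  expect_error(relative_bending(numeric(0)), "reference")
})

test_that("delta and gamma are invariant under rigid motion and scaling", {
  set.seed(11)
  for (i in 1:20) {
    n <- 8
    tr <- track_series(seq(0, by = 30, length.out = n),
                       p1 = cbind(-10 + rnorm(n, 0, .3), rnorm(n, 0, .3)),
                       p2 = cbind(rnorm(n, 0, .1), rnorm(n, 0, .1)),
                       p3 = cbind(12 + rnorm(n, 0, .3), 2 + rnorm(n, 0, .3)))
    base <- track_angles(tr)
    moved <- transform_track(tr, angle_deg = runif(1, -40, 40),
                             dx = rnorm(1, 0, 50), dy = rnorm(1, 0, 50),
                             scale = runif(1, 0.2, 5))
    out <- track_angles(moved)
    expect_equal(out$delta_deg, base$delta_deg, tolerance = 1e-9)
    expect_equal(out$gamma_deg, base$gamma_deg, tolerance = 1e-9)
    expect_equal(out$gamma_deg[1], 0)
  }
})

test_that("image-frame (y-down) series give the same bending angles", {
  sim <- simulate_tracks(noiseless_scenario(n_subjects = 2, seed = 3))
  tr <- sim$tracks[[1]]
  flipped <- track_series(tr$time_s,
                          cbind(tr$x1, -tr$y1), cbind(tr$x2, -tr$y2),
                          cbind(tr$x3, -tr$y3), convention = "y-down")
  expect_equal(track_angles(flipped)$gamma_deg, track_angles(tr)$gamma_deg,
               tolerance = 1e-12)
})

test_that("large single-frame jumps in delta are rejected as ambiguous", {
  # tip swings from -50 to +50 degrees between consecutive frames
  ang <- c(0, -50, 50) * pi / 180
  tr <- track_series(c(0, 30, 60), p1 = matrix(c(-1, 0), 3, 2, byrow = TRUE),
                     p2 = matrix(0, 3, 2), p3 = cbind(cos(ang), sin(ang)))
  expect_error(track_angles(tr), "90 degrees")
})

test_that("evaluation-time sampling picks nearest frames, ties to earlier", {
  n <- 111
  t_s <- seq(0, 55 * 60, by = 30)
  tr <- track_series(t_s, p1 = matrix(c(-1, 0), n, 2, byrow = TRUE),
                     p2 = matrix(0, n, 2),
                     p3 = cbind(cos(seq(0, 0.3, length.out = n)),
                                sin(seq(0, 0.3, length.out = n))))
  ang <- track_angles(tr)
  smp <- sample_at_times(ang, c(1, 55, 2.2, 0.25))
  expect_equal(smp$frame_time_s, c(60, 3300, 120, 0))
  # 2.2 min sits nearest the 2.0-min frame; 0.25 min is exactly midway
  # between frames 0 and 1, so the earlier frame wins the tie
  expect_error(sample_at_times(ang, 60), "coverage")
})
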