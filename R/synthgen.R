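#' Define a synthetic sealing experiment
#'
#' Describes the design of a humidity x time wound-sealing experiment with a
#' known latent model, mirroring the laboratory protocol: one frame every
#' 30 s over 55 min, evaluation at 1, 5, 10, 20, 40 and 55 min, and four
#' humidity conditions in the wound region (24, 49 and 100 % relative air
#' humidity plus a liquid water droplet, for which the wound opens and the
#' asymptotic bending angle is negative).
#'
#' The latent relative bending angle of subject s under condition c follows a
#' saturating exponential
#' \deqn{\gamma_{sc}(t) = (\gamma^\infty_c + b_s)\,(1 - e^{-t/\tau_c}),}
#' with a per-subject offset \eqn{b_s \sim N(0, \code{subject_sd}^2)} shared
#' across conditions (a repeated-measures structure with subject = leaf).
#'
#' @param conditions data frame with columns `condition` (label), `gamma_inf`
#'   (asymptotic relative bending angle, degrees; negative allowed) and `tau`
#'   (time constant, minutes, > 0).
#' @param n_subjects number of leaves (>= 2); default 17.
#' @param frame_interval seconds between frames (default 30).
#' @param duration recording span in minutes (default 55).
#' @param evaluation_times evaluation times in minutes, all within
#'   `[0, duration]`.
#' @param base_drift_amplitude amplitude (degrees) of a smooth sinusoidal
#'   drift of the leaf-base line, emulating rigid motion of the whole leaf.
#' @param coordinate_noise_sd standard deviation of i.i.d. Gaussian noise
#'   added to every emitted coordinate (same length units as the tracks, mm).
#' @param subject_sd between-leaf standard deviation of the asymptote
#'   (degrees).
#' @param delta0 pre-injury actual bending angle (degrees).
#' @param arm_base,arm_tip distances (mm) of points 1 and 3 from the hinge.
#' @param seed integer seed making the generated experiment reproducible.
#' @return a list of class `sealing_scenario`.
#' @export
sealing_scenario <- function(conditions = data.frame(
                               condition = c("24%", "49%", "100%", "droplet"),
                               gamma_inf = c(18, 10, 2, -12),
                               tau = c(8, 12, 20, 6)),
                             n_subjects = 17,
                             frame_interval = 30,
                             duration = 55,
                             evaluation_times = c(1, 5, 10, 20, 40, 55),
                             base_drift_amplitude = 1,
                             coordinate_noise_sd = 0.02,
                             subject_sd = 3,
                             delta0 = 5,
                             arm_base = 10,
                             arm_tip = 15,
                             seed = 1L) {
  if (!is.data.frame(conditions) ||
      !all(c("condition", "gamma_inf", "tau") %in% names(conditions)))
    stopf("'conditions' needs columns condition, gamma_inf, tau")
  check_finite(conditions$gamma_inf, "gamma_inf")
  check_finite(conditions$tau, "tau")
  if (any(conditions$tau <= 0)) stopf("time constants tau must be > 0")
  check_scalar(n_subjects, "n_subjects", lower = 2)
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_finite(evaluation_times, "evaluation_times")
  if (any(evaluation_times < 0 | evaluation_times > duration))
    stopf("evaluation_times must lie within [0, duration]")
  check_scalar(base_drift_amplitude, "base_drift_amplitude", lower = 0)
  check_scalar(coordinate_noise_sd, "coordinate_noise_sd", lower = 0)
  check_scalar(subject_sd, "subject_sd", lower = 0)
  check_scalar(arm_base, "arm_base", lower = 0, strict_lower = TRUE)
  check_scalar(arm_tip, "arm_tip", lower = 0, strict_lower = TRUE)
  structure(list(conditions = conditions,
                 n_subjects = as.integer(n_subjects),
                 frame_interval = frame_interval, duration = duration,
                 evaluation_times = sort(evaluation_times),
                 base_drift_amplitude = base_drift_amplitude,
                 coordinate_noise_sd = coordinate_noise_sd,
                 subject_sd = subject_sd, delta0 = delta0,
                 arm_base = arm_base, arm_tip = arm_tip,
                 seed = as.integer(seed)),
            class = "sealing_scenario")
}

latent_gamma <- function(gamma_inf, tau, t_min) gamma_inf * (1 - exp(-t_min / tau))

#' Simulate tracked-point experiments with known ground truth
#'
#' Emits one three-point [track_series()] per subject x condition plus a
#' ground-truth table of the latent relative bending angle at the evaluation
#' times.  Point 2 sits at a fixed hinge; point 1 lies on a base ray whose
#' orientation drifts smoothly; point 3 lies on a tip ray at
#' `delta0 + gamma(t)` relative to the base ray, so the downstream kinematics
#' recovers the latent angle exactly in the noiseless case.  Identical
#' scenario and seed give identical output.
#'
#' @param scenario a [sealing_scenario()].
#' @param frames `"all"` for the full 30-s frame grid, `"evaluation"` to emit
#'   only the pre-injury frame plus the evaluation times (faster for
#'   simulation studies; the recovered angles are identical at those times).
#' @return list with elements `tracks` (named list of `track_series`) and
#'   `truth` (data frame `subject`, `condition`, `time_min`, `gamma_true`).
#' @export
#' @examples
#' sim <- simulate_tracks(sealing_scenario(n_subjects = 3, seed = 7))
#' head(sim$truth)
simulate_tracks <- function(scenario, frames = c("all", "evaluation")) {
  if (!inherits(scenario, "sealing_scenario"))
    stopf("'scenario' must come from sealing_scenario()")
  frames <- match.arg(frames)
  sc <- scenario
  set.seed(sc$seed)
  t_min <- if (frames == "all") {
    seq(0, sc$duration * 60, by = sc$frame_interval) / 60
  } else {
    unique(sort(c(0, sc$evaluation_times)))
  }
  nf <- length(t_min)
  offsets <- stats::rnorm(sc$n_subjects, 0, sc$subject_sd)
  tracks <- list()
  truth_rows <- list()
  for (s in seq_len(sc$n_subjects)) {
    for (ci in seq_len(nrow(sc$conditions))) {
      cond <- sc$conditions$condition[ci]
      g_inf <- sc$conditions$gamma_inf[ci] + offsets[s]
      gam <- latent_gamma(g_inf, sc$conditions$tau[ci], t_min)
      phase <- stats::runif(1, 0, 2 * pi)
      drift <- sc$base_drift_amplitude *
        (sin(2 * pi * t_min / sc$duration + phase) - sin(phase))
      a_deg <- drift                      # base-line orientation
      b_deg <- a_deg + sc$delta0 + gam    # tip-line orientation
      a <- a_deg * pi / 180; b <- b_deg * pi / 180
      p2 <- cbind(rep(0, nf), rep(0, nf))
      p1 <- cbind(-sc$arm_base * cos(a), -sc$arm_base * sin(a))
      p3 <- cbind(sc$arm_tip * cos(b), sc$arm_tip * sin(b))
      if (sc$coordinate_noise_sd > 0) {
        noise <- matrix(stats::rnorm(nf * 6, 0, sc$coordinate_noise_sd), nf, 6)
        p1 <- p1 + noise[, 1:2]; p2 <- p2 + noise[, 3:4]; p3 <- p3 + noise[, 5:6]
      }
      id <- sprintf("s%02d_%s", s, cond)
      tracks[[id]] <- track_series(t_min * 60, p1, p2, p3, units = "mm",
                                   leaf_id = sprintf("s%02d", s),
                                   condition = cond)
      truth_rows[[id]] <- fast_df(
        subject = rep(sprintf("s%02d", s), length(sc$evaluation_times)),
        condition = rep(cond, length(sc$evaluation_times)),
        time_min = sc$evaluation_times,
        gamma_true = latent_gamma(g_inf, sc$conditions$tau[ci],
                                  sc$evaluation_times))
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(tracks = tracks, truth = truth)
}

#' Define a synthetic tensile test
#'
#' Ground truth for a quasi-static uniaxial tensile test on a succulent leaf:
#' an initial linear-elastic segment of slope `true_E`, then a concave
#' yielding segment that attains `true_strength` smoothly (continuous slope)
#' and plateaus there.  Displacement grows at `strain_rate * L0` per second
#' and readings are taken at `sampling_rate` Hz, as in the laboratory
#' protocol (0.002 1/s, 5 Hz).
#'
#' @param true_E elastic modulus, MPa.
#' @param true_strength tensile strength, MPa.
#' @param true_poisson Poisson's ratio (0 <= nu < 0.5).
#' @param geometry data frame of 5 stations with columns `a`, `b`: ellipse
#'   half-axes in m along the leaf.
#' @param L0 original free length, m.
#' @param strain_rate 1/s.
#' @param sampling_rate Hz.
#' @param yield_fraction fraction of `true_strength` at which the response
#'   leaves the linear segment (default 0.6).
#' @param noise_sd_force standard deviation of additive force noise, N.
#' @param seed integer seed.
#' @return list of class `tensile_spec`.
#' @export
tensile_spec <- function(true_E = 0.72, true_strength = 0.09,
                         true_poisson = 0.28,
                         geometry = data.frame(a = rep(1.5e-3, 5),
                                               b = rep(1.5e-3, 5)),
                         L0 = 0.02, strain_rate = 0.002, sampling_rate = 5,
                         yield_fraction = 0.6,
                         noise_sd_force = 0, seed = 1L) {
  check_scalar(true_E, "true_E", lower = 0, strict_lower = TRUE)
  check_scalar(true_strength, "true_strength", lower = 0, strict_lower = TRUE)
  check_scalar(true_poisson, "true_poisson", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  if (!is.data.frame(geometry) || !all(c("a", "b") %in% names(geometry)))
    stopf("'geometry' needs columns a and b (half-axes in m)")
  check_finite(geometry$a, "a"); check_finite(geometry$b, "b")
  if (any(geometry$a <= 0 | geometry$b <= 0))
    stopf("all geometry half-axes must be positive")
  check_scalar(L0, "L0", lower = 0, strict_lower = TRUE)
  check_scalar(strain_rate, "strain_rate", lower = 0, strict_lower = TRUE)
  check_scalar(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_scalar(yield_fraction, "yield_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(noise_sd_force, "noise_sd_force", lower = 0)
  structure(list(true_E = true_E, true_strength = true_strength,
                 true_poisson = true_poisson, geometry = geometry, L0 = L0,
                 strain_rate = strain_rate, sampling_rate = sampling_rate,
                 yield_fraction = yield_fraction,
                 noise_sd_force = noise_sd_force, seed = as.integer(seed)),
            class = "tensile_spec")
}

#' Simulate a tensile force-displacement record
#'
#' @param spec a [tensile_spec()].
#' @return list with `record` (data frame `time_s`, `force_N`,
#'   `displacement_m`, plus attribute `L0_m`), `geometry` (the 5-station
#'   ellipse table), and `poisson` (a [PoissonInput][poisson_ratio()]-style
#'   list `L0`, `dL`, `d0`, `dd` taken at the bounds of the linear-elastic
#'   range, as would be read off the first and last image of that range).
#' @export
simulate_tensile <- function(spec) {
  if (!inherits(spec, "tensile_spec"))
    stopf("'spec' must come from tensile_spec()")
  set.seed(spec$seed)
  E <- spec$true_E * 1e6          # Pa
  s_max <- spec$true_strength * 1e6
  s_y <- spec$yield_fraction * s_max
  eps_y <- s_y / E
  eps_f <- eps_y + 2 * (s_max - s_y) / E   # slope-continuous quadratic cap
  eps_end <- 1.05 * eps_f
  t_end <- eps_end / spec$strain_rate
  time_s <- seq(0, t_end, by = 1 / spec$sampling_rate)
  eps <- spec$strain_rate * time_s
  sigma <- ifelse(eps <= eps_y, E * eps,
           ifelse(eps >= eps_f, s_max,
                  s_max - (s_max - s_y) * ((eps_f - eps) / (eps_f - eps_y))^2))
  abar <- mean(pi * spec$geometry$a * spec$geometry$b)
  force <- sigma * abar
  if (spec$noise_sd_force > 0)
    force <- force + stats::rnorm(length(force), 0, spec$noise_sd_force)
  record <- data.frame(time_s = time_s, force_N = force,
                       displacement_m = eps * spec$L0)
  attr(record, "L0_m") <- spec$L0
  d0 <- 2 * spec$geometry$a[3]   # transverse diameter at mid-length mark
  poisson <- list(L0 = spec$L0, dL = eps_y * spec$L0,
                  d0 = d0, dd = spec$true_poisson * eps_y * d0)
  list(record = record, geometry = spec$geometry, poisson = poisson)
}

#' Define a synthetic turgor-probe profile
#'
#' Cell-pressure-probe readings of single parenchyma/chlorenchyma cells at
#' varying measurement depth, with an optional linear depth trend (in the
#' leaves studied, turgor tends to decrease slightly with depth).
#'
#' @param n_cells number of probed cells (>= 3); default 44 as in a full
#'   measurement campaign.
#' @param depth_range numeric length-2, probing depth range in micrometres.
#' @param turgor_mean mean turgor, MPa (> 0).
#' @param turgor_sd cell-to-cell standard deviation, MPa.
#' @param depth_slope linear trend of turgor with depth, MPa per micrometre.
#' @param seed integer seed.
#' @return list of class `turgor_spec`.
#' @export
turgor_spec <- function(n_cells = 44, depth_range = c(100, 1500),
                        turgor_mean = 0.042, turgor_sd = 0.015,
                        depth_slope = 0, seed = 1L) {
  check_scalar(n_cells, "n_cells", lower = 3)
  check_finite(depth_range, "depth_range")
  if (length(depth_range) != 2L || diff(depth_range) <= 0)
    stopf("'depth_range' must be an increasing length-2 range")
  check_scalar(turgor_mean, "turgor_mean", lower = 0, strict_lower = TRUE)
  check_scalar(turgor_sd, "turgor_sd", lower = 0)
  check_scalar(depth_slope, "depth_slope")
  structure(list(n_cells = as.integer(n_cells), depth_range = depth_range,
                 turgor_mean = turgor_mean, turgor_sd = turgor_sd,
                 depth_slope = depth_slope, seed = as.integer(seed)),
            class = "turgor_spec")
}

#' Simulate turgor-probe readings
#'
#' Turgor is `turgor_mean + depth_slope * (depth - mean depth) + noise`,
#' truncated to stay positive (a pressure probe cannot read a negative
#' turgor).
#'
#' @param spec a [turgor_spec()].
#' @return data frame with columns `depth_um`, `turgor_MPa`.
#' @export
simulate_turgor <- function(spec) {
  if (!inherits(spec, "turgor_spec"))
    stopf("'spec' must come from turgor_spec()")
  set.seed(spec$seed)
  depth <- sort(stats::runif(spec$n_cells, spec$depth_range[1],
                             spec$depth_range[2]))
  turgor <- spec$turgor_mean + spec$depth_slope * (depth - mean(depth))
  if (spec$turgor_sd > 0)
    turgor <- turgor + stats::rnorm(spec$n_cells, 0, spec$turgor_sd)
  turgor <- pmax(turgor, 1e-6)
  data.frame(depth_um = depth, turgor_MPa = turgor)
}
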