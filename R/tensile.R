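#' Elliptical cross-sectional area
#'
#' Leaf cross-sections are treated as ellipses, `A = pi * a * b`, with `a`
#' the half-width and `b` the half-height.  `rectangle = TRUE` switches to a
#' width x height rectangle (used for epidermis strips, whose large window
#' cells make an elliptical fit meaningless); there `a` and `b` are the full
#' width and height.
#'
#' @param a,b half-axes (or, for rectangles, full sides), any length unit.
#' @param rectangle logical.
#' @return area in the squared length unit; vectorised over `a`, `b`.
#' @export
#' @examples
#' cross_section_area(1.5e-3, 1.5e-3)       # circular leaf, m^2
cross_section_area <- function(a, b, rectangle = FALSE) {
  check_finite(a, "a"); check_finite(b, "b")
  if (any(a <= 0) || any(b <= 0)) stopf("half-axes must be positive")
  if (rectangle) a * b else pi * a * b
}

#' Mean cross-sectional area over the measurement stations
#'
#' @param geometry data frame with columns `a`, `b` (half-axes, m), one row
#'   per station along the leaf's longitudinal axis (five in the standard
#'   whole-leaf protocol).
#' @param rectangle see [cross_section_area()].
#' @return mean area, m^2.
#' @export
mean_area <- function(geometry, rectangle = FALSE) {
  if (!is.data.frame(geometry) || !all(c("a", "b") %in% names(geometry)))
    stopf("'geometry' needs columns a and b")
  mean(cross_section_area(geometry$a, geometry$b, rectangle = rectangle))
}

#' Engineering stress-strain curve from a force-displacement record
#'
#' Pointwise `sigma_i = F_i / Abar` and `eps_i = dL_i / L0` (engineering
#' stress and strain).
#'
#' @param record data frame with columns `force_N` and `displacement_m`.
#' @param abar mean cross-sectional area, m^2.
#' @param L0 original length, m; taken from the record's `L0_m` attribute if
#'   omitted.
#' @return data frame with columns `strain` (dimensionless) and `stress_Pa`.
#' @export
stress_strain <- function(record, abar, L0 = attr(record, "L0_m")) {
  if (is.null(L0)) stopf("'L0' missing and not stored on the record")
  check_scalar(abar, "abar", lower = 0, strict_lower = TRUE)
  check_scalar(L0, "L0", lower = 0, strict_lower = TRUE)
  if (!all(c("force_N", "displacement_m") %in% names(record)))
    stopf("'record' needs columns force_N and displacement_m")
  data.frame(strain = record$displacement_m / L0,
             stress_Pa = record$force_N / abar)
}

#' Tensile strength
#'
#' Maximum force over the whole record divided by the mean cross-sectional
#' area; the pre-rupture force peak is used even when the trace drops
#' afterwards.
#'
#' @inheritParams stress_strain
#' @return `sigma_max` in Pa.
#' @export
tensile_strength <- function(record, abar) {
  check_scalar(abar, "abar", lower = 0, strict_lower = TRUE)
  if (!nrow(record)) stopf("empty tensile record")
  max(record$force_N) / abar
}

#' Elastic modulus from the initial linear part of a stress-strain curve
#'
#' Scans prefix windows growing from the low-strain end and keeps the longest
#' one whose least-squares line has a coefficient of determination of at
#' least `r2_threshold`; the modulus is the slope over that window.  The rule
#' is deterministic and auditable.  The default threshold is tuned for
#' low-noise records, where prefix R^2 is slow to react to the gentle onset
#' of yielding; for noisy data it must be relaxed toward the R^2 the noise
#' itself permits (roughly `1 - var(noise) / var(stress in the window)`),
#' otherwise no window qualifies.
#'
#' @param curve data frame from [stress_strain()] (columns `strain`,
#'   `stress_Pa`).
#' @param min_points smallest admissible window (default 10 points).
#' @param r2_threshold required R^2 (default `1 - 1e-6`, for clean records;
#'   noise-scaled values like 0.999 or below are appropriate for real data).
#' @return list of class `elastic_fit`: `E_Pa`, `window` (strain bounds),
#'   `n_points`, `r2`.
#' @export
#' @examples
#' cv <- data.frame(strain = seq(0, 0.1, 1e-3), stress_Pa = 2e6 * seq(0, 0.1, 1e-3))
#' elastic_modulus(cv)$E_Pa   # 2e6 exactly
elastic_modulus <- function(curve, min_points = 10, r2_threshold = 1 - 1e-6) {
  if (!all(c("strain", "stress_Pa") %in% names(curve)))
    stopf("'curve' needs columns strain and stress_Pa")
  x <- curve$strain; y <- curve$stress_Pa
  n <- length(x)
  if (n < min_points)
    stopf("need at least %d points in the initial region, got %d", min_points, n)
  k <- seq_len(n)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x * x); syy <- cumsum(y * y); sxy <- cumsum(x * y)
  vx <- sxx - sx^2 / k
  vy <- syy - sy^2 / k
  cxy <- sxy - sx * sy / k
  r2 <- ifelse(vx > 0 & vy > 0, cxy^2 / (vx * vy), NA_real_)
  ok <- which(k >= min_points & !is.na(r2) & r2 >= r2_threshold)
  if (!length(ok))
    stopf(paste("no initial window of >= %d points reaches R^2 >= %g;",
                "consider relaxing 'r2_threshold' for noisy data"),
          min_points, r2_threshold)
  m <- max(ok)
  slope <- cxy[m] / vx[m]
  if (slope <= 0) stopf("non-positive slope in the detected linear window")
  structure(list(E_Pa = slope, window = c(x[1], x[m]), n_points = m,
                 r2 = r2[m]),
            class = "elastic_fit")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf("Elastic modulus: %.4g MPa (window strain %.4g..%.4g, %d points, R^2 = %.6f)\n",
              x$E_Pa / 1e6, x$window[1], x$window[2], x$n_points, x$r2))
  invisible(x)
}

#' Poisson's ratio from paired axial and transverse measurements
#'
#' `nu = (dd / d0) / (dL / L0)`, with `L0` and `d0` read off the first image
#' of the linear-elastic range and `dL`, `dd` the axial extension and
#' transverse contraction (magnitude) accumulated by its last image.
#'
#' @param L0,dL axial original length and extension, m.
#' @param d0,dd transverse original diameter and contraction (magnitude), m.
#' @return dimensionless `nu`.
#' @export
#' @examples
#' poisson_ratio(L0 = 1, dL = 0.10, d0 = 1, dd = 0.028)  # 0.28
poisson_ratio <- function(L0, dL, d0, dd) {
  check_scalar(L0, "L0", lower = 0, strict_lower = TRUE)
  check_scalar(d0, "d0", lower = 0, strict_lower = TRUE)
  check_finite(dL, "dL"); check_finite(dd, "dd")
  if (dL == 0)
    stopf("Poisson's ratio is undefined at zero axial extension (dL = 0)")
  (abs(dd) / d0) / (dL / L0)
}

#' Analyse one tensile test end to end
#'
#' Convenience wrapper: mean area, stress-strain conversion, strength,
#' modulus, and (when transverse data are supplied) Poisson's ratio.
#'
#' @param record force-displacement record (see [stress_strain()]).
#' @param geometry 5-station ellipse table.
#' @param poisson optional list `L0`, `dL`, `d0`, `dd`.
#' @param ... passed to [elastic_modulus()].
#' @return data frame row: `E_MPa`, `strength_MPa`, `poisson`, `window_lo`,
#'   `window_hi`, `r2`.
#' @export
analyse_tensile <- function(record, geometry, poisson = NULL, ...) {
  abar <- mean_area(geometry)
  curve <- stress_strain(record, abar)
  fit <- elastic_modulus(curve, ...)
  nu <- if (is.null(poisson)) NA_real_ else
    poisson_ratio(poisson$L0, poisson$dL, poisson$d0, poisson$dd)
  data.frame(E_MPa = fit$E_Pa / 1e6,
             strength_MPa = tensile_strength(record, abar) / 1e6,
             poisson = nu,
             window_lo = fit$window[1], window_hi = fit$window[2],
             r2 = fit$r2)
}
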