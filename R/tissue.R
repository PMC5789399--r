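#' Turgor-based elastic modulus of parenchymatous tissue
#'
#' Tissue stiffness of thin-walled, turgid parenchyma or chlorenchyma is
#' modelled as the sum of two contributions: a turgor term, linear in the
#' turgor pressure `P` (pressure stiffens the fluid-filled cells), and a
#' wall-geometry term proportional to the wall volume fraction `t_cw / d_c`
#' and the cell-wall modulus `E_cw` (the load carried by the wall network
#' itself).  With the default order-unity coefficients for approximately
#' isodiametric thin-walled cells,
#' \deqn{E_{tissue} = c_P P + c_w \frac{t_{cw}}{d_c} E_{cw},
#'       \qquad c_P = 4,\; c_w = 3.}
#' Both terms vanish for a flaccid tissue with negligible walls, and the
#' relation is affine-increasing in `P` at fixed geometry.
#'
#' @param P turgor pressure, MPa (>= 0).
#' @param d_c cell diameter, micrometres (> 0).
#' @param t_cw cell wall thickness, micrometres (>= 0).
#' @param nu Poisson's ratio of the tissue, `0 <= nu < 0.5` (validated and
#'   carried in the result for bookkeeping; the default isotropic small-strain
#'   form does not depend on it).
#' @param E_cw elastic modulus of the cell wall, MPa (>= 0).
#' @param turgor_coef,wall_coef model coefficients `c_P`, `c_w`.
#' @return list of class `tissue_modulus`: `E_MPa` and the two contributions
#'   `turgor_term_MPa`, `wall_term_MPa`.
#' @export
#' @examples
#' tissue_modulus(P = 0.042, d_c = 77, t_cw = 0.42, nu = 0.28, E_cw = 5.00)
tissue_modulus <- function(P, d_c, t_cw, nu, E_cw,
                           turgor_coef = 4, wall_coef = 3) {
  check_scalar(P, "P", lower = 0)
  check_scalar(d_c, "d_c", lower = 0, strict_lower = TRUE)
  check_scalar(t_cw, "t_cw", lower = 0)
  check_scalar(nu, "nu", lower = 0, upper = 0.5, strict_upper = TRUE)
  check_scalar(E_cw, "E_cw", lower = 0)
  check_scalar(turgor_coef, "turgor_coef", lower = 0)
  check_scalar(wall_coef, "wall_coef", lower = 0)
  turgor_term <- turgor_coef * P
  wall_term <- wall_coef * (t_cw / d_c) * E_cw
  structure(list(E_MPa = turgor_term + wall_term,
                 turgor_term_MPa = turgor_term,
                 wall_term_MPa = wall_term,
                 nu = nu),
            class = "tissue_modulus")
}

#' @export
print.tissue_modulus <- function(x, ...) {
  cat(sprintf("Tissue elastic modulus: %.4g MPa (turgor term %.4g + wall term %.4g)\n",
              x$E_MPa, x$turgor_term_MPa, x$wall_term_MPa))
  invisible(x)
}

#' Ring-equivalent thickness of a net of vascular bundles
#'
#' Converts the discrete net of peripheral vascular bundles into a continuous
#' ring of the same total cross-sectional area: `thickness =
#' sum(areas) / (2 pi r)`, with `r` the middle radius of the net.
#'
#' @param bundle_areas vector of bundle cross-sectional areas, um^2 (>= 0).
#' @param r middle radius of the net, um (> 0).
#' @return equivalent thickness, um.
#' @export
#' @examples
#' ring_equivalent_thickness(rep(2 * pi * 500 * 15 / 20, 20), 500)  # 15
ring_equivalent_thickness <- function(bundle_areas, r) {
  check_scalar(r, "r", lower = 0, strict_lower = TRUE)
  if (!length(bundle_areas)) {
    warnf("empty bundle list: ring-equivalent thickness is 0")
    return(0)
  }
  check_finite(bundle_areas, "bundle_areas")
  if (any(bundle_areas < 0)) stopf("bundle areas must be >= 0")
  sum(bundle_areas) / (2 * pi * r)
}

#' Correct histological shrinkage of succulent parenchymatous tissue
#'
#' Thin-section preparation shrinks succulent parenchymatous tissues by about
#' 15 % in linear dimension; measured lengths are rescaled to in-vivo size by
#' `measured / (1 - shrink_fraction)`.  Applies to linear dimensions of
#' parenchymatous tissues only.
#'
#' @param measured measured linear dimension(s), um.
#' @param shrink_fraction fraction lost during preparation, in `[0, 1)`;
#'   default 0.15.
#' @return corrected dimension(s), um.
#' @export
#' @examples
#' shrinkage_correct(85)        # 100
shrinkage_correct <- function(measured, shrink_fraction = 0.15) {
  check_finite(measured, "measured")
  check_scalar(shrink_fraction, "shrink_fraction", lower = 0, upper = 1,
               strict_upper = TRUE)
  measured / (1 - shrink_fraction)
}

#' Absolute humidity from relative humidity
#'
#' Water-vapour content of air in g/m^3.  If the saturation content at the
#' ambient temperature is known it is simply scaled by the relative humidity;
#' otherwise the saturation vapour density is computed from the temperature
#' via the Magnus saturation-pressure approximation (constants 6.1094 hPa,
#' 17.625, 243.04 degC) and the ideal-gas law for water vapour
#' (R_v = 461.5 J kg^-1 K^-1).
#'
#' @param rh relative humidity as a fraction in `[0, 1]`.
#' @param temperature air temperature, degC (used when `saturation_content`
#'   is not given).
#' @param saturation_content saturation water-vapour content at the ambient
#'   temperature, g/m^3.
#' @return absolute humidity, g/m^3.
#' @export
#' @examples
#' absolute_humidity(0.49, saturation_content = 19.41)  # 9.51
#' absolute_humidity(1, temperature = 22)               # ~19.4
absolute_humidity <- function(rh, temperature = NULL,
                              saturation_content = NULL) {
  check_finite(rh, "rh")
  if (any(rh < 0 | rh > 1)) stopf("'rh' must be a fraction in [0, 1]")
  if (!is.null(saturation_content)) {
    check_scalar(saturation_content, "saturation_content", lower = 0)
    return(rh * saturation_content)
  }
  if (is.null(temperature))
    stopf("provide either 'temperature' or 'saturation_content'")
  check_scalar(temperature, "temperature", lower = -273.15,
               strict_lower = TRUE)
  es_hpa <- 6.1094 * exp(17.625 * temperature / (temperature + 243.04))
  rho_sat <- es_hpa * 100 / (461.5 * (temperature + 273.15)) * 1000  # g/m^3
  rh * rho_sat
}
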