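# internal helpers ----------------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stopf("'%s' must be finite numeric (got %s)", name,
          paste(utils::head(x, 3), collapse = ", "))
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (length(x) != 1L) stopf("'%s' must be a single value", name)
  check_finite(x, name)
  ok <- if (strict_lower) x > lower else x >= lower
  ok <- ok && if (strict_upper) x < upper else x <= upper
  if (!ok) stopf("'%s' = %g is outside the admissible range", name, x)
  invisible(x)
}

#' Wrap an angle onto the line-angle range (-90, 90] degrees
#'
#' Orientations of undirected lines are only defined modulo 180 degrees; this
#' maps any angle in degrees onto the half-open interval (-90, 90].
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector in (-90, 90].
#' @keywords internal
wrap_line_angle <- function(deg) {
  r <- ((deg + 90) %% 180) - 90
  r[r == -90] <- 90
  r
}

# format a numeric for byte-stable text export (12 significant digits
# round-trip exactly through parse-and-reformat)
fmt_num <- function(x) sprintf("%.12g", x)

# data.frame constructor without the deparse/validation overhead of
# data.frame(); columns must be equal-length atomic vectors
fast_df <- function(...) {
  lst <- list(...)
  structure(lst, row.names = c(NA_integer_, -length(lst[[1]])),
            class = "data.frame")
}
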