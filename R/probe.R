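#' Probe geometry
#'
#' Describes the AFM tip used for indentation: a sphere (colloidal probe, as
#' used for glycocalyx measurements) or a four-sided pyramid (sharp mapping
#' tip). Exactly the fields of the active kind are stored.
#'
#' @param kind `"sphere"` or `"pyramid"`.
#' @param radius Sphere radius in micrometres (sphere only). The default,
#'   1.25 um, is a typical colloidal glass probe.
#' @param face_half_angle Pyramid face half-angle in degrees (pyramid only);
#'   must lie strictly between 0 and 90.
#' @return An object of class `probe_geometry`.
#' @examples
#' probe_geometry("sphere", radius = 1.25)
#' probe_geometry("pyramid", face_half_angle = 17.5)
#' @export
probe_geometry <- function(kind = c("sphere", "pyramid"), radius = NULL,
                           face_half_angle = NULL) {
  kind <- match.arg(kind)
  if (kind == "sphere") {
    if (is.null(radius)) radius <- 1.25
    if (!is.null(face_half_angle))
      stop("face_half_angle applies to pyramid probes only")
    if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
        radius <= 0)
      stop("sphere probe requires a single positive radius (um)")
    out <- list(kind = kind, radius = radius)
  } else {
    if (is.null(face_half_angle)) face_half_angle <- 17.5
    if (!is.null(radius)) stop("radius applies to sphere probes only")
    if (!is.numeric(face_half_angle) || length(face_half_angle) != 1L ||
        !is.finite(face_half_angle) ||
        face_half_angle <= 0 || face_half_angle >= 90)
      stop("pyramid probe requires 0 < face_half_angle < 90 degrees")
    out <- list(kind = kind, face_half_angle = face_half_angle)
  }
  structure(out, class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  if (x$kind == "sphere")
    cat(sprintf("AFM probe: sphere, radius %.3g um\n", x$radius))
  else
    cat(sprintf("AFM probe: pyramid, face half-angle %.3g deg\n",
                x$face_half_angle))
  invisible(x)
}

#' Cantilever calibration
#'
#' @param spring_constant Cantilever spring constant in N/m; must be positive.
#'   The default 0.02 N/m corresponds to a soft cantilever suitable for
#'   glycocalyx force spectroscopy.
#' @param deflection_offset Deflection zero offset, nm.
#' @param baseline_slope Residual force-per-piezo-distance slope (pN/nm)
#'   remaining after optical calibration; removed by [correct_baseline()].
#' @return An object of class `cantilever_calibration`.
#' @export
cantilever_calibration <- function(spring_constant = 0.02,
                                   deflection_offset = 0,
                                   baseline_slope = 0) {
  if (!is.numeric(spring_constant) || length(spring_constant) != 1L ||
      !is.finite(spring_constant) || spring_constant <= 0)
    stop("spring_constant must be a single positive number (N/m)")
  structure(list(spring_constant = spring_constant,
                 deflection_offset = deflection_offset,
                 baseline_slope = baseline_slope),
            class = "cantilever_calibration")
}

#' @export
print.cantilever_calibration <- function(x, ...) {
  cat(sprintf("Cantilever: k = %.4g N/m\n", x$spring_constant))
  invisible(x)
}

# spring constant in pN per nm of deflection (1 N/m = 1000 pN/nm)
k_pn_per_nm <- function(calibration) calibration$spring_constant * 1000
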