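#' Build a quasi-uniform radial magnetometer helmet
#'
#' Places sensors on the upper portion of a sphere concentric with the
#' conductor using a Fibonacci spiral, which gives a quasi-uniform
#' angular coverage for any sensor count. Sensor orientations are exactly
#' radial, as for an idealised whole-head magnetometer array.
#'
#' @param n_sensors number of channels (default 151).
#' @param helmet_coverage fraction of the full sphere covered, measured
#'   from the top pole (default 0.45: from the vertex down to slightly
#'   above the equatorial rim). Must lie in (0, 1].
#' @param sphere_center conductor centre, metres.
#' @param sphere_radius helmet radius, metres (default 0.10: a 1 cm
#'   standoff from the 0.09 m conductor surface, typical of the gap
#'   between scalp and dewar in whole-head systems).
#' @return An object of class `dba_sensor_array` with `positions`,
#'   `orientations` (radial unit vectors), `sphere_center`, `sphere_radius`.
#' @export
build_sensors <- function(n_sensors = 151, helmet_coverage = 0.45,
                          sphere_center = c(0, 0, 0), sphere_radius = 0.10) {
  if (n_sensors < 1) stop("n_sensors must be positive")
  if (helmet_coverage <= 0 || helmet_coverage > 1)
    stop("parameter error: helmet_coverage must be in (0, 1]")
  i <- seq_len(n_sensors) - 0.5
  z <- 1 - (i / n_sensors) * 2 * helmet_coverage
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z)
  positions <- sweep(dirs * sphere_radius, 2, sphere_center, "+")
  structure(list(positions = positions, orientations = dirs,
                 sphere_center = sphere_center,
                 sphere_radius = sphere_radius),
            class = "dba_sensor_array")
}

#' @export
print.dba_sensor_array <- function(x, ...) {
  cat("Sensor array:", nrow(x$positions),
      "radial magnetometers at", x$sphere_radius, "m\n")
  invisible(x)
}
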