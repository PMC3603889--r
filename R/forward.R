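#' Magnetic field of a current dipole in a spherical conductor
#'
#' Evaluates the analytic solution for the magnetic field of a current
#' dipole inside a homogeneous conducting sphere (Sarvas formula) and
#' projects it onto each sensor's orientation. For exactly radial sensor
#' orientations this reduces to the free-space radial component, because
#' volume currents in a spherical conductor produce no radial field; the
#' full formula is used so that arbitrary sensor orientations are
#' supported behind the same interface.
#'
#' @param source_pos 3-vector, metres, strictly inside the conductor.
#' @param moment 3-vector dipole moment, A m.
#' @param sensors a [build_sensors()] array; its `sphere_center` defines
#'   the conductor centre.
#' @return Numeric vector of per-sensor projected fields, Tesla.
#' @export
dipole_field <- function(source_pos, moment, sensors) {
  ctr <- sensors$sphere_center
  r0 <- as.numeric(source_pos) - ctr
  ecc <- sqrt(sum(r0^2))
  rs <- sweep(sensors$positions, 2, ctr)
  rad <- row_norms(rs)
  if (ecc >= min(rad)) stop("domain error: source not inside sensor sphere")
  B <- sarvas_field(r0, as.numeric(moment), rs)
  rowSums(B * sensors$orientations)
}

## Sarvas (1987) closed-form field of a current dipole q at r0 inside a
## conducting sphere centred at the origin, evaluated at rows of rs.
sarvas_field <- function(r0, q, rs) {
  n <- nrow(rs)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (all(qxr0 == 0)) return(matrix(0, n, 3))
  a_vec <- sweep(rs, 2, r0)          # r - r0
  a <- row_norms(a_vec)
  r <- row_norms(rs)
  adotr <- rowSums(a_vec * rs)
  FF <- a * (r * a + r^2 - rowSums(rs * matrix(r0, n, 3, byrow = TRUE)))
  c1 <- a^2 / r + adotr / a + 2 * a + 2 * r
  c2 <- a + 2 * r + adotr / a
  gradF <- rs * c1 - matrix(r0, n, 3, byrow = TRUE) * c2
  qxr0_dot_r <- rowSums(rs * matrix(qxr0, n, 3, byrow = TRUE))
  (MU0_OVER_4PI / FF^2) *
    (FF * matrix(qxr0, n, 3, byrow = TRUE) - qxr0_dot_r * gradF)
}

#' Compute the lead-field (gain) matrix
#'
#' Column i of the fixed-orientation gain is the sensor field of a unit
#' dipole (1 A m) at position i along the stored orientation. The
#' free-orientation gain stacks three columns (x, y, z moment components)
#' per source and is the input to [depth_weights()].
#'
#' @param space a `dba_source_space`.
#' @param sensors a `dba_sensor_array`.
#' @param orientation `"fixed"` (default) or `"free"`.
#' @return An object of class `dba_gain`: list with `values`
#'   (sensors x sources, Tesla per A m; sensors x 3*sources when free),
#'   `orientation`, and the number of sources `n_sources`.
#' @export
compute_gain <- function(space, sensors, orientation = c("fixed", "free")) {
  orientation <- match.arg(orientation)
  ctr <- sensors$sphere_center
  pos <- sweep(space$positions, 2, ctr)
  outside <- row_norms(sweep(space$positions, 2, space$conductor$center)) >=
    space$conductor$radius
  if (any(outside))
    stop("domain error: dipoles outside conductor at indices ",
         paste(utils::head(which(outside), 5), collapse = ", "))
  n_src <- nrow(pos)
  n_sen <- nrow(sensors$positions)
  rs <- sweep(sensors$positions, 2, ctr)
  if (orientation == "fixed") {
    values <- matrix(0, n_sen, n_src)
    for (i in seq_len(n_src)) {
      B <- sarvas_field(pos[i, ], space$orientations[i, ], rs)
      values[, i] <- rowSums(B * sensors$orientations)
    }
  } else {
    values <- matrix(0, n_sen, 3L * n_src)
    ex <- diag(3)
    for (i in seq_len(n_src)) for (k in 1:3) {
      B <- sarvas_field(pos[i, ], ex[k, ], rs)
      values[, 3L * (i - 1L) + k] <- rowSums(B * sensors$orientations)
    }
  }
  structure(list(values = values, orientation = orientation,
                 n_sources = n_src), class = "dba_gain")
}

gain_values <- function(G) {
  if (inherits(G, "dba_gain")) G$values else as.matrix(G)
}

#' Sensor-space sensitivity of each source
#'
#' The root-mean-square over sensors of each gain column: how strongly a
#' unit source at that location contributes to the array. Deep and
#' quasi-radial sources have low sensitivity.
#'
#' @param G a gain matrix from [compute_gain()] (fixed orientation).
#' @param normalize if `TRUE`, divide by the maximum value.
#' @return An object of class `dba_sensitivity`: list with `values`
#'   (one non-negative scalar per source) and `normalized`.
#' @export
sensitivity_map <- function(G, normalize = FALSE) {
  g <- gain_values(G)
  if (length(g) == 0) stop("gain matrix is empty")
  v <- sqrt(colMeans(g^2))
  if (normalize) v <- v / max(v)
  structure(list(values = v, normalized = normalize),
            class = "dba_sensitivity")
}
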