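## Shared fixtures, built once per test run and memoised.

.fx <- new.env()

## compact anatomy for most tests (~1300 sources)
test_space <- function() {
  if (is.null(.fx$sp))
    .fx$sp <- build_anatomy(default_structure_specs(), mesh_resolution = 0.5,
                            grid_spacing = 0.004, seed = 1)
  .fx$sp
}

test_sensors <- function() {
  if (is.null(.fx$sen)) .fx$sen <- build_sensors()
  .fx$sen
}

test_gain <- function() {
  if (is.null(.fx$G)) .fx$G <- compute_gain(test_space(), test_sensors())
  .fx$G
}

test_gain_free <- function() {
  if (is.null(.fx$Gf))
    .fx$Gf <- compute_gain(test_space(), test_sensors(), "free")
  .fx$Gf
}

test_noise_cov <- function() {
  if (is.null(.fx$C)) {
    noise <- generate_noise(noise_model(seed = 3), 151, 0.5)
    .fx$C <- estimate_noise_cov(noise[, 1:250])
  }
  .fx$C
}

## the three kernels at the default w = 0.6, snr_reg = 3
test_kernels <- function() {
  if (is.null(.fx$K)) {
    Kw <- wmne_kernel(test_gain(), test_noise_cov(),
                      depth_weights(test_gain_free(), 0.6))
    .fx$K <- list(wmne = Kw,
                  dspm = dspm_kernel(Kw, test_noise_cov()),
                  sloreta = sloreta_kernel(Kw, test_gain()))
  }
  .fx$K
}

## hand-built uniform source spaces for exact patch arithmetic:
## surface grids have 1 mm^2 elements, volume grids 10 mm^3 elements
uniform_space <- function(kind = c("surface", "volume"), n_side = 30,
                          dmd = 0.4) {
  kind <- match.arg(kind)
  spacing <- if (kind == "surface") 0.001 else 0.0021544347
  elem <- if (kind == "surface") 1 else 10   # mm^2 / mm^3
  ij <- expand.grid(i = seq_len(n_side), j = seq_len(n_side))
  pos <- cbind((ij$i - (n_side + 1) / 2) * spacing,
               (ij$j - (n_side + 1) / 2) * spacing,
               0.02)
  n <- nrow(pos)
  idx <- function(i, j) (j - 1L) * n_side + i
  adj <- vector("list", n)
  for (r in seq_len(n)) {
    i <- ij$i[r]; j <- ij$j[r]
    nb <- c(if (i > 1) idx(i - 1, j), if (i < n_side) idx(i + 1, j),
            if (j > 1) idx(i, j - 1), if (j < n_side) idx(i, j + 1))
    adj[[r]] <- nb
  }
  extent <- n * elem / if (kind == "surface") 100 else 1000
  structure(list(
    positions = pos,
    orientations = matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE),
    element_sizes = rep(elem, n),
    structure_labels = rep("uniform", n),
    adjacency = adj, triangles = list(),
    structures = data.frame(name = "uniform", geometry_kind = kind,
                            cell_type = "open",
                            orientation_rule = "surface_normal",
                            dmd = dmd, target_extent = extent,
                            first = 1L, last = n,
                            stringsAsFactors = FALSE),
    conductor = list(center = c(0, 0, 0), radius = 0.09)),
    class = "dba_source_space")
}

## independent mesh-area oracle: total area straight from the triangles
triangle_area_total <- function(space, name) {
  tr <- space$triangles[[name]]
  p1 <- space$positions[tr[, 1], , drop = FALSE]
  p2 <- space$positions[tr[, 2], , drop = FALSE]
  p3 <- space$positions[tr[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(0.5 * sqrt(rowSums(cr^2)))
}

## closed-form radial-field oracle: in a spherical conductor, volume
## currents contribute no radial field, so the radial projection equals
## the free-space dipole term mu0/4pi [q x (r - r0)] . r_hat / |r - r0|^3
radial_field_oracle <- function(source_pos, moment, sensors) {
  vapply(seq_len(nrow(sensors$positions)), function(i) {
    d <- sensors$positions[i, ] - source_pos
    b <- 1e-7 * c(moment[2] * d[3] - moment[3] * d[2],
                  moment[3] * d[1] - moment[1] * d[3],
                  moment[1] * d[2] - moment[2] * d[1]) / sum(d^2)^1.5
    sum(b * sensors$orientations[i, ])
  }, numeric(1))
}
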