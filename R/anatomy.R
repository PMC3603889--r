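#' Define a source structure
#'
#' A structure specification couples a geometric primitive (a wavy
#' spherical-cap sheet standing in for neocortex, a curved tube for the
#' hippocampal envelope, or an ellipsoidal voxel grid for a deep nucleus)
#' with its electrophysiological parameters: the cell-field type, the
#' dipole orientation rule and the dipole moment density (DMD).
#'
#' @param name character label, unique within an anatomy.
#' @param geometry_kind `"surface"` or `"volume"`.
#' @param cell_type `"open"` or `"closed"`: whether the summed dendritic
#'   currents of the population produce a non-vanishing external field.
#' @param orientation_rule `"surface_normal"`, `"random"` or
#'   `"principal_axis"`. Surface structures must use `"surface_normal"`;
#'   closed-field structures must use `"random"`.
#' @param dmd dipole moment density: nAm per mm^2 for surfaces, nAm per
#'   0.01 cm^3 for volumes. Must be positive.
#' @param target_extent total area (cm^2) or volume (cm^3) of the structure.
#' @param geometry list of geometric parameters understood by
#'   [build_anatomy()]; see [default_structure_specs()] for examples.
#' @return An object of class `dba_structure_spec`.
#' @export
structure_spec <- function(name, geometry_kind, cell_type, orientation_rule,
                           dmd, target_extent, geometry) {
  geometry_kind <- match.arg(geometry_kind, c("surface", "volume"))
  cell_type <- match.arg(cell_type, c("open", "closed"))
  orientation_rule <- match.arg(orientation_rule,
                                c("surface_normal", "random", "principal_axis"))
  if (!is.numeric(dmd) || dmd <= 0) stop("dmd must be positive")
  if (!is.numeric(target_extent) || target_extent <= 0)
    stop("target_extent must be positive")
  if (geometry_kind == "surface" && orientation_rule != "surface_normal")
    stop("surface structures must use the surface_normal orientation rule")
  if (cell_type == "closed" && orientation_rule != "random")
    stop("closed-field structures must use the random orientation rule")
  structure(list(name = name, geometry_kind = geometry_kind,
                 cell_type = cell_type, orientation_rule = orientation_rule,
                 dmd = dmd, target_extent = target_extent,
                 geometry = geometry),
            class = "dba_structure_spec")
}

#' Default synthetic deep-brain anatomy specifications
#'
#' Five structures emulating a left-hemisphere source model: a neocortex
#' analog (wavy spherical-cap sheet, 750 cm^2, DMD 0.25 nAm/mm^2), a
#' hippocampus analog (curved tube surface at about 65% of the conductor
#' radius, 15 cm^2, DMD 0.4 nAm/mm^2), an amygdala analog (1 cm^3 ellipsoid
#' grid, DMD 1 nAm/0.01 cm^3, randomly oriented open-field cells), a
#' thalamus analog (8 cm^3, DMD 0.025, closed-field) and a putamen analog
#' (9 cm^3, DMD 0.25, closed-field).
#'
#' @return List of [structure_spec()] objects.
#' @export
default_structure_specs <- function() {
  list(
    structure_spec("cortex", "surface", "open", "surface_normal",
                   dmd = 0.25, target_extent = 750,
                   geometry = list(type = "wavy_cap", base_radius = 0.080,
                                   theta_min = 0.15, theta_max = 2.0,
                                   wave_amp_rel = 0.12, wave_k = 9, wave_m = 10)),
    structure_spec("hippocampus", "surface", "open", "surface_normal",
                   dmd = 0.4, target_extent = 15,
                   geometry = list(type = "tube", sphere_radius = 0.058,
                                   u = c(0.6, 0.5, 0.35), w = c(-0.3, 0.6, 0.2),
                                   arc_span = c(-0.52, 0.52),
                                   tube_radius = 0.004)),
    structure_spec("amygdala", "volume", "open", "random",
                   dmd = 1, target_extent = 1,
                   geometry = list(type = "ellipsoid",
                                   center = c(0.006, 0.004, -0.016),
                                   semiaxes = c(0.008, 0.007, 0.0065))),
    structure_spec("thalamus", "volume", "closed", "random",
                   dmd = 0.025, target_extent = 8,
                   geometry = list(type = "ellipsoid",
                                   center = c(0.0093, 0.0011, 0.0046),
                                   semiaxes = c(0.0145, 0.0135, 0.0125))),
    structure_spec("putamen", "volume", "closed", "random",
                   dmd = 0.25, target_extent = 9,
                   geometry = list(type = "ellipsoid",
                                   center = c(-0.0162, 0.0104, 0.0051),
                                   semiaxes = c(0.0150, 0.0138, 0.0128)))
  )
}

## ---- surface mesh primitives -----------------------------------------

## wavy spherical cap: theta x phi grid, radius modulated by a smooth wave
mesh_wavy_cap <- function(g, mesh_resolution, jitter, rng_jitter) {
  nt <- max(4L, round(42 * mesh_resolution))
  np <- max(8L, round(84 * mesh_resolution))
  theta <- seq(g$theta_min, g$theta_max, length.out = nt)
  phi <- seq(0, 2 * pi, length.out = np + 1L)[-(np + 1L)]
  th <- rep(theta, each = np)
  ph <- rep(phi, times = nt)
  ## azimuthal ridges emulate gyral folding (normals tilt tangentially);
  ## wave_m > 0 adds a polar modulation on top of the ridges
  wave <- g$wave_amp_rel * sin(g$wave_k * ph)
  if (g$wave_m > 0)
    wave <- wave * sin(g$wave_m * (th - g$theta_min))
  r <- g$base_radius * (1 + wave)
  if (jitter > 0) r <- r * (1 + jitter * rng_jitter(length(r)))
  verts <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  idx <- function(i, j) (i - 1L) * np + ((j - 1L) %% np) + 1L
  tri <- vector("list", (nt - 1L) * np * 2L)
  k <- 0L
  for (i in seq_len(nt - 1L)) for (j in seq_len(np)) {
    k <- k + 1L; tri[[k]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    k <- k + 1L; tri[[k]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  list(vertices = verts, triangles = do.call(rbind, tri),
       outward = verts)  # radial hint
}

## curved tube: great-circle arc centerline on a sphere of given radius,
## circular cross-section swept with a stable in-plane frame
mesh_tube <- function(g, mesh_resolution, jitter, rng_jitter) {
  ns <- max(8L, round(30 * mesh_resolution)) + 1L
  nc <- max(8L, round(17 * mesh_resolution))
  u <- g$u / sqrt(sum(g$u^2))
  w <- g$w - sum(g$w * u) * u
  v <- w / sqrt(sum(w^2))
  s <- seq(g$arc_span[1], g$arc_span[2], length.out = ns)
  center <- t(vapply(s, function(si)
    g$sphere_radius * (cos(si) * u + sin(si) * v), numeric(3)))
  tangent <- t(vapply(s, function(si) -sin(si) * u + cos(si) * v, numeric(3)))
  binorm <- rbind(rep(u[2] * v[3] - u[3] * v[2], ns),
                  rep(u[3] * v[1] - u[1] * v[3], ns),
                  rep(u[1] * v[2] - u[2] * v[1], ns))
  binorm <- t(binorm)
  radial <- normalize_rows(center)   # in-plane outward
  ang <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  a <- g$tube_radius
  verts <- matrix(0, ns * nc, 3)
  outward <- matrix(0, ns * nc, 3)
  for (i in seq_len(ns)) {
    ring_dir <- outer(cos(ang), radial[i, ]) + outer(sin(ang), binorm[i, ])
    rr <- a
    if (jitter > 0) rr <- a * (1 + jitter * rng_jitter(nc))
    rows <- (i - 1L) * nc + seq_len(nc)
    verts[rows, ] <- matrix(center[i, ], nc, 3, byrow = TRUE) + rr * ring_dir
    outward[rows, ] <- ring_dir
  }
  idx <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  tri <- vector("list", (ns - 1L) * nc * 2L)
  k <- 0L
  for (i in seq_len(ns - 1L)) for (j in seq_len(nc)) {
    k <- k + 1L; tri[[k]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    k <- k + 1L; tri[[k]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  list(vertices = verts, triangles = do.call(rbind, tri), outward = outward)
}

## per-vertex areas (one third of each incident triangle) and area-weighted
## vertex normals, flipped towards the supplied outward hints
mesh_vertex_geometry <- function(vertices, triangles, outward) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cross_rows(p2 - p1, p3 - p1)
  tri_area <- 0.5 * row_norms(cr)
  n <- nrow(vertices)
  areas <- numeric(n)
  normals <- matrix(0, n, 3)
  for (k in 1:3) {
    vi <- triangles[, k]
    areas <- areas + unname(tapply(tri_area, factor(vi, levels = seq_len(n)),
                                   sum, default = 0)) / 3
    for (d in 1:3)
      normals[, d] <- normals[, d] +
        unname(tapply(cr[, d], factor(vi, levels = seq_len(n)), sum,
                      default = 0))
  }
  normals <- normalize_rows(normals)
  flip <- rowSums(normals * outward) < 0
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  list(areas = areas, normals = normals, total_area = sum(tri_area))
}

## symmetric adjacency list from triangle edges
mesh_adjacency <- function(triangles, n) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(1, 3)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(n)))
}

## ---- volume grid primitive -------------------------------------------

## regular grid filling an ellipsoid; keeps exactly the n voxels closest to
## the centre in the ellipsoid norm so the total volume matches the target
grid_ellipsoid <- function(g, target_mm3, spacing) {
  vox <- (spacing * 1e3)^3            # mm^3 per voxel
  n_keep <- round(target_mm3 / vox)
  if (n_keep < 1) stop("sizing error: target volume below one voxel")
  if (abs(n_keep * vox - target_mm3) / target_mm3 > 0.05)
    stop("sizing error: grid spacing cannot match target volume within 5%")
  half <- ceiling(max(g$semiaxes) / spacing) + 1L
  ii <- seq(-half, half)
  coords <- as.matrix(expand.grid(ix = ii, iy = ii, iz = ii))
  pos <- coords * spacing
  pos <- sweep(pos, 2, g$center, "+")
  enorm <- sqrt(((pos[, 1] - g$center[1]) / g$semiaxes[1])^2 +
                ((pos[, 2] - g$center[2]) / g$semiaxes[2])^2 +
                ((pos[, 3] - g$center[3]) / g$semiaxes[3])^2)
  ord <- order(enorm, seq_along(enorm))
  if (enorm[ord[n_keep]] > 1.25)
    stop("sizing error: ellipsoid too small for target volume at this spacing")
  keep <- sort(ord[seq_len(n_keep)])
  pos <- pos[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]
  ## 6-connectivity among kept voxels
  key <- function(cc) paste(cc[, 1], cc[, 2], cc[, 3])
  lut <- seq_len(n_keep)
  names(lut) <- key(coords)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  adj <- vector("list", n_keep)
  for (o in seq_len(6)) {
    nb <- lut[key(sweep(coords, 2, offs[o, ], "+"))]
    ok <- !is.na(nb)
    for (i in which(ok)) adj[[i]] <- c(adj[[i]], unname(nb[i]))
  }
  list(positions = pos, voxel_mm3 = vox, adjacency = lapply(adj, sort))
}

## ---- anatomy assembly ------------------------------------------------

#' Build a synthetic deep-brain source space
#'
#' Assembles the surface and volume structures of `specs` into one
#' contiguous source space inside a spherical conductor. Surface meshes are
#' rescaled about their centroid so that their total area matches the
#' requested extent exactly; volume grids keep exactly the number of voxels
#' that realises the target volume. Orientation rules are applied per
#' structure: surface normals for sheets, seeded uniform random unit
#' vectors for unoriented nuclei, and the dominant eigenvector of the
#' position covariance for principal-axis nuclei.
#'
#' @param specs list of [structure_spec()] objects.
#' @param conductor list with `center` (3-vector, metres) and `radius`
#'   (metres). Default: origin, 0.09 m.
#' @param mesh_resolution positive scale factor for surface mesh density.
#' @param grid_spacing voxel spacing for volume grids, metres (default 2 mm).
#' @param jitter relative vertex jitter amplitude used to emulate
#'   inter-individual anatomical variability (default 0).
#' @param seed RNG seed controlling random orientations and jitter.
#' @return An object of class `dba_source_space` with fields `positions`
#'   (n x 3, metres), `orientations` (n x 3, unit), `element_sizes`
#'   (mm^2 for surface dipoles, mm^3 for volume dipoles),
#'   `structure_labels`, `adjacency`, `triangles`, `structures`
#'   (per-structure table) and `conductor`.
#' @export
build_anatomy <- function(specs, conductor = list(center = c(0, 0, 0),
                                                  radius = 0.09),
                          mesh_resolution = 1, grid_spacing = 0.002,
                          jitter = 0, seed = 1L) {
  if (length(specs) == 0) stop("specs must be non-empty")
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("structure names must be unique")
  with_seed(seed, {
    rng_jitter <- function(n) stats::runif(n, -1, 1)
    parts <- vector("list", length(specs))
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      if (sp$geometry_kind == "surface") {
        mesh <- switch(sp$geometry$type,
                       wavy_cap = mesh_wavy_cap(sp$geometry, mesh_resolution,
                                                jitter, rng_jitter),
                       tube = mesh_tube(sp$geometry, mesh_resolution,
                                        jitter, rng_jitter),
                       stop("unknown surface geometry type: ", sp$geometry$type))
        geomv <- mesh_vertex_geometry(mesh$vertices, mesh$triangles,
                                      mesh$outward)
        ## exact extent: area scales with the square of an isotropic rescale.
        ## Caps scale about the conductor centre (pure radial rescale keeps
        ## the sheet spherical); tubes scale about their own centroid so
        ## their depth is preserved.
        target_mm2 <- sp$target_extent * 100
        fac <- sqrt(target_mm2 / (geomv$total_area * 1e6))
        ctr <- if (identical(sp$geometry$type, "wavy_cap")) conductor$center
               else colMeans(mesh$vertices)
        mesh$vertices <- sweep(sweep(mesh$vertices, 2, ctr), 2, ctr / fac, "+") * fac
        geomv <- mesh_vertex_geometry(mesh$vertices, mesh$triangles,
                                      mesh$outward)
        parts[[si]] <- list(
          positions = mesh$vertices, orientations = geomv$normals,
          element_sizes = geomv$areas * 1e6,  # m^2 -> mm^2
          adjacency = mesh_adjacency(mesh$triangles, nrow(mesh$vertices)),
          triangles = mesh$triangles)
      } else {
        gr <- grid_ellipsoid(sp$geometry, sp$target_extent * 1000,
                             grid_spacing)
        n <- nrow(gr$positions)
        ori <- switch(sp$orientation_rule,
          random = normalize_rows(matrix(stats::rnorm(3 * n), n, 3)),
          principal_axis = {
            ev <- eigen(stats::cov(gr$positions), symmetric = TRUE)$vectors[, 1]
            if (ev[which.max(abs(ev))] < 0) ev <- -ev
            matrix(ev, n, 3, byrow = TRUE)
          },
          stop("volume structures use random or principal_axis orientation"))
        parts[[si]] <- list(positions = gr$positions, orientations = ori,
                            element_sizes = rep(gr$voxel_mm3, n),
                            adjacency = gr$adjacency, triangles = NULL)
      }
    }
    assemble_source_space(specs, parts, conductor)
  })
}

assemble_source_space <- function(specs, parts, conductor) {
  ns <- vapply(parts, function(p) nrow(p$positions), integer(1))
  offset <- c(0L, cumsum(ns))[seq_along(ns)]
  positions <- do.call(rbind, lapply(parts, `[[`, "positions"))
  orientations <- do.call(rbind, lapply(parts, `[[`, "orientations"))
  element_sizes <- unlist(lapply(parts, `[[`, "element_sizes"), use.names = FALSE)
  labels <- rep(vapply(specs, `[[`, character(1), "name"), times = ns)
  adjacency <- vector("list", sum(ns))
  triangles <- list()
  for (si in seq_along(parts)) {
    off <- offset[si]
    adj <- parts[[si]]$adjacency
    for (i in seq_along(adj)) adjacency[[off + i]] <- adj[[i]] + off
    if (!is.null(parts[[si]]$triangles))
      triangles[[specs[[si]]$name]] <- parts[[si]]$triangles + off
  }
  depth_in <- conductor$radius -
    row_norms(sweep(positions, 2, conductor$center))
  if (any(depth_in <= 0))
    stop("geometry error: dipoles on or outside the conductor sphere at ",
         "indices ", paste(utils::head(which(depth_in <= 0), 5), collapse = ", "))
  structures <- data.frame(
    name = vapply(specs, `[[`, character(1), "name"),
    geometry_kind = vapply(specs, `[[`, character(1), "geometry_kind"),
    cell_type = vapply(specs, `[[`, character(1), "cell_type"),
    orientation_rule = vapply(specs, `[[`, character(1), "orientation_rule"),
    dmd = vapply(specs, `[[`, numeric(1), "dmd"),
    target_extent = vapply(specs, `[[`, numeric(1), "target_extent"),
    first = offset + 1L, last = offset + ns,
    stringsAsFactors = FALSE)
  space <- structure(list(positions = positions, orientations = orientations,
                          element_sizes = element_sizes,
                          structure_labels = labels, adjacency = adjacency,
                          triangles = triangles, structures = structures,
                          conductor = conductor),
                     class = "dba_source_space")
  check_structure_overlap(space)
  space
}

## minimum pairwise distance between structures must stay positive
check_structure_overlap <- function(space, min_gap = 5e-4) {
  st <- space$structures
  for (a in seq_len(nrow(st) - 1L)) for (b in (a + 1L):nrow(st)) {
    pa <- space$positions[st$first[a]:st$last[a], , drop = FALSE]
    pb <- space$positions[st$first[b]:st$last[b], , drop = FALSE]
    ## bounding-box prefilter
    if (any(apply(pa, 2, min) > apply(pb, 2, max) + min_gap) ||
        any(apply(pb, 2, min) > apply(pa, 2, max) + min_gap)) next
    d2min <- Inf
    for (i in seq_len(nrow(pa))) {
      d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2 +
        (pb[, 3] - pa[i, 3])^2
      d2min <- min(d2min, min(d2))
      if (d2min < min_gap^2) break
    }
    if (d2min < min_gap^2)
      stop("geometry error: structures ", st$name[a], " and ", st$name[b],
           " overlap or nearly touch")
  }
  invisible(space)
}

#' @export
print.dba_source_space <- function(x, ...) {
  cat("Synthetic source space:", nrow(x$positions), "dipoles,",
      nrow(x$structures), "structures\n")
  st <- x$structures
  for (i in seq_len(nrow(st))) {
    n <- st$last[i] - st$first[i] + 1L
    unit <- if (st$geometry_kind[i] == "surface") "cm^2" else "cm^3"
    cat(sprintf("  %-12s %-7s %5d dipoles, %6.2f %s, DMD %.4g\n",
                st$name[i], st$geometry_kind[i], n,
                structure_extent(x, st$name[i]), unit, st$dmd[i]))
  }
  invisible(x)
}

#' Indices of the dipoles belonging to a structure
#' @param space a `dba_source_space`.
#' @param name structure name.
#' @return Integer vector of dipole indices.
#' @export
structure_indices <- function(space, name) {
  st <- space$structures
  i <- match(name, st$name)
  if (is.na(i)) stop("unknown structure: ", name)
  st$first[i]:st$last[i]
}

#' Realised extent (cm^2 or cm^3) of a structure
#' @inheritParams structure_indices
#' @return Total area in cm^2 (surface) or volume in cm^3 (volume).
#' @export
structure_extent <- function(space, name) {
  idx <- structure_indices(space, name)
  st <- space$structures
  kind <- st$geometry_kind[match(name, st$name)]
  sum(space$element_sizes[idx]) / if (kind == "surface") 100 else 1000
}

#' Dipole depths below the conductor surface
#' @param space a `dba_source_space`.
#' @return Numeric vector, metres, distance from each dipole to the
#'   conductor sphere surface.
#' @export
source_depths <- function(space) {
  space$conductor$radius -
    row_norms(sweep(space$positions, 2, space$conductor$center))
}
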