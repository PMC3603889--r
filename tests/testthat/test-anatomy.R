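test_that("structure specs enforce orientation and field-type rules", {
  expect_error(structure_spec("x", "surface", "open", "random", 1, 1, list()),
               "surface_normal")
  expect_error(structure_spec("x", "volume", "closed", "principal_axis",
                              1, 1, list()), "random")
  expect_error(structure_spec("x", "volume", "closed", "random", -1, 1,
                              list()), "dmd")
})

test_that("realised extents match targets and the independent mesh oracle", {
  sp <- test_space()
  ## hippocampus analog: 15 cm^2 target
  expect_gte(structure_extent(sp, "hippocampus"), 14.25)
  expect_lte(structure_extent(sp, "hippocampus"), 15.75)
  for (nm in sp$structures$name) {
    tgt <- sp$structures$target_extent[match(nm, sp$structures$name)]
    expect_lt(abs(structure_extent(sp, nm) - tgt) / tgt, 0.05)
  }
  ## element sizes conserve total mesh area computed from the triangles
  for (nm in c("cortex", "hippocampus")) {
    idx <- structure_indices(sp, nm)
    area_mm2 <- triangle_area_total(sp, nm) * 1e6
    expect_lt(abs(sum(sp$element_sizes[idx]) - area_mm2) / area_mm2, 1e-9)
  }
})

test_that("orientations are unit norm; surface dipoles follow vertex normals", {
  sp <- test_space()
  expect_lt(max(abs(sqrt(rowSums(sp$orientations^2)) - 1)), 1e-12)
  ## surface orientations are the vertex normals by construction: check
  ## they are orthogonal to the local mesh edges on average (outward, not
  ## anti-parallel to the radial hint)
  cx <- structure_indices(sp, "cortex")
  outward <- rowSums(sp$orientations[cx, ] *
                     sp$positions[cx, ] / sqrt(rowSums(sp$positions[cx, ]^2)))
  expect_true(all(outward > 0))
})

test_that("random orientations are uniform on the sphere (Rayleigh test)", {
  sp <- test_space()
  idx <- which(sp$structure_labels %in% c("thalamus", "putamen"))
  ori <- sp$orientations[idx, ]
  n <- nrow(ori)
  expect_gte(n, 200)
  rbar2 <- sum(colMeans(ori)^2)
  stat <- 3 * n * rbar2          # ~ chi^2(3) under uniformity
  expect_lt(stat, qchisq(0.99, df = 3))
})

test_that("adjacency is symmetric and confined to single structures", {
  sp <- test_space()
  for (i in seq(1, nrow(sp$positions), by = 17)) {
    for (j in sp$adjacency[[i]]) {
      expect_true(i %in% sp$adjacency[[j]])
      expect_identical(sp$structure_labels[i], sp$structure_labels[j])
    }
  }
})

test_that("all dipoles lie strictly inside the conductor, ordered by depth", {
  sp <- test_space()
  r <- sqrt(rowSums(sp$positions^2))
  expect_true(all(r < sp$conductor$radius))
  depth <- source_depths(sp)
  mdep <- function(nm) mean(depth[structure_indices(sp, nm)])
  nuclei <- mean(depth[sp$structure_labels %in%
                       c("amygdala", "thalamus", "putamen")])
  expect_gt(nuclei, mdep("hippocampus"))
  expect_gt(mdep("hippocampus"), mdep("cortex"))
})

test_that("anatomy is bit-reproducible for a fixed seed and varies with it", {
  specs <- default_structure_specs()[c(2, 4)]   # hippocampus + thalamus
  a <- build_anatomy(specs, grid_spacing = 0.005, seed = 7)
  b <- build_anatomy(specs, grid_spacing = 0.005, seed = 7)
  expect_identical(a$positions, b$positions)
  expect_identical(a$orientations, b$orientations)
  d <- build_anatomy(specs, grid_spacing = 0.005, seed = 8)
  expect_false(identical(d$orientations, b$orientations))
  j <- build_anatomy(specs, grid_spacing = 0.005, seed = 7, jitter = 0.02)
  expect_false(identical(j$positions, b$positions))
})

test_that("overlapping structures raise a geometry error", {
  specs <- default_structure_specs()[4:5]
  specs[[2]]$geometry$center <- specs[[1]]$geometry$center
  expect_error(build_anatomy(specs, grid_spacing = 0.005, seed = 1),
               "overlap")
})

test_that("volume grids reject unreachable extents", {
  specs <- default_structure_specs()[3]
  specs[[1]]$geometry$semiaxes <- c(0.003, 0.003, 0.003)  # too small for 1 cm^3
  expect_error(build_anatomy(specs, grid_spacing = 0.002, seed = 1),
               "sizing error")
})

test_that("principal-axis nuclei align with the envelope's dominant axis", {
  spec <- structure_spec("lgn", "volume", "open", "principal_axis",
                         dmd = 0.25, target_extent = 0.2,
                         geometry = list(type = "ellipsoid",
                                         center = c(0.02, -0.015, 0),
                                         semiaxes = c(0.006, 0.003, 0.0025)))
  sp <- build_anatomy(list(spec), grid_spacing = 0.002, seed = 1)
  ori <- sp$orientations
  expect_true(all(abs(ori %*% ori[1, ] - 1) < 1e-12))  # all identical
  expect_gt(abs(ori[1, 1]), 0.95)   # dominant axis is x
})
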