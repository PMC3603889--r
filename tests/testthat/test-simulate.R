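test_that("patch growth on a uniform grid is exact and connected", {
  us <- uniform_space("surface", n_side = 30)   # 900 x 1 mm^2 cells
  seed <- 435                                    # near the middle
  p <- grow_patch(us, seed, 1)                   # 1 cm^2 -> 100 cells
  expect_length(p$member_indices, 100)
  expect_equal(p$total_extent, 1)
  expect_true(seed %in% p$member_indices)
  ## connectivity: every member reachable within the member set
  mem <- p$member_indices
  seen <- seed
  repeat {
    nb <- unique(unlist(us$adjacency[seen]))
    grown <- union(seen, intersect(nb, mem))
    if (length(grown) == length(seen)) break
    seen <- grown
  }
  expect_setequal(seen, mem)
})

test_that("tiny targets give singleton patches; big targets clamp with warning", {
  us <- uniform_space("surface")
  p <- grow_patch(us, 10, 0.001)     # below one element
  expect_length(p$member_indices, 1)
  expect_warning(p2 <- grow_patch(us, 10, 99), "whole structure")
  expect_length(p2$member_indices, nrow(us$positions))
})

test_that("patch extent error is bounded by the largest element", {
  sp <- test_space()
  for (seed in c(structure_indices(sp, "hippocampus")[20],
                 structure_indices(sp, "thalamus")[50])) {
    p <- grow_patch(sp, seed, 2)
    lab <- sp$structure_labels[seed]
    unit <- if (sp$structures$geometry_kind[
      match(lab, sp$structures$name)] == "surface") 100 else 1000
    max_elem <- max(sp$element_sizes[p$member_indices])
    expect_lte(abs(p$total_extent - 2) * unit, max_elem)
  }
})

test_that("patch currents follow the DMD scale convention", {
  ## surface: 1 cm^2 at DMD 0.4 -> 40 nAm total
  us <- uniform_space("surface", dmd = 0.4)
  p <- patch_currents(grow_patch(us, 435, 1), us)
  expect_equal(p$total_current, 40)
  expect_equal(p$currents, rep(0.4, 100))
  ## volume: 1 cm^3 at DMD 0.025 -> 2.5 nAm total
  uv <- uniform_space("volume", dmd = 0.025)
  pv <- patch_currents(grow_patch(uv, 435, 1), uv)
  expect_equal(pv$total_current, 2.5)
  ## empty patch -> zero total
  p0 <- p; p0$member_indices <- integer(0)
  expect_equal(patch_currents(p0, us)$total_current, 0)
})

test_that("gaussian envelope has unit peak and exact FWHM", {
  env <- gaussian_timecourse(30, peak_sample = 500, n_samples = 1000,
                             rate_hz = 1000)
  expect_equal(env[500], 1)
  expect_equal(env[515], 0.5)  # +15 ms at 1 kHz
  expect_equal(env[485], 0.5)
  expect_error(gaussian_timecourse(30, 2000, 1000, 1000), "parameter error")
  ## cortical-envelope ratio at the subcortical peak
  expect_equal(exp(-4 * log(2) * (15 / 30)^2), 0.5)
})

test_that("recordings superpose linearly and keep baseline silent", {
  sp <- test_space(); G <- test_gain()
  cfg <- sim_config(d_t_ms = 30, sampling_rate_hz = 1250)
  hip <- structure_indices(sp, "hippocampus")
  cx <- structure_indices(sp, "cortex")
  p1 <- patch_currents(grow_patch(sp, hip[30], 2), sp)
  p2 <- patch_currents(grow_patch(sp, cx[700], 3), sp)
  r12 <- simulate_recording(G, sp, list(p1, p2), NULL, cfg)
  r1 <- simulate_recording(G, sp, list(p1), NULL, cfg)
  ## single cortical patch placed at the subcortical slot on purpose:
  ## rebuild with the cortical peak by passing both but zero first
  p0 <- p1; p0$currents <- p1$currents * 0
  r2 <- simulate_recording(G, sp, list(p0, p2), NULL, cfg)
  expect_lt(max(abs(r12$data - (r1$data + r2$data))),
            1e-12 * max(abs(r12$data)))
  expect_true(all(r12$data[, r12$baseline_span] == 0))
  expect_equal(r12$r_c, exp(-4 * log(2) * (30 / 30)^2))
})

test_that("energy SNR is conserved exactly for every structure and size", {
  sp <- test_space(); G <- test_gain()
  noise <- generate_noise(noise_model(seed = 6), 151, 0.6)
  for (nm in sp$structures$name) {
    idx <- structure_indices(sp, nm)
    for (size in c(1, 3)) {
      p <- patch_currents(suppressWarnings(
        grow_patch(sp, idx[length(idx) %/% 2], size)), sp)
      cfg <- sim_config(snr_energy = 20, sampling_rate_hz = 1250)
      rec <- simulate_recording(G, sp, list(p), noise, cfg)
      ratio <- sum(rec$signal^2) / sum(rec$noise^2)
      expect_lt(abs(ratio - 20) / 20, 1e-6)
    }
  }
})

test_that("noiseless recordings are returned unscaled; silent patches error", {
  sp <- test_space(); G <- test_gain()
  hip <- structure_indices(sp, "hippocampus")
  p <- patch_currents(grow_patch(sp, hip[10], 1), sp)
  cfg <- sim_config(sampling_rate_hz = 1250)
  rec <- simulate_recording(G, sp, list(p), NULL, cfg)
  expect_equal(rec$scale, 1)
  q <- p$currents * 1e-9
  topo <- G$values[, p$member_indices, drop = FALSE] %*% q
  env <- gaussian_timecourse(cfg$fwhm_ms, rec$subcortical_peak_sample,
                             ncol(rec$data), 1250)
  env[rec$baseline_span] <- 0
  expect_equal(rec$data, topo %*% t(env))
  ## a silent (zero-current) patch cannot be scaled to a target SNR
  p0 <- p; p0$currents <- p$currents * 0
  noise <- generate_noise(noise_model(seed = 6), 151, 0.6)
  expect_error(simulate_recording(G, sp, list(p0), noise, cfg),
               "unscalable")
})

test_that("d_t = 60 ms fully separates the activations", {
  cfg <- sim_config(d_t_ms = 60)
  expect_lt(exp(-4 * log(2) * (cfg$d_t_ms / cfg$fwhm_ms)^2), 1e-4)
})
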