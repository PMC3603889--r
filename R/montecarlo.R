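#' Monte Carlo experiment grid
#'
#' Defines the full localization-error experiment: which structures are
#' swept, patch sizes, inverse methods, cortical-subcortical peak offsets
#' and the number of independent noise seeds (each seed emulating one
#' subject's resting-state background).
#'
#' @param structures character vector of structure names to sweep.
#' @param patch_sizes cm^2 / cm^3 (default 1:5).
#' @param methods subset of `c("wmne", "dspm", "sloreta")`.
#' @param d_t_values_ms peak offsets (default `c(0, 15, 30, 45, 60)`).
#' @param noise_seeds integer seeds, one per emulated subject (default
#'   `1:7`).
#' @param snr_energy activation-to-noise energy ratio (default 20).
#' @param seed_stride use every k-th dipole of each structure as a patch
#'   seed (default 1 = every dipole).
#' @param cortical_patch `NULL` for single-source runs, or a list with
#'   `seed_index` and `size` describing a cortical co-activation.
#' @param w depth-weighting exponent (default 0.6).
#' @param snr_reg regularization SNR (default 3).
#' @return Object of class `dba_grid`.
#' @export
experiment_grid <- function(structures, patch_sizes = 1:5,
                            methods = c("wmne", "dspm", "sloreta"),
                            d_t_values_ms = c(0, 15, 30, 45, 60),
                            noise_seeds = 1:7, snr_energy = 20,
                            seed_stride = 1L, cortical_patch = NULL,
                            w = 0.6, snr_reg = 3) {
  methods <- match.arg(methods, c("wmne", "dspm", "sloreta"),
                       several.ok = TRUE)
  if (length(structures) == 0 || length(patch_sizes) == 0)
    stop("grid must be non-empty")
  structure(list(structures = structures, patch_sizes = patch_sizes,
                 methods = methods, d_t_values_ms = d_t_values_ms,
                 noise_seeds = noise_seeds, snr_energy = snr_energy,
                 seed_stride = as.integer(seed_stride),
                 cortical_patch = cortical_patch, w = w,
                 snr_reg = snr_reg),
            class = "dba_grid")
}

## kernels for the three methods sharing one wMNE solution
build_kernels <- function(G, G_free, C, methods, w, snr_reg) {
  S <- depth_weights(G_free, w)
  Kw <- wmne_kernel(G, C, S, snr_reg)
  ks <- list()
  if ("wmne" %in% methods) ks$wmne <- Kw
  if ("dspm" %in% methods) ks$dspm <- dspm_kernel(Kw, C)
  if ("sloreta" %in% methods) ks$sloreta <- sloreta_kernel(Kw, G)
  ks
}

#' Run the Monte Carlo localization experiment
#'
#' For every noise seed, estimates the noise covariance from a baseline
#' segment, builds the three inverse kernels, and then for every seed
#' source, patch size and peak offset simulates a recording, applies each
#' kernel at the subcortical peak sample, and records both localization
#' errors plus (for two-source cells) the detection summary. Cell
#' failures are caught and recorded, never dropped silently.
#'
#' @param grid an [experiment_grid()].
#' @param space source space.
#' @param G,G_free fixed- and free-orientation gains.
#' @param nm a [noise_model()]; its seed field is overridden per subject
#'   seed.
#' @param config base [sim_config()]; `d_t_ms` and `snr_energy` are taken
#'   from the grid.
#' @param truth `"seed"` (default) or `"centroid"`: whether localization
#'   error is measured against the patch seed position or the
#'   current-weighted patch centroid.
#' @return Object of class `dba_mc_result`: `results` (one row per cell x
#'   method), `grid`, `failures`.
#' @export
run_grid <- function(grid, space, G, G_free, nm, config = sim_config(),
                     truth = c("seed", "centroid")) {
  truth <- match.arg(truth)
  config$snr_energy <- grid$snr_energy
  fs <- config$sampling_rate_hz
  nm$sampling_rate_hz <- fs
  dur <- (config$baseline_ms + config$post_ms) / 1000 + 0.1
  rows <- list()
  failures <- list()
  cort <- grid$cortical_patch
  cort_patch <- if (!is.null(cort)) {
    cp <- grow_patch(space, cort$seed_index, cort$size)
    patch_currents(cp, space)
  }
  for (ns in grid$noise_seeds) {
    nm$seed <- ns
    noise <- generate_noise(nm, nrow(gain_values(G)), dur)
    n_base <- round(config$baseline_ms / 1000 * fs)
    C <- estimate_noise_cov(noise[, seq_len(n_base), drop = FALSE])
    kernels <- build_kernels(G, G_free, C, grid$methods, grid$w,
                             grid$snr_reg)
    for (st in grid$structures) {
      idx <- structure_indices(space, st)
      seeds <- idx[seq(1, length(idx), by = grid$seed_stride)]
      for (sd_i in seeds) for (ps in grid$patch_sizes)
        for (dt in grid$d_t_values_ms) {
          cell <- sprintf("seed%d_%s_src%d_size%g_dt%g", ns, st, sd_i, ps, dt)
          out <- tryCatch({
            p <- suppressWarnings(grow_patch(space, sd_i, ps))
            p <- patch_currents(p, space)
            patches <- if (is.null(cort_patch)) list(p)
                       else list(p, cort_patch)
            config$d_t_ms <- dt
            rec <- simulate_recording(G, space, patches, noise, config)
            tl <- if (truth == "seed") space$positions[sd_i, ]
                  else colSums(space$positions[p$member_indices, ,
                                               drop = FALSE] * p$currents) /
                       sum(p$currents)
            b <- rec$data[, rec$subcortical_peak_sample]
            lapply(names(kernels), function(mth) {
              est <- as.numeric(kernel_values(kernels[[mth]]) %*% b)
              det <- if (!is.null(cort_patch))
                detection_summary(est, space, tl) else NULL
              data.frame(noise_seed = ns, structure = st, seed_index = sd_i,
                         patch_size = ps, d_t_ms = dt, r_c = rec$r_c,
                         method = mth,
                         dle_g_cm = dle_g(est, space$positions, tl),
                         dle_m_cm = dle_m(est, space$positions, tl),
                         detected = if (is.null(det)) NA else det$detected,
                         stringsAsFactors = FALSE)
            })
          }, error = function(e) e)
          if (inherits(out, "error")) {
            failures[[cell]] <- conditionMessage(out)
          } else rows <- c(rows, out)
        }
    }
  }
  structure(list(results = do.call(rbind, rows), grid = grid,
                 failures = failures),
            class = "dba_mc_result")
}

#' Aggregate Monte Carlo results
#'
#' Per-seed-source mean localization errors across noise seeds, DLE_g
#' histograms per patch size (masses summing to one per condition), and
#' the detection rate versus realized cortical ratio per method.
#'
#' @param mc a `dba_mc_result`.
#' @param breaks histogram breaks in cm (default 0 to 10 by 0.5; values
#'   above the last break are clipped into the final bin).
#' @return List with `per_source` (mean DLEs), `histograms`, and
#'   `detection` (from [detection_threshold_curve()] when two-source cells
#'   are present).
#' @export
aggregate_results <- function(mc, breaks = seq(0, 10, by = 0.5)) {
  res <- mc$results
  per_source <- stats::aggregate(
    cbind(dle_g_cm, dle_m_cm) ~ structure + seed_index + method + patch_size,
    data = res, FUN = mean)
  histograms <- lapply(split(res, list(res$method, res$patch_size),
                             drop = TRUE), function(d) {
    x <- pmin(d$dle_g_cm, max(breaks) - 1e-9)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  })
  det <- if (!all(is.na(res$detected))) detection_threshold_curve(mc)
  list(per_source = per_source, histograms = histograms, detection = det)
}

#' Detection rate versus cortical-to-subcortical ratio
#'
#' Fraction of two-source cells in which a local maximum above threshold
#' is found within the search ball around the subcortical truth, per
#' method and per realized cortical-envelope ratio level.
#'
#' @param mc a `dba_mc_result` from a grid with a cortical co-activation.
#' @return Data frame with `method`, `r_c`, `detection_rate`, `n`.
#' @export
detection_threshold_curve <- function(mc) {
  res <- mc$results[!is.na(mc$results$detected), , drop = FALSE]
  if (nrow(res) == 0) stop("no two-source cells in this result")
  agg <- stats::aggregate(detected ~ method + r_c, data = res, FUN = mean)
  n <- stats::aggregate(detected ~ method + r_c, data = res, FUN = length)
  data.frame(method = agg$method, r_c = agg$r_c,
             detection_rate = agg$detected, n = n$detected)
}
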