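#' Grow a connected activation patch
#'
#' Accretes dipoles around a seed by a distance-ordered breadth-first
#' search over the structure's adjacency graph: the frontier vertex
#' closest (Euclidean) to the seed is added first, ties broken by index,
#' until the cumulative element size reaches the target extent. The patch
#' never leaves the seed's structure; if the structure is smaller than the
#' target, the whole structure is used with a warning.
#'
#' @param space a `dba_source_space`.
#' @param seed_index dipole index of the patch seed.
#' @param target_extent patch size in cm^2 (surface) or cm^3 (volume).
#' @return An object of class `dba_patch`: `seed_index`, `member_indices`,
#'   `total_extent` (cm^2/cm^3), `structure`, and `currents` (nAm,
#'   filled by [patch_currents()]).
#' @export
grow_patch <- function(space, seed_index, target_extent) {
  n <- nrow(space$positions)
  if (seed_index < 1 || seed_index > n) stop("invalid seed index")
  struct <- space$structure_labels[seed_index]
  st <- space$structures
  kind <- st$geometry_kind[match(struct, st$name)]
  unit_mm <- if (kind == "surface") 100 else 1000   # mm^2/cm^2 or mm^3/cm^3
  target_mm <- target_extent * unit_mm
  struct_total <- sum(space$element_sizes[structure_indices(space, struct)])
  if (target_mm > struct_total) {
    warning("structure ", struct, " smaller than requested patch; ",
            "using the whole structure")
    target_mm <- struct_total
  }
  seed_pos <- space$positions[seed_index, ]
  dist_to_seed <- function(i)
    sqrt(colSums((t(space$positions[i, , drop = FALSE]) - seed_pos)^2))
  members <- integer(0)
  in_patch <- logical(n)
  frontier_idx <- seed_index
  frontier_d <- 0
  in_frontier <- logical(n)
  in_frontier[seed_index] <- TRUE
  acc <- 0
  while (length(frontier_idx) > 0 && acc < target_mm) {
    pick <- order(frontier_d, frontier_idx)[1]
    v <- frontier_idx[pick]
    frontier_idx <- frontier_idx[-pick]
    frontier_d <- frontier_d[-pick]
    members <- c(members, v)
    in_patch[v] <- TRUE
    acc <- acc + space$element_sizes[v]
    nb <- space$adjacency[[v]]
    nb <- nb[!in_patch[nb] & !in_frontier[nb] &
             space$structure_labels[nb] == struct]
    if (length(nb)) {
      in_frontier[nb] <- TRUE
      frontier_idx <- c(frontier_idx, nb)
      frontier_d <- c(frontier_d, dist_to_seed(nb))
    }
  }
  structure(list(seed_index = seed_index, member_indices = sort(members),
                 total_extent = acc / unit_mm, structure = struct,
                 currents = NULL),
            class = "dba_patch")
}

#' Assign dipole currents from the dipole moment density
#'
#' Each member dipole carries a current proportional to its element size:
#' `q_i = dmd * A_i` (nAm) for surface dipoles with areas in mm^2, and
#' `q_i = dmd * V_i / 10` for volume dipoles with volumes in mm^3 and the
#' DMD expressed per 0.01 cm^3. Under both conventions the total patch
#' current equals `dmd * extent * 100` nAm with the extent in cm^2 or
#' cm^3, which reproduces the published per-structure current table.
#'
#' @param patch a `dba_patch`.
#' @param space the source space the patch was grown on.
#' @param dmd dipole moment density; default taken from the structure.
#' @return The patch with its `currents` field filled (nAm, one per
#'   member) and a `total_current` field (nAm).
#' @export
patch_currents <- function(patch, space, dmd = NULL) {
  st <- space$structures
  row <- match(patch$structure, st$name)
  if (is.null(dmd)) dmd <- st$dmd[row]
  if (dmd <= 0) stop("dmd must be positive")
  es <- space$element_sizes[patch$member_indices]
  if (length(es) > 0 && any(es <= 0)) stop("degenerate mesh: zero element size")
  q <- if (st$geometry_kind[row] == "surface") dmd * es else dmd * es / 10
  patch$currents <- q
  patch$total_current <- sum(q)
  patch
}

#' Gaussian activation envelope
#'
#' Unit-peak Gaussian time course with the given full width at half
#' maximum: the value at `peak +/- fwhm/2` is exactly 0.5.
#'
#' @param fwhm_ms full width at half maximum, milliseconds.
#' @param peak_sample sample index of the peak (1-based).
#' @param n_samples record length.
#' @param rate_hz sampling rate.
#' @return Numeric vector of length `n_samples` in `[0, 1]`.
#' @export
gaussian_timecourse <- function(fwhm_ms, peak_sample, n_samples, rate_hz) {
  if (fwhm_ms <= 0) stop("fwhm must be positive")
  if (peak_sample < 1 || peak_sample > n_samples)
    stop("parameter error: peak outside the record")
  t_ms <- (seq_len(n_samples) - peak_sample) / rate_hz * 1000
  exp(-4 * log(2) * (t_ms / fwhm_ms)^2)
}

#' Default visual-cortex-analog patch seed
#'
#' The cortex-analog dipole whose direction from the conductor centre is
#' closest to the posterior-superior direction `(0, -1, 0.25)`, standing
#' in for a visual-cortex activation site.
#'
#' @param space a `dba_source_space` containing a `"cortex"` structure.
#' @return A dipole index.
#' @export
default_cortical_seed <- function(space) {
  cx <- structure_indices(space, "cortex")
  dirs <- normalize_rows(space$positions[cx, , drop = FALSE])
  tgt <- c(0, -1, 0.25) / sqrt(1.0625)
  cx[which.max(dirs %*% tgt)]
}

#' Simulation configuration
#'
#' @param patch_sizes patch sizes swept in the Monte Carlo runs, cm^2 or
#'   cm^3 (default 1 to 5 by 1).
#' @param fwhm_ms Gaussian envelope width (default 30 ms).
#' @param baseline_ms pre-activation baseline (default 200 ms) used for
#'   noise-covariance estimation.
#' @param d_t_ms peak offset between the cortical and subcortical
#'   activations, 0 to 60 ms.
#' @param snr_energy target activation-to-noise energy ratio (default 20).
#' @param sampling_rate_hz default 1250.
#' @param post_ms record length after baseline (default 250 ms).
#' @return An object of class `dba_sim_config`.
#' @export
sim_config <- function(patch_sizes = 1:5, fwhm_ms = 30, baseline_ms = 200,
                       d_t_ms = 0, snr_energy = 20, sampling_rate_hz = 1250,
                       post_ms = 250) {
  if (d_t_ms < 0) stop("d_t_ms must be non-negative")
  if (snr_energy <= 0) stop("snr_energy must be positive")
  if (fwhm_ms <= 0) stop("fwhm_ms must be positive")
  structure(list(patch_sizes = patch_sizes, fwhm_ms = fwhm_ms,
                 baseline_ms = baseline_ms, d_t_ms = d_t_ms,
                 snr_energy = snr_energy,
                 sampling_rate_hz = sampling_rate_hz, post_ms = post_ms),
            class = "dba_sim_config")
}

#' Synthesise a sensor recording from activated patches
#'
#' Sums the noiseless fields of the supplied patches (gain times
#' per-dipole currents, modulated by each patch's Gaussian envelope),
#' scales the summed field so that its energy is `snr_energy` times the
#' noise energy, and adds the noise. The first patch is taken as the
#' subcortical activation whose peak defines the evaluation sample; a
#' second patch, if present, is the cortical co-activation peaking
#' `d_t_ms` earlier.
#'
#' @param G fixed-orientation gain.
#' @param space source space (for unit bookkeeping).
#' @param patches list of `dba_patch` objects with currents assigned.
#' @param noise sensors x samples noise matrix, or `NULL` for a noiseless
#'   recording (no SNR scaling is applied then).
#' @param config a [sim_config()].
#' @return Object of class `dba_recording`: `data` (sensors x samples,
#'   Tesla), `sampling_rate_hz`, `baseline_span` (sample indices),
#'   `subcortical_peak_sample`, `cortical_peak_sample`, `truth` (list with
#'   the scaled per-patch current vectors and envelopes), `r_c` (realized
#'   cortical-envelope amplitude at the subcortical peak), `scale`.
#' @export
simulate_recording <- function(G, space, patches, noise, config) {
  fs <- config$sampling_rate_hz
  n_base <- round(config$baseline_ms / 1000 * fs)
  n_post <- round(config$post_ms / 1000 * fs)
  n_samp <- n_base + n_post
  g <- gain_values(G)
  if (!is.null(noise) && ncol(noise) < n_samp)
    stop("noise segment shorter than baseline + activation window")
  d_t_samp <- round(config$d_t_ms / 1000 * fs)
  sub_peak <- n_base + max(d_t_samp, round(0.4 * n_post)) + 1L
  cort_peak <- sub_peak - d_t_samp
  if (sub_peak > n_samp) stop("record too short for the requested offsets")
  peaks <- c(sub_peak, cort_peak)
  signal <- matrix(0, nrow(g), n_samp)
  envelopes <- vector("list", length(patches))
  topos <- vector("list", length(patches))
  for (pi in seq_along(patches)) {
    p <- patches[[pi]]
    if (is.null(p$currents)) stop("patch has no currents; run patch_currents()")
    peak <- if (pi <= 2) peaks[pi] else sub_peak
    env <- gaussian_timecourse(config$fwhm_ms, peak, n_samp, fs)
    env[seq_len(n_base)] <- 0          # baseline strictly silent
    q_am <- p$currents * 1e-9          # nAm -> A m
    topo <- g[, p$member_indices, drop = FALSE] %*% q_am
    signal <- signal + topo %*% t(env)
    envelopes[[pi]] <- env
    topos[[pi]] <- topo
  }
  e_sig <- sum(signal^2)
  if (is.null(noise)) {
    scale <- 1
    data <- signal
    noise_used <- NULL
  } else {
    noise_used <- noise[, seq_len(n_samp), drop = FALSE]
    e_noise <- sum(noise_used^2)
    if (e_sig == 0)
      stop("unscalable signal: patches are magnetically silent")
    scale <- sqrt(config$snr_energy * e_noise / e_sig)
    data <- scale * signal + noise_used
  }
  r_c <- if (length(patches) >= 2)
    exp(-4 * log(2) * (config$d_t_ms / config$fwhm_ms)^2) else NA_real_
  truth <- list(patches = patches, envelopes = envelopes,
                topographies = lapply(topos, function(x) x * scale),
                scaled_currents = lapply(patches,
                                         function(p) p$currents * scale))
  structure(list(data = data, sampling_rate_hz = fs,
                 baseline_span = seq_len(n_base),
                 subcortical_peak_sample = sub_peak,
                 cortical_peak_sample = cort_peak,
                 truth = truth, r_c = r_c, scale = scale,
                 noise = noise_used, signal = scale * signal),
            class = "dba_recording")
}
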