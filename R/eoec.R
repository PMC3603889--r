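#' Pick default alpha generators: thalamus plus posterior cortex
#'
#' Selects the `n_thalamus` thalamus-analog dipoles closest to the
#' structure centroid and the `n_occipital` cortex-analog dipoles whose
#' direction is closest to the posterior direction `(0, -1, 0)`,
#' emulating the thalamo-occipital alpha network.
#'
#' @param space a `dba_source_space`.
#' @param n_thalamus,n_occipital counts (defaults 10 and 20).
#' @return Integer vector of dipole indices.
#' @export
default_alpha_sources <- function(space, n_thalamus = 10, n_occipital = 20) {
  th <- structure_indices(space, "thalamus")
  ctr <- colMeans(space$positions[th, , drop = FALSE])
  th_sel <- th[order(row_norms(sweep(space$positions[th, , drop = FALSE],
                                     2, ctr)))][seq_len(n_thalamus)]
  cx <- structure_indices(space, "cortex")
  dirs <- normalize_rows(space$positions[cx, , drop = FALSE])
  post <- dirs %*% c(0, -1, 0)
  cx_sel <- cx[order(-post)][seq_len(n_occipital)]
  c(th_sel, cx_sel)
}

#' Synthesise eyes-open / eyes-closed block recordings
#'
#' Each block carries independent narrow-band (10 Hz, 0.7 Hz sigma) alpha
#' time series at the given source indices, projected through the gain,
#' on top of independent 1/f sensor background noise. In the eyes-closed
#' condition the alpha source amplitudes are multiplied by
#' `modulation_ratio`. The eyes-open alpha field energy is set to
#' `eo_alpha_energy` times the noise energy per block.
#'
#' @param space source space.
#' @param G fixed-orientation gain.
#' @param alpha_sources dipole indices of the alpha generators
#'   (default [default_alpha_sources()]).
#' @param modulation_ratio eyes-closed over eyes-open alpha amplitude
#'   ratio (> 0; 1 gives exchangeable conditions).
#' @param seed RNG seed.
#' @param n_blocks blocks per condition (default 8).
#' @param block_s block duration, seconds (default 5).
#' @param sampling_rate_hz default 250.
#' @param spectrum background 1/f exponent (default 1).
#' @param eo_alpha_energy eyes-open alpha-to-noise energy ratio
#'   (default 0.5).
#' @return List with elements `eyes_open` and `eyes_closed`, each of class
#'   `dba_condition`: `condition`, `blocks` (list of sensors x samples
#'   matrices), `sampling_rate_hz`.
#' @export
synthesize_eo_ec <- function(space, G, alpha_sources = NULL,
                             modulation_ratio = 2, seed = 1L, n_blocks = 8,
                             block_s = 5, sampling_rate_hz = 250,
                             spectrum = 1, eo_alpha_energy = 0.5) {
  if (modulation_ratio <= 0) stop("modulation_ratio must be positive")
  if (n_blocks < 2) stop("need at least two blocks per condition")
  if (is.null(alpha_sources)) alpha_sources <- default_alpha_sources(space)
  g <- gain_values(G)
  ga <- g[, alpha_sources, drop = FALSE]
  if (max(colSums(ga^2)) == 0) stop("unscalable: silent alpha sources")
  fs <- sampling_rate_hz
  n <- round(block_s * fs)
  bg_env <- function(f) ifelse(f <= 0, 0, pmax(f, 1)^(-spectrum / 2))
  alpha_env <- function(f) exp(-(f - 10)^2 / (2 * 0.7^2))
  n_ch <- nrow(g)
  with_seed(seed, {
    make_block <- function(amp) {
      noise <- t(vapply(seq_len(n_ch), function(i) {
        x <- shape_spectrum(stats::rnorm(n), bg_env, fs)
        x / stats::sd(x)
      }, numeric(n)))
      s_a <- t(vapply(seq_along(alpha_sources), function(j)
        shape_spectrum(stats::rnorm(n), alpha_env, fs), numeric(n)))
      sig <- ga %*% s_a
      sc <- sqrt(eo_alpha_energy * sum(noise^2) / sum(sig^2))
      noise + amp * sc * sig
    }
    eo <- lapply(seq_len(n_blocks), function(b) make_block(1))
    ec <- lapply(seq_len(n_blocks), function(b) make_block(modulation_ratio))
    list(eyes_open = structure(list(condition = "eyes_open", blocks = eo,
                                    sampling_rate_hz = fs),
                               class = "dba_condition"),
         eyes_closed = structure(list(condition = "eyes_closed", blocks = ec,
                                      sampling_rate_hz = fs),
                                 class = "dba_condition"))
  })
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase). The
#' design corners are placed outside the analysis band (geometric margin)
#' so the passband stays flat within 1 dB over the band itself.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param band two-element vector, Hz.
#' @param fs sampling rate, Hz.
#' @return Filtered data, same shape.
#' @export
bandpass_filter <- function(x, band, fs) {
  corners <- c(band[1] * 0.8, band[2] * 1.25)
  bf <- signal::butter(2, corners / (fs / 2), type = "pass")
  ff <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) t(apply(x, 1, ff)) else ff(x)
}

#' Alpha-band source power contrast with FDR correction
#'
#' Band-passes each block, projects it to source space through the
#' inverse kernel, computes per-block per-source band power, contrasts
#' the two conditions with a two-sample Student t-test across blocks
#' (positive t means eyes-closed greater), and controls the false
#' discovery rate with Benjamini-Hochberg.
#'
#' @param recordings list with `eyes_open` and `eyes_closed`
#'   `dba_condition` objects (from [synthesize_eo_ec()]).
#' @param kernel an inverse kernel.
#' @param band_hz analysis band (default `c(8, 12)`).
#' @param fdr_level significance level on the q-values (default 0.05).
#' @return Object of class `dba_contrast`: data frame `table` with
#'   `source`, `t`, `p`, `q`, `significant`, plus `band_hz` and
#'   `fdr_level`.
#' @export
alpha_contrast <- function(recordings, kernel, band_hz = c(8, 12),
                           fdr_level = 0.05) {
  eo <- recordings$eyes_open
  ec <- recordings$eyes_closed
  if (length(eo$blocks) < 2 || length(ec$blocks) < 2)
    stop("need at least two blocks per condition")
  fs <- eo$sampling_rate_hz
  K <- kernel_values(kernel)
  block_power <- function(blk) {
    filt <- bandpass_filter(blk, band_hz, fs)
    rowMeans((K %*% filt)^2)
  }
  p_eo <- vapply(eo$blocks, block_power, numeric(nrow(K)))
  p_ec <- vapply(ec$blocks, block_power, numeric(nrow(K)))
  n1 <- ncol(p_ec); n2 <- ncol(p_eo)
  m1 <- rowMeans(p_ec); m2 <- rowMeans(p_eo)
  v1 <- apply(p_ec, 1, stats::var); v2 <- apply(p_eo, 1, stats::var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t_stat <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  p_val <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  q_val <- stats::p.adjust(p_val, method = "BH")
  structure(list(table = data.frame(source = seq_len(nrow(K)), t = t_stat,
                                    p = p_val, q = q_val,
                                    significant = q_val < fdr_level),
                 band_hz = band_hz, fdr_level = fdr_level),
            class = "dba_contrast")
}
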