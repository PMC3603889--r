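#' Resting-state sensor noise model
#'
#' Parameters of the synthetic ongoing-activity surrogate: a 1/f^beta
#' background per channel plus a shared narrow-band alpha source projected
#' onto the channels with random signs, which induces weak inter-channel
#' correlation. The alpha gain is defined as the ratio of the
#' power-spectral-density bump at the alpha peak to the 1/f background at
#' the same frequency, so the PSD at `alpha_peak_hz` is approximately
#' `(1 + alpha_peak_gain)` times the extrapolated background level.
#'
#' @param spectrum 1/f exponent beta of the background PSD (default 1).
#' @param alpha_peak_hz alpha peak frequency, Hz (default 10).
#' @param alpha_peak_gain bump-to-background PSD ratio at the peak
#'   (default 3; 0 disables the alpha component).
#' @param sensor_white_sd per-channel standard deviation, Tesla
#'   (default 100 fT, typical magnetometer resting noise).
#' @param sampling_rate_hz sampling rate (default 1250). Must exceed
#'   twice the alpha peak frequency.
#' @param seed RNG seed; identical seeds give identical segments.
#' @return An object of class `dba_noise_model`.
#' @export
noise_model <- function(spectrum = 1, alpha_peak_hz = 10, alpha_peak_gain = 3,
                        sensor_white_sd = 100e-15, sampling_rate_hz = 1250,
                        seed = 1L) {
  if (sampling_rate_hz <= 2 * alpha_peak_hz)
    stop("sampling_rate_hz must exceed twice alpha_peak_hz")
  if (alpha_peak_gain < 0) stop("alpha_peak_gain must be non-negative")
  structure(list(spectrum = spectrum, alpha_peak_hz = alpha_peak_hz,
                 alpha_peak_gain = alpha_peak_gain,
                 sensor_white_sd = sensor_white_sd,
                 sampling_rate_hz = sampling_rate_hz, seed = seed),
            class = "dba_noise_model")
}

## shape white Gaussian input by an even spectral envelope (frequency-domain
## filtering; envelope given as a function of folded frequency in Hz)
shape_spectrum <- function(w, envelope, fs) {
  n <- length(w)
  f <- (seq_len(n) - 1) * fs / n
  fold <- pmin(f, fs - f)
  h <- envelope(fold)
  h[1] <- 0                       # remove DC
  Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
}

#' Generate multichannel resting-state noise
#'
#' Synthesises `n_channels` of surrogate ongoing MEG activity in the
#' frequency domain: each channel is an independent 1/f^beta background,
#' plus a shared Gaussian-envelope (sigma 0.7 Hz) narrow-band alpha source
#' added with a random sign per channel and scaled so the PSD bump at the
#' alpha peak is `alpha_peak_gain` times the background there. Channels
#' are finally scaled to the configured per-channel standard deviation.
#'
#' @param model a [noise_model()].
#' @param n_channels number of channels.
#' @param duration_s segment length, seconds (>= 0.2).
#' @return Matrix `n_channels x n_samples` (Tesla), with attribute
#'   `sampling_rate_hz`.
#' @export
generate_noise <- function(model, n_channels, duration_s) {
  if (duration_s < 0.2) stop("parameter error: duration must be >= 0.2 s")
  fs <- model$sampling_rate_hz
  n <- round(duration_s * fs)
  beta <- model$spectrum
  bg_env <- function(f) ifelse(f <= 0, 0, pmax(f, 1)^(-beta / 2))
  fa <- model$alpha_peak_hz
  alpha_env <- function(f) exp(-(f - fa)^2 / (2 * 0.7^2))
  with_seed(model$seed, {
    out <- matrix(0, n_channels, n)
    shared <- if (model$alpha_peak_gain > 0)
      shape_spectrum(stats::rnorm(n), alpha_env, fs) else NULL
    c_alpha <- sqrt(model$alpha_peak_gain) * bg_env(fa)
    signs <- if (!is.null(shared)) sample(c(-1, 1), n_channels, TRUE)
    for (ch in seq_len(n_channels)) {
      x <- shape_spectrum(stats::rnorm(n), bg_env, fs)
      if (!is.null(shared)) x <- x + signs[ch] * c_alpha * shared
      out[ch, ] <- x / stats::sd(x) * model$sensor_white_sd
    }
    attr(out, "sampling_rate_hz") <- fs
    out
  })
}

#' Welch power spectral density estimate
#'
#' Mean periodogram over Hann-windowed half-overlapping segments; used by
#' the tests and the eyes-open/eyes-closed synthesis checks.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length (default 1024, clipped to `length(x)`).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 1024) {
  nperseg <- min(nperseg, length(x))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)] * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / length(starts) / (fs * sum(win^2))
  nf <- floor(nperseg / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd[seq_len(nf)])
}
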