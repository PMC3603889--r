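#' Estimate the sensor noise covariance from a baseline segment
#'
#' Sample covariance across baseline samples with diagonal loading: a
#' fraction of the mean diagonal is added to every diagonal entry, which
#' keeps the matrix positive definite when the baseline is shorter than
#' the channel count (200 ms at 1250 Hz gives 250 samples for 151
#' channels).
#'
#' @param baseline sensors x samples matrix.
#' @param loading_fraction diagonal loading as a fraction of the mean
#'   diagonal (default 0.05).
#' @return Object of class `dba_noise_cov`: `matrix`, `n_samples_used`,
#'   `regularization_applied`.
#' @export
estimate_noise_cov <- function(baseline, loading_fraction = 0.05) {
  n <- ncol(baseline)
  if (n < 2) stop("need at least two baseline samples")
  x <- baseline - rowMeans(baseline)
  C <- tcrossprod(x) / (n - 1)
  sds <- sqrt(diag(C))
  if (any(sds == 0)) warning("constant channels: covariance is rank deficient")
  mu <- mean(diag(C))
  if (mu == 0) mu <- .Machine$double.eps
  C <- C + diag(loading_fraction * mu, nrow(C))
  structure(list(matrix = (C + t(C)) / 2, n_samples_used = n,
                 regularization_applied = loading_fraction),
            class = "dba_noise_cov")
}

cov_values <- function(C) if (inherits(C, "dba_noise_cov")) C$matrix else as.matrix(C)

#' Depth-weighting source covariance diagonal
#'
#' The diagonal source covariance `S_ii = ||G_i||_F^(-2w)`, where `G_i` is
#' the three-column free-orientation gain of the i-th point source before
#' orientation constraints are applied. `w = 0` gives the identity (plain
#' MNE); larger `w` boosts deep sources whose gain norms are small,
#' partially compensating the superficial bias of the minimum-norm
#' solution.
#'
#' @param G_free free-orientation gain from
#'   `compute_gain(space, sensors, "free")` (sensors x 3*sources).
#' @param w weighting exponent in `[0, 1]` (default 0.6).
#' @param cap weights of magnetically silent sources (zero gain norm) are
#'   capped at `cap` times the largest finite weight, with a warning.
#' @return Numeric vector of per-source weights (length sources).
#' @export
depth_weights <- function(G_free, w = 0.6, cap = 10) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  g <- gain_values(G_free)
  if (ncol(g) %% 3 != 0)
    stop("depth weights need the 3-component free-orientation gain")
  n_src <- ncol(g) / 3
  fro2 <- colSums(g^2)
  norms <- sqrt(fro2[seq(1, by = 3, length.out = n_src)] +
                fro2[seq(2, by = 3, length.out = n_src)] +
                fro2[seq(3, by = 3, length.out = n_src)])
  if (w == 0) return(rep(1, n_src))
  s <- norms^(-2 * w)
  bad <- !is.finite(s)
  if (any(bad)) {
    warning(sum(bad), " silent source(s): depth weight capped")
    s[bad] <- cap * max(s[!bad])
  }
  s
}

#' Depth-weighted minimum-norm inverse kernel
#'
#' `K = S G^t (G S G^t + lambda^2 C)^(-1)` with the regularization
#' `lambda^2 = trace(G S G^t) / (trace(C) * snr_reg^2)`, the conventional
#' signal-to-noise parameterisation of Tikhonov regularisation for
#' minimum-norm imaging.
#'
#' @param G fixed-orientation gain (sensors x sources).
#' @param C noise covariance ([estimate_noise_cov()] or matrix), positive
#'   definite.
#' @param S per-source weight vector from [depth_weights()], or `NULL`
#'   for plain MNE.
#' @param snr_reg regularization SNR (default 3).
#' @return Object of class `dba_inverse_kernel`: `matrix` (sources x
#'   sensors), `method`, `lambda2`, `weights`, `snr_reg`.
#' @export
wmne_kernel <- function(G, C, S = NULL, snr_reg = 3) {
  g <- gain_values(G)
  Cm <- cov_values(C)
  if (is.null(S)) S <- rep(1, ncol(g))
  if (length(S) != ncol(g)) stop("length(S) must equal the source count")
  gs <- sweep(g, 2, S, "*")            # G S
  gsgt <- gs %*% t(g)
  lambda2 <- sum(diag(gsgt)) / (sum(diag(Cm)) * snr_reg^2)
  A <- gsgt + lambda2 * Cm
  A <- (A + t(A)) / 2
  K <- t(chol_solve(A, gs))            # S G^t A^{-1}
  structure(list(matrix = K, method = "wmne", lambda2 = lambda2,
                 weights = S, snr_reg = snr_reg),
            class = "dba_inverse_kernel")
}

kernel_values <- function(K)
  if (inherits(K, "dba_inverse_kernel")) K$matrix else as.matrix(K)

#' dSPM noise-normalised kernel
#'
#' Divides each row of the minimum-norm kernel by the square root of its
#' noise variance `(K C K^t)_ii`, so that pure noise drawn from `C`
#' produces unit-variance source estimates.
#'
#' @param K_wmne a [wmne_kernel()].
#' @param C the noise covariance used to build it.
#' @return `dba_inverse_kernel` with `method = "dspm"`.
#' @export
dspm_kernel <- function(K_wmne, C) {
  K <- kernel_values(K_wmne)
  Cm <- cov_values(C)
  nv <- rowSums((K %*% Cm) * K)
  bad <- nv <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-noise-variance row(s) capped")
    nv[bad] <- min(nv[!bad])
  }
  out <- K_wmne
  out$matrix <- K / sqrt(nv)
  out$method <- "dspm"
  out
}

#' sLORETA standardized kernel
#'
#' Standardises each row of the minimum-norm kernel by the square root of
#' the model variance of its estimate, `diag(K (G S G^t + lambda^2 C)
#' K^t) = diag(K G) * S`. For an unweighted kernel (`S = I`) this is the
#' classical division by `sqrt(diag(K G))`; with depth weighting the
#' extra `sqrt(S_i)` factor is what preserves the exact zero
#' localization error of noiseless point sources. Either way the
#' operation is a pure row rescaling, so cross-talk shapes are unchanged.
#'
#' @param K_wmne a [wmne_kernel()].
#' @param G the fixed-orientation gain used to build it.
#' @return `dba_inverse_kernel` with `method = "sloreta"`.
#' @export
sloreta_kernel <- function(K_wmne, G) {
  K <- kernel_values(K_wmne)
  g <- gain_values(G)
  rii <- rowSums(K * t(g))
  if (any(rii <= 0))
    stop("non-positive resolution diagonal at source ",
         which(rii <= 0)[1])
  S <- if (inherits(K_wmne, "dba_inverse_kernel") &&
           !is.null(K_wmne$weights)) K_wmne$weights else rep(1, nrow(K))
  out <- K_wmne
  out$matrix <- K / sqrt(rii * S)
  out$method <- "sloreta"
  out
}

#' Resolution matrix
#'
#' `R = K G`: the linear map from true to estimated source amplitudes.
#' Columns are point-spread functions (PSF), rows cross-talk functions
#' (CTF).
#'
#' @param K an inverse kernel.
#' @param G the gain matrix.
#' @return Object of class `dba_resolution`: `matrix` (sources x
#'   sources), `kernel_method`.
#' @export
resolution_matrix <- function(K, G) {
  Km <- kernel_values(K)
  g <- gain_values(G)
  if (ncol(Km) != nrow(g)) stop("non-conforming kernel and gain")
  method <- if (inherits(K, "dba_inverse_kernel")) K$method else "custom"
  structure(list(matrix = Km %*% g, kernel_method = method),
            class = "dba_resolution")
}

resolution_values <- function(R)
  if (inherits(R, "dba_resolution")) R$matrix else as.matrix(R)
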