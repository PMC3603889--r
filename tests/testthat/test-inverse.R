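test_that("noise covariance estimation is consistent and homogeneous", {
  set.seed(21)
  x <- matrix(rnorm(20 * 5000), 20, 5000)
  C <- estimate_noise_cov(x, loading_fraction = 0)
  offd <- C$matrix[upper.tri(C$matrix)]
  expect_lt(max(abs(offd)), 0.05)
  expect_equal(diag(C$matrix), rep(1, 20), tolerance = 0.1)
  C2 <- estimate_noise_cov(3 * x, loading_fraction = 0)
  expect_equal(C2$matrix, 9 * C$matrix, tolerance = 1e-12)
  ## loading keeps zero data positive definite
  expect_warning(C0 <- estimate_noise_cov(matrix(1, 4, 10),
                                          loading_fraction = 0.1),
                 "constant")
  expect_true(all(eigen(C0$matrix, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("depth weights follow the free-orientation gain norms", {
  ## two sources with 3-column norms n and 2n
  g <- cbind(diag(3), 2 * diag(3))   # norms 1 and 2
  expect_equal(depth_weights(g, 0), c(1, 1))
  w05 <- depth_weights(g, 0.5)
  expect_equal(w05[1] / w05[2], 2)
  w06 <- depth_weights(g, 0.6)          # joint 3-column norms sqrt(3), sqrt(12)
  expect_equal(w06, c(3^(-0.6), 12^(-0.6)))
  expect_error(depth_weights(g, 1.5), "w must be")
  expect_error(depth_weights(diag(4), 0.5), "free-orientation")
})

test_that("lambda2 matches the trace-ratio rule on a toy system", {
  G <- matrix(c(2, 0, 1, 0, 1, 0, 0, 1, 3), 3, 3)
  C <- diag(c(1, 2, 3))
  S <- c(1, 0.5, 2)
  K <- wmne_kernel(G, C, S, snr_reg = 3)
  gsgt <- G %*% diag(S) %*% t(G)
  expect_equal(K$lambda2, sum(diag(gsgt)) / (sum(diag(C)) * 9))
})

test_that("in the exact-inverse limit the resolution matrix is identity", {
  set.seed(3)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))       # orthogonal gain
  K <- wmne_kernel(q, diag(5), NULL, snr_reg = 1e8)
  R <- resolution_matrix(K, q)
  expect_lt(max(abs(R$matrix - diag(5))), 1e-10)
  expect_lt(max(abs(K$matrix - t(q))), 1e-10)
})

test_that("plain MNE is superficially biased; depth weighting compensates", {
  sp <- test_space(); G <- test_gain()
  C <- test_noise_cov()
  K0 <- wmne_kernel(G, C, NULL)
  Kw <- test_kernels()$wmne
  R0 <- resolution_matrix(K0, G)$matrix
  Rw <- resolution_matrix(Kw, G)$matrix
  depth <- source_depths(sp)
  deep <- which(sp$structure_labels %in%
                c("hippocampus", "amygdala", "thalamus", "putamen"))
  ## point-source maxima land on shallower sources without weighting
  argmax0 <- apply(abs(R0[, deep]), 2, which.max)
  expect_gt(mean(depth[deep] - depth[argmax0]), 0)
  ## deep-source amplitude recovered better with w = 0.6
  i <- structure_indices(sp, "thalamus")[60]
  expect_gt(abs(Rw[i, i]), abs(R0[i, i]))
  ## and the median deep localization error shrinks
  d0 <- vapply(deep, function(i) dle_m(R0[, i], sp$positions,
                                       sp$positions[i, ]), numeric(1))
  dw <- vapply(deep, function(i) dle_m(Rw[, i], sp$positions,
                                       sp$positions[i, ]), numeric(1))
  expect_lt(median(dw), median(d0))
})

test_that("dSPM rows have unit noise sensitivity and unit noise variance", {
  C <- test_noise_cov()
  Kd <- test_kernels()$dspm
  nv <- rowSums((Kd$matrix %*% C$matrix) * Kd$matrix)
  expect_lt(max(abs(nv - 1)), 1e-9)
  ## Monte Carlo: estimates of pure noise drawn from C have variance ~ 1
  set.seed(17)
  ch <- chol(C$matrix)
  noise <- t(ch) %*% matrix(rnorm(151 * 10000), 151)
  est <- Kd$matrix[seq(1, nrow(Kd$matrix), by = 25), ] %*% noise
  v <- apply(est, 1, var)
  expect_lt(max(abs(v - 1)), 0.1)
})

test_that("dSPM maps are invariant to a joint rescaling of noise and data", {
  G <- test_gain(); C <- test_noise_cov()
  S <- depth_weights(test_gain_free(), 0.6)
  b <- test_gain()$values[, 333] * 1e-9
  Kd <- dspm_kernel(wmne_kernel(G, C, S), C)
  C2 <- C; C2$matrix <- 4 * C$matrix
  Kd2 <- dspm_kernel(wmne_kernel(G, C2, S), C2)
  expect_equal(as.numeric(Kd2$matrix %*% (2 * b)),
               as.numeric(Kd$matrix %*% b), tolerance = 1e-9)
})

test_that("sLORETA matches a hand computation on a 2x2 toy system", {
  G <- matrix(c(1, 0.2, 0.3, 1), 2, 2)
  C <- diag(2)
  Kw <- wmne_kernel(G, C, NULL, snr_reg = 3)
  ## by hand: K = G^t (G G^t + l2 I)^-1, rows / sqrt(diag(K G))
  l2 <- sum(diag(G %*% t(G))) / (2 * 9)
  Kh <- t(G) %*% solve(G %*% t(G) + l2 * diag(2))
  Rh <- Kh %*% G
  Kh <- Kh / sqrt(diag(Rh))
  Ks <- sloreta_kernel(Kw, G)
  expect_equal(Ks$matrix, Kh, tolerance = 1e-12)
})

test_that("sLORETA localizes noiseless point sources exactly", {
  sp <- test_space(); G <- test_gain()
  Rs <- resolution_matrix(test_kernels()$sloreta, G)$matrix
  worst <- 0
  for (i in seq(1, nrow(sp$positions), by = 3)) {
    worst <- max(worst, dle_m(Rs[, i], sp$positions, sp$positions[i, ]))
  }
  expect_equal(worst, 0)
  ## the standardized resolution rows stay proportional to wMNE's
  Rw <- resolution_matrix(test_kernels()$wmne, G)$matrix
  i <- 777
  expect_equal(Rs[i, ] / Rs[i, i], Rw[i, ] / Rw[i, i], tolerance = 1e-10)
})

test_that("resolution matrix is the exact kernel-gain product, trace-bounded", {
  G <- test_gain()
  for (K in test_kernels()) {
    R <- resolution_matrix(K, G)
    expect_identical(R$matrix, K$matrix %*% G$values)
  }
  Rw <- resolution_matrix(test_kernels()$wmne, G)
  expect_lte(sum(diag(Rw$matrix)), 151)
})

test_that("normalized CTF rows are identical across the three operators", {
  G <- test_gain()
  Rs <- lapply(test_kernels(), function(K) {
    R <- resolution_matrix(K, G)$matrix
    R / sqrt(rowSums(R^2))
  })
  expect_lt(max(abs(Rs$wmne - Rs$dspm)), 1e-10)
  expect_lt(max(abs(Rs$wmne - Rs$sloreta)), 1e-10)
})
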