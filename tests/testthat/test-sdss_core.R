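test_that("sample covariance matches hand-computed outer products", {
  g <- array_geometry(2)
  # two snapshots e1, e2 -> I/2
  fr <- snapshot_frame(cbind(c(1, 0), c(0, 1)), g)
  expect_cplx_equal(sample_covariance(fr)$matrix, diag(2) / 2)
  # repeated unit vector -> rank-1 outer product
  fr2 <- snapshot_frame(matrix(rep(c(1, 0), 5), 2), g)
  R2 <- sample_covariance(fr2)$matrix
  expect_cplx_equal(R2, outer(c(1, 0), c(1, 0)))
  # all-zero frame -> zero matrix
  fr0 <- snapshot_frame(matrix(0, 2, 3), g)
  expect_true(all(sample_covariance(fr0)$matrix == 0))
})

test_that("covariance estimates validate Hermitian symmetry and size", {
  expect_error(covariance_estimate(matrix(c(0, 1, 0, 0), 2), "sample"),
               "Hermitian")
  expect_error(covariance_estimate(matrix(1, 2, 3), "sample"), "square")
})

test_that("forward smoothing averages overlapping diagonal blocks", {
  R <- covariance_estimate(diag(5), "sample")
  for (q in 1:5)
    expect_cplx_equal(forward_smooth(R, q)$matrix, diag(5 - q + 1))
  Rh <- covariance_estimate(random_hpsd(4, 1), "sample")
  expect_cplx_equal(forward_smooth(Rh, 1)$matrix, Rh$matrix)
  # hand example M=3, q=2
  R3 <- covariance_estimate(matrix(c(2, 1, 0, 1, 3, 1, 0, 1, 4), 3), "sample")
  expect_cplx_equal(forward_smooth(R3, 2)$matrix,
                    matrix(c(2.5, 1, 1, 3.5), 2))
  expect_error(forward_smooth(R3, 4), "q")
  expect_error(forward_smooth(forward_smooth(R3, 2), 1), "sample")
})

test_that("backward smoothing is forward smoothing of the exchange-conjugate", {
  # real persymmetric input: backward equals forward
  Rp <- matrix(c(2, 1, 0, 1, 3, 1, 0, 1, 2), 3)
  Rpe <- covariance_estimate(Rp, "sample")
  expect_cplx_equal(backward_smooth(Rpe, 2)$matrix,
                    forward_smooth(Rpe, 2)$matrix)
  expect_cplx_equal(backward_smooth(Rpe, 2)$matrix, oracle_backward(Rp, 2))
  # complex Hermitian with R[1,2] = i, against the independent oracle
  Rc <- matrix(c(2 + 0i, -1i, 0, 1i, 3 + 0i, 0.5, 0, 0.5, 4 + 0i), 3)
  Rce <- covariance_estimate(Rc, "sample")
  expect_cplx_equal(backward_smooth(Rce, 2)$matrix, oracle_backward(Rc, 2))
})

test_that("fb smoothing is the mean of forward and backward and is persymmetric", {
  for (seed in 1:5) {
    R <- covariance_estimate(random_hpsd(4, seed), "sample")
    f <- forward_smooth(R, 2)$matrix
    b <- backward_smooth(R, 2)$matrix
    fb <- fb_smooth(R, 2)$matrix
    expect_cplx_equal(fb, (f + b) / 2)
    l <- nrow(fb)
    J <- matrix(0, l, l); J[cbind(l:1, 1:l)] <- 1
    expect_lt(max_abs(J %*% Conj(fb) %*% J - fb), 1e-10 * max_abs(fb))
    ev <- Re(eigen(fb, symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(min(ev), -1e-10 * sum(Re(diag(fb))))
  }
})

test_that("mvdr weights solve the distortionless minimum-variance problem", {
  # identity covariance reduces to delay-and-sum
  g <- array_geometry(4)
  a <- steering_vector(g, 0.4)
  w <- mvdr_weights(covariance_estimate(diag(4), "fb"), a)$weights
  expect_cplx_equal(w, das_weights(a)$weights, tol = 1e-12)
  # hand example diag(1, 4), a = ones
  w2 <- mvdr_weights(covariance_estimate(diag(c(1, 4)), "fb"), c(1, 1))$weights
  expect_cplx_equal(w2, c(0.8, 0.2))
  # scale invariance of the Capon quotient
  R <- covariance_estimate(random_hpsd(4, 9) + diag(4), "fb")
  Rc <- covariance_estimate(7 * R$matrix, "fb")
  expect_cplx_equal(mvdr_weights(R, a)$weights, mvdr_weights(Rc, a)$weights,
                    tol = 1e-10)
  # distortionless constraint
  w3 <- mvdr_weights(R, a, loading = 0.01)$weights
  expect_lt(Mod(sum(Conj(w3) * a) - 1), 1e-8)
  # singular covariance reported with guidance
  expect_error(mvdr_weights(covariance_estimate(matrix(0, 2, 2), "fb"), c(1, 1)),
               "loading")
})

test_that("direction scans peak at the source for both beamformers", {
  g <- array_geometry(24, num_subarrays = 6)
  th0 <- 0.21
  fr <- simulate_snapshots(g, source_set(th0), 100, noise_variance = 1e-6,
                           seed = 4)
  angles <- seq(-pi / 3, pi / 3, length.out = 241)
  nearest <- which.min(abs(angles - th0))
  for (m in c("das", "mvdr_sdss")) {
    img <- beamform_image(fr, m, angles = angles)
    expect_equal(which.max(img$pixels), nearest)
  }
})

test_that("mvdr_sdss resolves a two-point scene more sharply than das", {
  g <- array_geometry(32, num_subarrays = 8)
  fr <- simulate_snapshots(g, source_set(c(-0.2, 0.25)), 200,
                           noise_variance = 0.01, seed = 0)
  angles <- seq(-pi / 3, pi / 3, length.out = 361)
  w_das <- beam_width_3db(beamform_image(fr, "das", angles = angles))
  w_mv <- beam_width_3db(beamform_image(fr, "mvdr_sdss", angles = angles))
  expect_lte(w_mv, w_das)
})

test_that("an all-zero frame reconstructs to an all-zero image", {
  g <- array_geometry(8, num_subarrays = 2)
  fr <- snapshot_frame(matrix(0, 8, 4), g)
  for (m in c("das", "mvdr_sdss"))
    expect_true(all(beamform_image(fr, m)$pixels == 0))
})

test_that("log compression yields a nonnegative bounded display image", {
  g <- array_geometry(16, num_subarrays = 4)
  fr <- simulate_snapshots(g, source_set(0.1), 50, noise_variance = 0.01,
                           seed = 6)
  img <- beamform_image(fr, "mvdr_sdss", compress = TRUE, dynamic_range_db = 60)
  expect_true(all(img$pixels >= 0 & img$pixels <= 60))
  expect_equal(max(img$pixels), 60)  # peak sits at the top of the range
})

test_that("post-filter gains behave as closed forms predict", {
  img <- recon_image(matrix(2, 4, 4), method = "das")
  # zero noise: identity
  expect_equal(wiener_postfilter(img, 0)$pixels, img$pixels)
  # noise equal to signal power: image halved
  expect_equal(wiener_postfilter(img, 2)$pixels, img$pixels / 2)
  # zero SNR everywhere: zero image
  expect_true(all(snr_postfilter(img, 0)$pixels == 0))
  # snr = 1: halved
  expect_equal(snr_postfilter(img, 1)$pixels, img$pixels / 2)
  expect_error(wiener_postfilter(img, -1), "noise_power")
  expect_error(snr_postfilter(img, -1), "snr_map")
})
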