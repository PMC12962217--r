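# Image-quality metrics and the diffusion tensor fit.

test_that("metric basics: perfect match, noise law, negative SSIM", {
  set.seed(1)
  ref <- array(abs(rnorm(64 * 64)) + 0.1, c(64, 64))
  expect_equal(psnr(ref, ref), 300)   # capped sentinel for an exact match
  expect_equal(nrmse(ref, ref), 0)
  expect_equal(ssim(ref, ref), 1, tolerance = 1e-12)
  expect_error(psnr(ref, ref[1:10, 1:10]), "shape mismatch")
  # known-noise PSNR closed form: 20 log10(max / sigma)
  sigma <- 0.05
  x <- ref + rnorm(length(ref), sd = sigma)
  expect_equal(psnr(x, ref), 20 * log10(max(ref) / sigma), tolerance = 0.5)
  # an image against its negative has negative structural similarity
  a <- array(0, c(32, 32))
  a[8:24, 8:24] <- outer(sin(1:17 / 2), cos(1:17 / 3)) + 2
  expect_lt(ssim(3 - a, a), 0)
})

# independent oracle: direct per-window double loop (no convolution code)
brute_ssim <- function(x, ref) {
  L <- max(ref); C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  r <- (seq_len(11) - 6)
  k <- exp(-r^2 / (2 * 1.5^2)); w <- outer(k, k); w <- w / sum(w)
  n <- nrow(x); m <- ncol(x)
  vals <- c()
  for (i in 6:(n - 5)) for (j in 6:(m - 5)) {
    wx <- x[(i - 5):(i + 5), (j - 5):(j + 5)]
    wr <- ref[(i - 5):(i + 5), (j - 5):(j + 5)]
    mx <- sum(w * wx); mr <- sum(w * wr)
    vx <- sum(w * wx^2) - mx^2; vr <- sum(w * wr^2) - mr^2
    cxr <- sum(w * wx * wr) - mx * mr
    vals <- c(vals, ((2 * mx * mr + C1) * (2 * cxr + C2)) /
                ((mx^2 + mr^2 + C1) * (vx + vr + C2)))
  }
  mean(vals)
}

test_that("SSIM matches a brute-force window-by-window evaluation", {
  set.seed(3)
  ref <- array(abs(rnorm(24 * 20)) + 0.2, c(24, 20))
  x <- ref + rnorm(length(ref), sd = 0.1)
  expect_equal(ssim(x, ref), brute_ssim(x, ref), tolerance = 1e-10)
})

test_that("DTI fit inverts the simulator's signal model exactly", {
  prot <- protocol_spec(seed = 5L)  # 1 b0 + 20 directions, b = 1000
  spec <- default_phantom(c(2L, 24L, 24L))
  truth <- make_ground_truth(spec, prot)
  maps <- dwiunroll:::phantom_maps(spec)
  tm <- fit_dti(Mod(truth), prot$bvals, prot$bvecs)
  sup <- maps$S0 > 0
  expect_lt(max(abs(tm$S0[sup] - maps$S0[sup]) / maps$S0[sup]), 1e-6)
  scale <- max(abs(maps$D6))
  for (k in 1:6) {
    err <- abs(tm$D6[k, , , ][sup] - maps$D6[k, , , ][sup])
    expect_lt(max(err) / scale, 1e-6)
  }
  # isotropic voxels have FA 0; anisotropic stick tends to FA 1
  iso_vox <- sup & abs(maps$D6[1, , , ] - maps$D6[2, , , ]) < 1e-12 &
    abs(maps$D6[4, , , ]) < 1e-12
  expect_lt(max(tm$fa[iso_vox]), 1e-6)
  expect_true(all(tm$fa >= 0 & tm$fa <= 1))
  expect_true(all(diff(tm$evals[3:1, 1, 12, 12]) >= 0))  # sorted eigenvalues
})

test_that("stick tensors give FA near 1 and cFA encodes the axis", {
  shape <- c(1L, 8L, 8L)
  D <- diag(c(1.5e-3, 1e-6, 1e-6))
  spec <- phantom_spec(shape, list(list(cy = 0, cx = 0, ry = 0.45, rx = 0.45,
                                        angle = 0, S0 = 1, D = D)))
  prot <- protocol_spec(bvals = c(0, rep(1000, 8)),
                        bvecs = cbind(0, make_bvecs(8, seed = 2)),
                        n_shots = 1L, r_inplane = 1L, mb_factor = 1L,
                        partial_fourier = 1, seed = 2L)
  truth <- make_ground_truth(spec, prot)
  tm <- fit_dti(Mod(truth), prot$bvals, prot$bvecs)
  expect_gt(tm$fa[1, 4, 4], 0.99)
  expect_gt(abs(tm$e1[1, 1, 4, 4]), 0.99)  # principal axis along x
  expect_equal(tm$cfa[1, 1, 4, 4], tm$fa[1, 4, 4] * abs(tm$e1[1, 1, 4, 4]))
})

test_that("FA is invariant under joint rotation of tensors and directions", {
  set.seed(9)
  # random rotation via QR of a random matrix
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  D <- rot_tensor(c(1.6e-3, 0.4e-3, 0.2e-3), 25)
  spec1 <- phantom_spec(c(1L, 8L, 8L),
                        list(list(cy = 0, cx = 0, ry = 0.45, rx = 0.45,
                                  angle = 0, S0 = 1, D = D)))
  spec2 <- phantom_spec(c(1L, 8L, 8L),
                        list(list(cy = 0, cx = 0, ry = 0.45, rx = 0.45,
                                  angle = 0, S0 = 1,
                                  D = qr_R %*% D %*% t(qr_R))))
  g <- make_bvecs(10, seed = 4)
  prot1 <- protocol_spec(bvals = c(0, rep(1000, 10)), bvecs = cbind(0, g),
                         n_shots = 1L, r_inplane = 1L, mb_factor = 1L,
                         partial_fourier = 1, seed = 3L)
  prot2 <- protocol_spec(bvals = c(0, rep(1000, 10)),
                         bvecs = cbind(0, qr_R %*% g), n_shots = 1L,
                         r_inplane = 1L, mb_factor = 1L, partial_fourier = 1,
                         seed = 3L)
  t1 <- fit_dti(Mod(make_ground_truth(spec1, prot1)), prot1$bvals, prot1$bvecs)
  t2 <- fit_dti(Mod(make_ground_truth(spec2, prot2)), prot2$bvals, prot2$bvecs)
  expect_equal(t1$fa[1, 4, 4], t2$fa[1, 4, 4], tolerance = 1e-8)
})

test_that("degenerate designs are rejected with informative errors", {
  sig <- array(1, c(7, 1, 2, 2))
  expect_error(fit_dti(sig, rep(1000, 7), make_bvecs(7, 1)), "b = 0")
  # collinear directions cannot span the tensor space
  g_bad <- matrix(rep(c(1, 0, 0), 7), 3)
  expect_error(fit_dti(array(1, c(8, 1, 2, 2)), c(0, rep(1000, 7)),
                       cbind(0, g_bad)), "singular design")
})
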