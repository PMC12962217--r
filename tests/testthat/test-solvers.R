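# CG, the data-consistency update, singular value thresholding and the
# locally low rank machinery.

test_that("CG returns the rhs in one iteration for the identity map", {
  set.seed(1)
  b <- array(rand_complex(24), c(2, 1, 3, 4))
  x <- conjugate_gradient(b, function(v) v, n_iter = 1)
  expect_lt(max(Mod(x - b)), 1e-13)
})

test_that("CG terminates exactly on SPD systems of dimension <= 6", {
  for (n in 2:6) {
    set.seed(n)
    M <- matrix(rnorm(n * n), n)
    A <- crossprod(M) + diag(n)  # SPD
    b <- rnorm(n)
    ref <- solve(A, b)           # direct dense oracle
    x <- conjugate_gradient(b, function(v) as.vector(A %*% v), n_iter = n)
    expect_lt(max(abs(x - ref)), 1e-8 * max(abs(ref)))
    rn <- attr(x, "resnorm")
    expect_lt(rn[length(rn)], 1e-8 * rn[1])
    # the energy norm of the error is the monotone CG quantity
    enorm <- vapply(seq_len(n), function(k) {
      xk <- conjugate_gradient(b, function(v) as.vector(A %*% v), n_iter = k)
      e <- xk - ref
      sqrt(Re(sum(e * (A %*% e))))
    }, numeric(1))
    expect_true(all(diff(enorm) <= 1e-10))
  }
  # default budget matches the unrolled algorithm
  expect_identical(formals(conjugate_gradient)$n_iter, 6L)
})

test_that("compiled CG on the normal operator matches the generic R CG", {
  ti <- tiny_instance(Ny = 8, Nx = 8, seed = 21)
  y <- dwiunroll:::mask_kspace(rand_kspace(ti$dims), ti$enc$mask)
  b <- apply_adjoint(y, ti$enc)
  rho <- 0.2
  xr <- conjugate_gradient(b, function(v) normal_op(v, ti$enc, rho), 6L)
  xc <- dwiunroll:::cg_normal(b, ti$enc, rho, 6L)
  expect_lt(max(Mod(xr - xc)), 1e-10)
})

test_that("x_update solves the damped normal equations", {
  ti <- tiny_instance(Nd = 1, Ns = 2, Nc = 2, Nz = 1, Ny = 8, Nx = 8,
                      seed = 31)
  A <- dense_forward_matrix(ti$enc, ti$dims)
  y <- dwiunroll:::mask_kspace(rand_kspace(ti$dims), ti$enc$mask)
  v <- rand_stack(ti$dims)
  u <- rand_stack(ti$dims)
  rho <- 0.4
  N <- Conj(t(A)) %*% A + (rho / 2) * diag(ncol(A))
  rhs <- Conj(t(A)) %*% as.vector(y) + (rho / 2) * as.vector(v - u)
  ref <- solve(N, rhs)
  x <- x_update(y, ti$enc, v, u, rho, cg_iters = 300L, tol = 1e-14)
  expect_lt(max(Mod(as.vector(x) - ref)), 1e-8)
  # identity encodings, full mask, rho = 0: x is the inverse FFT of y
  enc <- identity_enc()
  y0 <- array(rand_complex(64), c(1, 1, 1, 8, 8))
  x0 <- x_update(y0, enc, rho = 0, cg_iters = 2L)
  expect_lt(max(Mod(x0[1, 1, , ] - ref_cfft2(y0[1, 1, 1, , ], inverse = TRUE))),
            1e-10)
  # rho -> infinity forces x -> v - u
  xinf <- x_update(y, ti$enc, v, u, rho = 1e10, cg_iters = 50L)
  expect_lt(max(Mod(xinf - (v - u))) / max(Mod(v - u)), 1e-6)
})

test_that("singular value thresholding obeys its closed forms", {
  set.seed(5)
  M <- matrix(rand_complex(35), 7, 5)
  expect_identical(svt_block(M, 0), M)
  expect_lt(max(Mod(svt_block(M, svd(M)$d[1] + 1))), 1e-14)
  # rank-1: a * u v^H thresholded at a/2 gives (a/2) u v^H
  u <- rand_complex(7); u <- u / sqrt(sum(Mod(u)^2))
  v <- rand_complex(5); v <- v / sqrt(sum(Mod(v)^2))
  a <- 3
  M1 <- a * u %*% Conj(t(v))
  expect_lt(max(Mod(svt_block(M1, a / 2) - (a / 2) * u %*% Conj(t(v)))), 1e-12)
  # non-expansiveness on random pairs
  for (i in 1:10) {
    A <- matrix(rand_complex(24), 6)
    B <- matrix(rand_complex(24), 6)
    tau <- runif(1, 0, 2)
    expect_lte(sqrt(sum(Mod(svt_block(A, tau) - svt_block(B, tau))^2)),
               sqrt(sum(Mod(A - B)^2)) + 1e-12)
  }
})

# brute-force LLR oracle: explicit per-patch loop, zero padding, no shared
# code with llr_prox internals
brute_llr <- function(x, bs, tau, off) {
  d <- dim(x)
  py <- bs * ceiling((d[3] + off[1]) / bs)
  px <- bs * ceiling((d[4] + off[2]) / bs)
  out <- x
  for (z in seq_len(d[2])) {
    pad <- array(0i, c(d[1], py, px))
    pad[, off[1] + seq_len(d[3]), off[2] + seq_len(d[4])] <- x[, z, , ]
    res <- pad
    for (by in seq_len(py / bs)) for (bx in seq_len(px / bs)) {
      iy <- (by - 1) * bs + seq_len(bs); ix <- (bx - 1) * bs + seq_len(bs)
      M <- matrix(0i, bs * bs, d[1])
      for (dd in seq_len(d[1])) M[, dd] <- as.vector(pad[dd, iy, ix])
      sv <- svd(M)
      keep <- pmax(sv$d - tau, 0)
      M2 <- sv$u %*% diag(keep, length(keep)) %*% Conj(t(sv$v))
      for (dd in seq_len(d[1])) res[dd, iy, ix] <- M2[, dd]
    }
    out[, z, , ] <- res[, off[1] + seq_len(d[3]), off[2] + seq_len(d[4])]
  }
  out
}

test_that("llr_prox matches the brute-force per-patch SVD oracle", {
  set.seed(8)
  x <- array(rand_complex(3 * 2 * 16 * 16), c(3, 2, 16, 16))
  cfg <- llr_config(block_size = 4L, threshold = 0.8, shift_seed = 3L)
  for (it in c(1L, 2L, 5L)) {
    off <- dwiunroll:::llr_offset(cfg, it)
    expect_lt(max(Mod(llr_prox(x, cfg, it) - brute_llr(x, 4L, 0.8, off))),
              1e-10)
  }
  # threshold 0 is the identity; energy never increases
  expect_identical(llr_prox(x, llr_config(block_size = 4L, threshold = 0)), x)
  out <- llr_prox(x, cfg)
  expect_lte(sqrt(sum(Mod(out)^2)), sqrt(sum(Mod(x)^2)))
  # constant-along-diffusion stacks are rank 1 per patch: shrinkage only
  xc <- array(rep(rand_complex(2 * 16 * 16), each = 3), c(3, 2, 16, 16))
  oc <- llr_prox(xc, llr_config(block_size = 4L, threshold = 1e-9))
  expect_lt(max(Mod(oc - xc)), 1e-6)
  expect_error(llr_prox(x, llr_config(block_size = 32L, threshold = 1)),
               "block larger")
})

test_that("ADMM-LLR reconstructs toys and improves on zero filling", {
  # noiseless fully sampled: near-exact recovery
  sim <- small_sim(Ndwi = 2, n_shots = 1L, mb = 1L, n_coils = 3L,
                   phase_amp = 0, n = 16L)
  cfg <- llr_config(block_size = 4L, threshold = 1e-4, n_iter = 25L)
  x <- admm_llr(sim$kspace, sim$enc, cfg, rho = 0.05, cg_iters = 15L)
  expect_lt(dwiunroll:::rel_err(x, sim$truth), 1e-3)
  # undersampled noisy toy: beats the zero-filled adjoint
  prot <- protocol_spec(bvals = c(0, rep(1000, 4)), n_shots = 3L,
                        r_inplane = 2L, mb_factor = 2L, partial_fourier = 5 / 8,
                        n_coils = 4L, phase_amplitude = 0.5, noise_sd = 0,
                        seed = 31L)
  sim2 <- suppressWarnings(simulate_kspace(prot, n_y = 24L, n_x = 24L))
  prot$noise_sd <- noise_sd_for_snr(sim2$kspace, 20)
  sim2 <- suppressWarnings(simulate_kspace(prot, n_y = 24L, n_x = 24L))
  cfg2 <- llr_config(block_size = 6L, threshold = 0.02, n_iter = 15L)
  xr <- admm_llr(sim2$kspace, sim2$enc, cfg2, rho = 0.05)
  x0 <- apply_adjoint(sim2$kspace$data, sim2$enc)
  expect_gt(psnr(xr, sim2$truth), psnr(x0, sim2$truth))
  # primal residual decreases on this well-conditioned toy
  pr <- attr(xr, "primal_resnorm")
  expect_lt(pr[length(pr)], pr[1])
})
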