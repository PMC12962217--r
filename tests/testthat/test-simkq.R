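# Synthetic acquisition generator: signal model, coils, phases, sampling
# geometry and the simulated k-space round trip.

test_that("ground truth follows the mono-exponential tensor signal model", {
  shape <- c(1L, 8L, 8L)
  # single-region phantom covering the centre voxel
  D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  spec <- phantom_spec(shape, list(list(cy = 0, cx = 0, ry = 0.4, rx = 0.4,
                                        angle = 0, S0 = 2, D = D)))
  prot <- protocol_spec(bvals = c(0, 1000, 1000),
                        bvecs = cbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        n_shots = 1L, r_inplane = 1L, mb_factor = 1L,
                        partial_fourier = 1, n_coils = 1L, seed = 2L)
  x <- make_ground_truth(spec, prot)
  ctr <- Mod(x[, 1, 5, 5])
  # b = 0 equals S0; closed forms along/perpendicular to the fast axis
  expect_equal(ctr[1], 2)
  expect_equal(ctr[2], 2 * exp(-1000 * 1.7e-3), tolerance = 1e-12)
  expect_equal(ctr[3], 2 * exp(-1000 * 0.3e-3), tolerance = 1e-12)
  # isotropic tensor: signal independent of direction
  spec_iso <- phantom_spec(shape, list(list(cy = 0, cx = 0, ry = 0.4, rx = 0.4,
                                            angle = 0, S0 = 1,
                                            D = diag(rep(1e-3, 3)))))
  g <- make_bvecs(5, seed = 3)
  prot_iso <- protocol_spec(bvals = c(0, rep(1000, 5)),
                            bvecs = cbind(0, g), n_shots = 1L, r_inplane = 1L,
                            mb_factor = 1L, partial_fourier = 1,
                            n_coils = 1L, seed = 2L)
  xi <- make_ground_truth(spec_iso, prot_iso)
  sig <- Mod(xi[2:6, 1, 5, 5])
  expect_lt(max(abs(sig - exp(-1))), 1e-12)
  # non-PSD tensor is rejected
  expect_error(phantom_spec(shape, list(list(cy = 0, cx = 0, ry = .3, rx = .3,
                                             angle = 0, S0 = 1,
                                             D = diag(c(1, 1, -1) * 1e-3)))),
               "positive semidefinite")
})

test_that("coil maps are SOS-normalized, smooth and reproducible", {
  S <- make_coils(4, c(2L, 16L, 16L), seed = 5)
  sos <- apply(Mod(S)^2, c(2, 3, 4), sum)
  expect_lt(max(abs(sos - 1)), 1e-6)
  expect_identical(S, make_coils(4, c(2L, 16L, 16L), seed = 5))
  expect_false(identical(S, make_coils(4, c(2L, 16L, 16L), seed = 6)))
  S1 <- make_coils(1, c(1L, 8L, 8L), seed = 1)
  expect_lt(max(abs(Mod(S1) - 1)), 1e-6)
})

test_that("shot phases are unit magnitude, seeded, and off for b0", {
  prot <- protocol_spec(bvals = c(0, 1000, 1000), n_shots = 2L,
                        r_inplane = 1L, mb_factor = 2L, partial_fourier = 1,
                        seed = 7L)
  Phi <- make_shot_phases(prot, c(2L, 12L, 12L))
  expect_lt(max(abs(Mod(Phi) - 1)), 1e-6)
  expect_lt(max(Mod(Phi[1, , , , ] - 1)), 1e-12)  # b0 volume unit phase
  expect_gt(max(Mod(Phi[2, 1, , , ] - 1)), 0.1)   # DWI volumes corrupted
  expect_identical(Phi, make_shot_phases(prot, c(2L, 12L, 12L)))
  # RMS phase close to the requested amplitude
  expect_equal(sqrt(mean(Arg(Phi[2, 1, 1, , ])^2)), prot$phase_amplitude,
               tolerance = 0.25)
  Phi0 <- make_shot_phases(prot, c(2L, 12L, 12L), amplitude = 0)
  expect_lt(max(Mod(Phi0 - 1)), 1e-12)
})

test_that("sampling masks realize the interleaved shift-encoded geometry", {
  prot <- protocol_spec(n_shots = 3L, r_inplane = 2L, partial_fourier = 5 / 8,
                        seed = 1L)
  expect_warning(m <- make_sampling(prot, 64L, 64L), "truncated")
  n_keep <- ceiling(5 / 8 * 64)
  # per-shot line count: ceiling(retained lines / 6) modulo residue effects
  lines <- apply(m[, , , 1], c(1, 2), sum)
  expect_true(all(lines %in% c(floor(n_keep / 6), ceiling(n_keep / 6))))
  # per-shot in-plane factor 6: sampled lines are 6 apart
  ky <- which(m[1, 1, , 1] == 1)
  expect_true(all(diff(ky) == 6))
  # partial Fourier removes the top lines
  expect_equal(sum(m[, , (n_keep + 1):64, ]), 0)
  # union over one diffusion volume's shots has in-plane factor 2
  u <- pmin(m[2, 1, , 1] + m[2, 2, , 1] + m[2, 3, , 1], 1)
  kyu <- which(u == 1)
  expect_true(all(diff(kyu) == 2))
  # all kx sampled on acquired lines
  expect_true(all(m[1, 1, ky, ] == 1))
  # shift encoding: union over 6 consecutive diffusion volumes of a fixed
  # shot covers all 6 residue classes
  m48 <- suppressWarnings(make_sampling(
    protocol_spec(bvals = c(0, rep(1000, 6)), n_shots = 3L, r_inplane = 2L,
                  partial_fourier = 1, seed = 1L), 48L, 8L))
  res <- sort(unique(unlist(lapply(1:6, function(d)
    which(m48[d, 1, , 1] == 1) %% 6))))
  expect_equal(res, 0:5)
  # trivial full mask
  mfull <- make_sampling(protocol_spec(bvals = 0, n_shots = 1L,
                                       r_inplane = 1L, partial_fourier = 1,
                                       seed = 1), 8L, 8L)
  expect_equal(sum(mfull), 64)
})

test_that("mask accounting: per-shot acceleration is mb * n_shots * r_inplane", {
  prot <- protocol_spec(n_shots = 3L, r_inplane = 2L, mb_factor = 2L,
                        partial_fourier = 1, seed = 1L)
  m <- suppressWarnings(make_sampling(prot, 48L, 8L))
  inplane_per_shot <- 48 / sum(m[1, 1, , 1])
  expect_equal(inplane_per_shot * prot$mb_factor, 12)
})

test_that("simulated k-space round-trips and obeys the noise law", {
  # noiseless, identity-like: 1 shot, 1 band, full sampling, no phases
  prot <- protocol_spec(bvals = c(0, 1000), n_shots = 1L, r_inplane = 1L,
                        mb_factor = 1L, partial_fourier = 1, n_coils = 3L,
                        phase_amplitude = 0, noise_sd = 0, seed = 4L)
  sim <- simulate_kspace(prot, n_y = 16L, n_x = 16L)
  rec <- apply_adjoint(sim$kspace$data, sim$enc)
  expect_lt(max(Mod(rec - sim$truth)), 1e-8)
  # every generated dataset satisfies the operator type invariants
  expect_s3_class(sim$enc, "encoding_operator")
  expect_s3_class(sim$kspace, "kspace_data")
  # retrospective 2-of-4-shot subsampling leaves in-plane factor 2
  prot4 <- protocol_spec(bvals = c(0, 1000), n_shots = 4L, r_inplane = 1L,
                         mb_factor = 1L, partial_fourier = 1, n_coils = 3L,
                         phase_amplitude = 0.3, noise_sd = 0, seed = 4L)
  sim4 <- simulate_kspace(prot4, n_y = 16L, n_x = 16L)
  sim2 <- subset_shots(sim4, c(1, 3))
  u <- pmin(sim2$enc$mask[1, 1, , 1] + sim2$enc$mask[1, 2, , 1], 1)
  expect_true(all(diff(which(u == 1)) == 2))
  expect_equal(dim(sim2$kspace$data)[2], 2L)
  # noise power: E sum |n|^2 = noise_sd^2 * #sampled entries, within 5%
  protn <- protocol_spec(bvals = c(0, 1000), n_shots = 1L, r_inplane = 1L,
                         mb_factor = 1L, partial_fourier = 1, n_coils = 8L,
                         phase_amplitude = 0, noise_sd = 0.5, seed = 12L)
  siman <- simulate_kspace(protn, n_y = 32L, n_x = 32L)
  sim0 <- simulate_kspace(protocol_spec(bvals = c(0, 1000), n_shots = 1L,
                                        r_inplane = 1L, mb_factor = 1L,
                                        partial_fourier = 1, n_coils = 8L,
                                        phase_amplitude = 0, noise_sd = 0,
                                        seed = 12L), n_y = 32L, n_x = 32L)
  n_samp <- sum(siman$kspace$mask) * 8
  expect_gt(n_samp, 1e4)
  noise_power <- sum(Mod(siman$kspace$data - sim0$kspace$data)^2)
  expect_equal(noise_power, 0.5^2 * n_samp, tolerance = 0.05)
  # bit-identical under a fixed seed
  expect_identical(simulate_kspace(protn, n_y = 32L, n_x = 32L)$kspace$data,
                   siman$kspace$data)
})
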