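# Synthetic multi-band multi-shot DWI k-space generator with known ground
# truth. The default protocol mirrors the submillimeter 3-shot acquisition
# scaled to desk size: 1 b0 + 20 diffusion directions at b = 1000 s/mm2,
# 3 shots per direction, combined in-plane acceleration 2 (so per-shot
# in-plane factor 6), multi-band 2, 5/8 partial Fourier, with the starting
# ky line shifted by one between adjacent diffusion directions so that
# k-q-space sampling is complementary.

#' Acquisition protocol specification
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per diffusion
#'   volume (include the b = 0 volume).
#' @param bvecs 3 x Ndiff matrix of unit diffusion directions (the b0
#'   column is ignored). Default: deterministic electrostatically spread
#'   directions from [make_bvecs()].
#' @param n_shots EPI shots (interleaves) per diffusion volume.
#' @param r_inplane combined in-plane acceleration of one diffusion
#'   volume's shot union; the per-shot in-plane factor is
#'   `n_shots * r_inplane`.
#' @param mb_factor multi-band (simultaneous-slice) factor.
#' @param partial_fourier fraction of ky space acquired, in (1/2, 1].
#' @param delta_shift ky-line shift between adjacent diffusion volumes.
#' @param n_coils number of receive coils.
#' @param phase_amplitude RMS amplitude (radians) of the smooth random
#'   shot-to-shot phase corruption fields.
#' @param noise_sd standard deviation of the complex Gaussian measurement
#'   noise per sampled k-space point (0 = noiseless).
#' @param seed integer seed driving all randomness of the simulator.
#' @return a `protocol_spec` list.
#' @export
protocol_spec <- function(bvals = c(0, rep(1000, 20)),
                          bvecs = NULL,
                          n_shots = 3L,
                          r_inplane = 2L,
                          mb_factor = 2L,
                          partial_fourier = 5 / 8,
                          delta_shift = 1L,
                          n_coils = 8L,
                          phase_amplitude = 0.8,
                          noise_sd = 0,
                          seed = 1L) {
  n_diff <- length(bvals)
  if (is.null(bvecs)) {
    nb <- sum(bvals > 0)
    bv <- make_bvecs(nb, seed = derive_seed(seed, "bvecs"))
    bvecs <- matrix(0, 3, n_diff)
    bvecs[, bvals > 0] <- bv
  }
  if (!is.matrix(bvecs) || nrow(bvecs) != 3 || ncol(bvecs) != n_diff)
    stop("bvecs must be a 3 x length(bvals) matrix")
  if (n_shots < 1) stop("n_shots must be >= 1")
  if (partial_fourier <= 1 / 2 || partial_fourier > 1)
    stop("partial_fourier must be in (1/2, 1]")
  if (phase_amplitude < 0) stop("phase_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    n_diff = as.integer(n_diff), bvals = as.double(bvals), bvecs = bvecs,
    n_shots = as.integer(n_shots), r_inplane = as.integer(r_inplane),
    mb_factor = as.integer(mb_factor), partial_fourier = partial_fourier,
    delta_shift = as.integer(delta_shift), n_coils = as.integer(n_coils),
    phase_amplitude = phase_amplitude, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "protocol_spec")
}

#' Deterministic electrostatically spread diffusion directions
#'
#' Unit vectors spread on the sphere by minimizing the electrostatic
#' (Coulomb) energy of antipodal point pairs, starting from a seeded
#' uniform draw; used as the default diffusion-direction table.
#'
#' @param n number of directions.
#' @param seed integer seed for the starting configuration.
#' @param n_iter descent iterations.
#' @return 3 x n matrix of unit column vectors.
#' @export
make_bvecs <- function(n, seed = 1L, n_iter = 200L) {
  g <- with_seed(seed, {
    v <- matrix(rnorm(3 * n), 3, n)
    sweep(v, 2, sqrt(colSums(v^2)), "/")
  })
  step <- 0.05
  for (it in seq_len(n_iter)) {
    f <- matrix(0, 3, n)
    for (i in seq_len(n)) {
      d <- g - g[, i]
      d2 <- colSums(d^2); d2[i] <- Inf
      da <- g + g[, i]             # antipode interactions
      da2 <- colSums(da^2); da2[i] <- Inf
      f[, i] <- -rowSums(sweep(d, 2, d2^1.5, "/")) +
        rowSums(sweep(da, 2, da2^1.5, "/"))
    }
    disp <- step * f
    # cap the displacement so near-coincident starting points cannot make
    # the descent overshoot
    dn <- sqrt(colSums(disp^2))
    too_big <- dn > 0.1
    if (any(too_big))
      disp[, too_big] <- sweep(disp[, too_big, drop = FALSE], 2,
                               dn[too_big] / 0.1, "/")
    g <- g + disp
    g <- sweep(g, 2, sqrt(colSums(g^2)), "/")
  }
  g
}

#' Ellipse phantom specification
#'
#' A stack of 2D ellipse regions painted in order (later regions override
#' earlier ones), each carrying a proton-density value `S0` and a symmetric
#' positive-semidefinite diffusion tensor `D` in mm^2/s. Region geometry is
#' given in fractional field-of-view units (centre offsets and semi-axes in
#' \[-0.5, 0.5\]).
#'
#' @param shape integer vector `(Nz, Ny, Nx)`.
#' @param regions list of regions; each a list with `cy, cx` (centre), `ry,
#'   rx` (semi-axes), `angle` (degrees), `S0`, `D` (3x3 PSD matrix), and
#'   optionally `slices` (1-based z indices, default all) and `slice_shift`
#'   (fractional per-slice centre shift).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape, regions) {
  stopifnot(length(shape) == 3)
  for (r in regions) {
    ev <- eigen(r$D, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-12 * max(abs(ev)))
      stop("diffusion tensors must be positive semidefinite")
    if (abs(r$cy) + r$ry > 0.5 + 1e-9 || abs(r$cx) + r$rx > 0.5 + 1e-9)
      stop("region extends beyond the image bounds")
  }
  structure(list(shape = as.integer(shape), regions = regions),
            class = "phantom_spec")
}

#' Rotate an axis-aligned diffusion tensor in the imaging plane
#'
#' Builds `R diag(lambda) R'` for a rotation by `angle_deg` degrees about
#' the slice axis; convenience for phantom construction.
#'
#' @param lambda eigenvalues (mm^2/s), length 3.
#' @param angle_deg in-plane rotation angle in degrees.
#' @return 3x3 symmetric PSD matrix.
#' @export
rot_tensor <- function(lambda, angle_deg) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  R %*% diag(lambda) %*% t(R)
}

#' Default brain-like ellipse phantom
#'
#' An outer fast-diffusing isotropic rim with interior anisotropic
#' (white-matter-like) and isotropic (gray-matter-like) blobs; region
#' centres drift slightly with slice index so simultaneous-band slices have
#' distinct content.
#'
#' @inheritParams phantom_spec
#' @return a `phantom_spec`.
#' @export
default_phantom <- function(shape) {
  iso <- function(d) diag(rep(d, 3))
  regions <- list(
    list(cy = 0, cx = 0, ry = 0.44, rx = 0.40, angle = 0, S0 = 1.0,
         D = iso(2.0e-3), slice_shift = 0),
    list(cy = -0.14, cx = -0.10, ry = 0.16, rx = 0.11, angle = 30, S0 = 0.85,
         D = rot_tensor(c(1.7e-3, 0.3e-3, 0.3e-3), 30), slice_shift = 0.04),
    list(cy = 0.12, cx = 0.14, ry = 0.13, rx = 0.09, angle = -50, S0 = 0.9,
         D = rot_tensor(c(1.5e-3, 0.25e-3, 0.25e-3), -50), slice_shift = -0.05),
    list(cy = 0.16, cx = -0.17, ry = 0.10, rx = 0.08, angle = 0, S0 = 0.8,
         D = iso(0.9e-3), slice_shift = 0.03),
    list(cy = -0.05, cx = 0.2, ry = 0.07, rx = 0.06, angle = 80, S0 = 0.95,
         D = rot_tensor(c(1.2e-3, 0.2e-3, 0.2e-3), 80), slice_shift = -0.03))
  phantom_spec(shape, regions)
}

# Per-voxel S0 and tensor maps painted from the ellipse regions.
phantom_maps <- function(spec) {
  Nz <- spec$shape[1]; Ny <- spec$shape[2]; Nx <- spec$shape[3]
  S0 <- array(0, c(Nz, Ny, Nx))
  D6 <- array(0, c(6, Nz, Ny, Nx))  # Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
  u <- (seq_len(Ny) - 1) / Ny - 0.5 + 0.5 / Ny
  v <- (seq_len(Nx) - 1) / Nx - 0.5 + 0.5 / Nx
  U <- matrix(u, Ny, Nx); V <- matrix(v, Ny, Nx, byrow = TRUE)
  for (r in spec$regions) {
    slices <- if (is.null(r$slices)) seq_len(Nz) else r$slices
    shift <- if (is.null(r$slice_shift)) 0 else r$slice_shift
    a <- r$angle * pi / 180
    for (z in slices) {
      cy <- r$cy + shift * (z - 1); cx <- r$cx - shift * (z - 1)
      du <- U - cy; dv <- V - cx
      ru <- cos(a) * du + sin(a) * dv
      rv <- -sin(a) * du + cos(a) * dv
      inside <- (ru / r$ry)^2 + (rv / r$rx)^2 <= 1
      S0[z, , ][inside] <- r$S0
      dvec <- c(r$D[1, 1], r$D[2, 2], r$D[3, 3], r$D[1, 2], r$D[1, 3], r$D[2, 3])
      for (k in 1:6) D6[k, z, , ][inside] <- dvec[k]
    }
  }
  list(S0 = S0, D6 = D6)
}

#' Ground-truth diffusion-weighted image stack
#'
#' Paints the phantom and evaluates the mono-exponential tensor signal
#' model `S = S0 * exp(-b g' D g)` for every diffusion volume; the b = 0
#' volume equals the S0 map.
#'
#' @param spec a [phantom_spec()].
#' @param prot a [protocol_spec()].
#' @return complex image stack `(Ndiff, Nz, Ny, Nx)` (zero imaginary part).
#' @export
make_ground_truth <- function(spec, prot) {
  maps <- phantom_maps(spec)
  Nz <- spec$shape[1]; Ny <- spec$shape[2]; Nx <- spec$shape[3]
  Nd <- prot$n_diff
  x <- array(0, c(Nd, Nz, Ny, Nx))
  d6 <- function(k) array(maps$D6[k, , , ], dim(maps$S0))
  for (d in seq_len(Nd)) {
    b <- prot$bvals[d]
    if (b == 0) {
      x[d, , , ] <- maps$S0
    } else {
      g <- prot$bvecs[, d]
      # g' D g from the 6 unique tensor components
      q <- g[1]^2 * d6(1) + g[2]^2 * d6(2) + g[3]^2 * d6(3) +
        2 * g[1] * g[2] * d6(4) + 2 * g[1] * g[3] * d6(5) +
        2 * g[2] * g[3] * d6(6)
      x[d, , , ] <- maps$S0 * exp(-b * q)
    }
  }
  x <- x + 0i
  dim(x) <- c(Nd, Nz, Ny, Nx)
  x
}

#' Smooth synthetic coil sensitivity maps
#'
#' Gaussian-profile magnitudes centred on points around the field of view
#' with low-order polynomial phases, normalized so the coil sum of squares
#' is exactly 1 on the support.
#'
#' @param n_coils number of coils.
#' @param shape integer `(Nz, Ny, Nx)`.
#' @param seed integer seed.
#' @param support optional logical/0-1 array `(Nz, Ny, Nx)`; maps are zero
#'   outside it (default: full field of view).
#' @return complex array `(Nc, Nz, Ny, Nx)`.
#' @export
make_coils <- function(n_coils, shape, seed = 1L, support = NULL) {
  stopifnot(n_coils >= 1, length(shape) == 3)
  Nz <- shape[1]; Ny <- shape[2]; Nx <- shape[3]
  u <- (seq_len(Ny) - 1) / Ny - 0.5
  v <- (seq_len(Nx) - 1) / Nx - 0.5
  U <- matrix(u, Ny, Nx); V <- matrix(v, Ny, Nx, byrow = TRUE)
  S <- array(0i, c(n_coils, Nz, Ny, Nx))
  coefs <- with_seed(seed, array(rnorm(n_coils * Nz * 6, sd = 1.5),
                                 c(n_coils, Nz, 6)))
  for (cc in seq_len(n_coils)) {
    ang <- 2 * pi * (cc - 1) / n_coils
    cy <- 0.55 * sin(ang); cx <- 0.55 * cos(ang)
    for (z in seq_len(Nz)) {
      r2 <- (U - cy)^2 + (V - cx)^2
      mag <- exp(-r2 / (2 * 0.45^2))
      p <- coefs[cc, z, ]
      ph <- p[1] + p[2] * U + p[3] * V + 0.5 * (p[4] * U^2 + p[5] * U * V +
                                                  p[6] * V^2)
      S[cc, z, , ] <- mag * exp(1i * ph)
    }
  }
  sos <- sqrt(apply(Mod(S)^2, c(2, 3, 4), sum))
  for (cc in seq_len(n_coils))
    S[cc, , , ] <- array(S[cc, , , ], dim(sos)) / sos
  if (!is.null(support)) {
    sup <- array(as.logical(support), c(Nz, Ny, Nx))
    for (cc in seq_len(n_coils)) {
      plane <- S[cc, , , , drop = FALSE]
      plane[!array(sup, dim(plane))] <- 0i
      S[cc, , , ] <- plane
    }
  }
  S
}

#' Smooth random shot-to-shot phase corruption maps
#'
#' Unit-magnitude maps whose phase is a smooth low-order 2D polynomial
#' random field (plus a random linear ramp) per (diffusion, shot), scaled
#' to the requested RMS amplitude. All shots of b = 0 volumes default to
#' zero phase (diffusion encoding off implies no motion-induced phase),
#' which also pins the gauge of the first shot.
#'
#' @param prot a [protocol_spec()].
#' @param shape integer `(Nz, Ny, Nx)`.
#' @param amplitude RMS phase amplitude in radians (default from `prot`).
#' @param seed integer seed (default derived from `prot$seed`).
#' @param b0_unit if `TRUE` (default) b = 0 volumes get unit phase maps.
#' @return complex array `(Ndiff, Ns, Nz, Ny, Nx)` with unit magnitude.
#' @export
make_shot_phases <- function(prot, shape, amplitude = prot$phase_amplitude,
                             seed = derive_seed(prot$seed, "phases"),
                             b0_unit = TRUE) {
  stopifnot(amplitude >= 0, length(shape) == 3)
  Nz <- shape[1]; Ny <- shape[2]; Nx <- shape[3]
  Nd <- prot$n_diff; Ns <- prot$n_shots
  u <- (seq_len(Ny) - 1) / Ny - 0.5
  v <- (seq_len(Nx) - 1) / Nx - 0.5
  U <- matrix(u, Ny, Nx); V <- matrix(v, Ny, Nx, byrow = TRUE)
  Phi <- array(1 + 0i, c(Nd, Ns, Nz, Ny, Nx))
  coefs <- with_seed(seed, array(rnorm(Nd * Ns * Nz * 8), c(Nd, Ns, Nz, 8)))
  for (d in seq_len(Nd)) {
    if (b0_unit && prot$bvals[d] == 0) next
    for (s in seq_len(Ns)) for (z in seq_len(Nz)) {
      p <- coefs[d, s, z, ]
      f <- p[1] + 2 * (p[2] * U + p[3] * V) + p[4] * U^2 + p[5] * U * V +
        p[6] * V^2 + 2 * pi * 0.3 * (p[7] * U + p[8] * V)
      if (amplitude > 0) {
        f <- f * amplitude / sqrt(mean(f^2))
        Phi[d, s, z, , ] <- exp(1i * f)
      }
    }
  }
  Phi
}

#' CAIPI multi-band phase ramps
#'
#' Linear per-slice phase ramps along ky implementing the controlled
#' inter-slice image shift that makes simultaneously excited slices
#' separable. The default shifts adjacent slices by half the field of view.
#'
#' @param mb_factor number of simultaneous slices.
#' @param n_ky number of ky lines.
#' @param fov_shift image-domain shift per slice as a fraction of the field
#'   of view (default 1/2).
#' @return complex matrix `(Nz, Ny)` of unit magnitude; slice 1 has zero
#'   phase.
#' @export
make_caipi_phases <- function(mb_factor, n_ky, fov_shift = 0.5) {
  z <- 0:(mb_factor - 1)
  ky <- 0:(n_ky - 1)
  exp(2i * pi * fov_shift * outer(z, ky))
}

#' Interleaved shot sampling masks with diffusion shift encoding
#'
#' Shot `s` of diffusion volume `d` samples the ky lines with
#' `ky mod R == (d * delta + s * r_inplane) mod R` (0-based), where
#' `R = n_shots * r_inplane` is the per-shot in-plane factor; all kx are
#' sampled on an acquired line. Partial Fourier removes the top
#' `(1 - pf) * Ny` ky lines. The union of one volume's shots has in-plane
#' factor `r_inplane`, and shifting the start line by `delta` per diffusion
#' volume makes sampling complementary across the diffusion dimension.
#'
#' @param prot a [protocol_spec()].
#' @param n_ky,n_kx matrix size.
#' @return 0/1 array `(Ndiff, Ns, Ny, Nx)`.
#' @export
make_sampling <- function(prot, n_ky, n_kx) {
  R <- prot$n_shots * prot$r_inplane
  if (n_ky %% R != 0)
    warning(sprintf("pattern period %d does not divide %d ky lines; pattern truncated",
                    R, n_ky))
  n_keep <- as.integer(ceiling(prot$partial_fourier * n_ky - 1e-9))
  mask <- array(0, c(prot$n_diff, prot$n_shots, n_ky, n_kx))
  ky <- 0:(n_ky - 1)
  for (d in seq_len(prot$n_diff)) for (s in seq_len(prot$n_shots)) {
    start <- ((d - 1) * prot$delta_shift + (s - 1) * prot$r_inplane) %% R
    lines <- ky[ky %% R == start & ky < n_keep]
    mask[d, s, lines + 1, ] <- 1
  }
  mask
}

#' Simulate a multi-band multi-shot DWI acquisition
#'
#' Builds ground truth, coil maps, shot-to-shot phase corruption, CAIPI
#' phases and sampling masks from the protocol, applies the forward
#' encoding operator and adds complex Gaussian noise on the sampled
#' locations.
#'
#' @param spec a [phantom_spec()]; default [default_phantom()] at the given
#'   matrix size.
#' @param prot a [protocol_spec()].
#' @param n_y,n_x matrix size (used when `spec` is `NULL`).
#' @return list with components `kspace` ([kspace_data()]), `truth`
#'   (complex image stack) and `enc` (the true [encoding_operator()]).
#' @export
simulate_kspace <- function(prot, spec = NULL, n_y = 64L, n_x = 64L) {
  if (is.null(spec)) spec <- default_phantom(c(prot$mb_factor, n_y, n_x))
  shape <- spec$shape
  if (shape[1] != prot$mb_factor)
    stop("phantom Nz must equal the multi-band factor")
  truth <- make_ground_truth(spec, prot)
  coils <- make_coils(prot$n_coils, shape, seed = derive_seed(prot$seed, "coils"))
  phases <- make_shot_phases(prot, shape)
  mb <- make_caipi_phases(prot$mb_factor, shape[2])
  mask <- make_sampling(prot, shape[2], shape[3])
  enc <- encoding_operator(coils, phases, mb, mask)
  y <- apply_forward(truth, enc)
  if (prot$noise_sd > 0) {
    dm <- dim(y)
    noise <- with_seed(derive_seed(prot$seed, "noise"), {
      array(complex(real = rnorm(prod(dm), sd = prot$noise_sd / sqrt(2)),
                    imaginary = rnorm(prod(dm), sd = prot$noise_sd / sqrt(2))),
            dm)
    })
    m5 <- aperm(array(rep(mask, prot$n_coils), c(dim(mask), prot$n_coils)),
                c(1, 2, 5, 3, 4))
    y <- y + noise * m5
  }
  list(kspace = kspace_data(y, mask, noise_sd = prot$noise_sd),
       truth = truth, enc = enc)
}

#' Retrospectively keep a subset of shots
#'
#' Restricts a simulated acquisition to the given shots (e.g. keeping 2 of
#' 4 fully sampled shots yields 2-fold in-plane undersampling).
#'
#' @param sim result of [simulate_kspace()].
#' @param shots 1-based shot indices to keep.
#' @return list of the same structure as [simulate_kspace()].
#' @export
subset_shots <- function(sim, shots) {
  enc <- sim$enc
  enc2 <- encoding_operator(enc$coils,
                            enc$phases[, shots, , , , drop = FALSE],
                            enc$mb,
                            enc$mask[, shots, , , drop = FALSE])
  y2 <- sim$kspace$data[, shots, , , , drop = FALSE]
  list(kspace = kspace_data(y2, enc2$mask, noise_sd = sim$kspace$noise_sd),
       truth = sim$truth, enc = enc2)
}

#' Noise level for a target k-space signal-to-noise ratio
#'
#' @param y complex k-space array or [kspace_data()].
#' @param mask sampling mask matching `y` (taken from `y` if omitted).
#' @param snr target ratio of RMS sampled signal to per-sample noise RMS.
#' @return noise standard deviation.
#' @export
noise_sd_for_snr <- function(y, snr, mask = NULL) {
  if (inherits(y, "kspace_data")) {
    mask <- y$mask
    y <- y$data
  }
  stopifnot(!is.null(mask), snr > 0)
  n_samp <- sum(mask) * dim(y)[3]
  sqrt(sum(Mod(y)^2) / n_samp) / snr
}
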