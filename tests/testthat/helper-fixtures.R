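# Shared fixture builders: small random encoding instances, a dense
# materialization of the encoding operator, and a pure-R reference FFT.

rand_complex <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

# random, fully validated encoding instance
tiny_instance <- function(Nd = 2, Ns = 2, Nc = 2, Nz = 2, Ny = 8, Nx = 8,
                          mask_p = 0.7, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    coils <- array(rand_complex(Nc * Nz * Ny * Nx), c(Nc, Nz, Ny, Nx))
    sos <- sqrt(apply(Mod(coils)^2, c(2, 3, 4), sum))
    for (cc in seq_len(Nc))
      coils[cc, , , ] <- array(coils[cc, , , ], c(Nz, Ny, Nx)) / sos
    phases <- array(exp(1i * rnorm(Nd * Ns * Nz * Ny * Nx)),
                    c(Nd, Ns, Nz, Ny, Nx))
    mb <- make_caipi_phases(Nz, Ny)
    mask <- array(rbinom(Nd * Ns * Ny * Nx, 1, mask_p), c(Nd, Ns, Ny, Nx))
    mask[, , 1, 1] <- 1  # guarantee non-empty planes
    list(enc = encoding_operator(coils, phases, mb, mask),
         dims = c(Nd = Nd, Ns = Ns, Nc = Nc, Nz = Nz, Ny = Ny, Nx = Nx))
  })
}

rand_stack <- function(dims) {
  array(rand_complex(prod(dims[c("Nd", "Nz", "Ny", "Nx")])),
        unname(dims[c("Nd", "Nz", "Ny", "Nx")]))
}

rand_kspace <- function(dims) {
  array(rand_complex(prod(dims[c("Nd", "Ns", "Nc", "Ny", "Nx")])),
        unname(dims[c("Nd", "Ns", "Nc", "Ny", "Nx")]))
}

# identity-encoding operator: single coil/shot/slice, flat maps, full mask
identity_enc <- function(Ny = 8, Nx = 8) {
  encoding_operator(array(1 + 0i, c(1, 1, Ny, Nx)),
                    array(1 + 0i, c(1, 1, 1, Ny, Nx)),
                    array(1 + 0i, c(1, Ny)),
                    array(1, c(1, 1, Ny, Nx)))
}

# densely materialized matrix of the forward operator (columns = canonical
# basis images), the independent oracle for operator tests
dense_forward_matrix <- function(enc, dims) {
  nx <- prod(dims[c("Nd", "Nz", "Ny", "Nx")])
  ny <- prod(dims[c("Nd", "Ns", "Nc", "Ny", "Nx")])
  A <- matrix(0i, ny, nx)
  e <- array(0i, unname(dims[c("Nd", "Nz", "Ny", "Nx")]))
  for (j in seq_len(nx)) {
    e[j] <- 1
    A[, j] <- as.vector(apply_forward(e, enc))
    e[j] <- 0
  }
  A
}

# reference centered orthonormal FFT built on stats::fft (independent of
# the compiled path)
ref_cfft2 <- function(m, inverse = FALSE) {
  # fftshift: index 0 moves to floor(n/2); ifftshift is its inverse
  sh <- function(a) {
    n1 <- nrow(a); n2 <- ncol(a)
    k1 <- n1 - floor(n1 / 2); k2 <- n2 - floor(n2 / 2)
    a[c((k1 + 1):n1, 1:k1), c((k2 + 1):n2, 1:k2), drop = FALSE]
  }
  ish <- function(a) {
    n1 <- nrow(a); n2 <- ncol(a)
    a[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
      c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2)), drop = FALSE]
  }
  if (!inverse) sh(stats::fft(ish(m))) / sqrt(length(m))
  else sh(stats::fft(ish(m), inverse = TRUE)) / sqrt(length(m))
}

# small simulated acquisition used by several test files
small_sim <- function(Ndwi = 2, n_shots = 2L, r_inplane = 1L, mb = 2L,
                      pf = 1, n_coils = 3L, phase_amp = 0.5, noise = 0,
                      n = 16L, seed = 9L) {
  prot <- protocol_spec(bvals = c(0, rep(1000, Ndwi)), n_shots = n_shots,
                        r_inplane = r_inplane, mb_factor = mb,
                        partial_fourier = pf, n_coils = n_coils,
                        phase_amplitude = phase_amp, noise_sd = noise,
                        seed = seed)
  suppressWarnings(simulate_kspace(prot, n_y = n, n_x = n))
}
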