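# Self-gated shot-to-shot phase estimation and MUSE-style reconstruction.
#
# Motion during the diffusion-encoding gradients imprints a smooth,
# shot-specific phase on each interleave. Self-gating estimates that phase
# from each shot's own k-space: reconstruct the shot image alone
# (Tikhonov-regularized CG-SENSE), smooth it by windowing central k-space,
# and keep only the phase. A per-shot global phase constant is
# unobservable, so estimates are defined up to that gauge.

#' Configuration for shot-phase estimation
#'
#' @param method `"selfgated"` (estimate from the data) or `"navigated"`
#'   (pass provided navigator maps through unchanged).
#' @param smoothing fraction of central k-space covered by the Hann window
#'   used to smooth the shot image before taking its phase, in (0, 1].
#' @param cg_iters CG iterations of the per-shot reconstruction.
#' @param lambda_l2 Tikhonov weight of the per-shot reconstruction.
#' @return a `phase_config` list.
#' @export
phase_config <- function(method = c("selfgated", "navigated"),
                         smoothing = 0.25, cg_iters = 10L, lambda_l2 = 0.01) {
  method <- match.arg(method)
  if (smoothing <= 0 || smoothing > 1) stop("smoothing fraction must be in (0, 1]")
  structure(list(method = method, smoothing = smoothing,
                 cg_iters = as.integer(cg_iters), lambda_l2 = lambda_l2),
            class = "phase_config")
}

# Hann window covering the central `frac` of a (Ny, Nx) k-space plane.
hann_window <- function(n_y, n_x, frac) {
  wy <- floor(n_y * frac / 2)
  wx <- floor(n_x * frac / 2)
  h1 <- function(n, w) {
    cy <- floor(n / 2)  # centered-DFT origin
    k <- seq_len(n) - 1 - cy
    ifelse(abs(k) <= w, 0.5 * (1 + cos(pi * k / (w + 1))), 0)
  }
  outer(h1(n_y, wy), h1(n_x, wx))
}

#' Self-gated shot-to-shot phase estimation
#'
#' For every (diffusion, shot): reconstructs the shot image from that
#' shot's k-space alone by Tikhonov-regularized CG-SENSE (no shot-phase
#' term), applies a Hann window over the central fraction of its k-space,
#' and returns the unit-magnitude phase map `exp(i * angle(.))`.
#'
#' @param y k-space array `(Nd, Ns, Nc, Ny, Nx)` or [kspace_data()].
#' @param coils complex coil maps `(Nc, Nz, Ny, Nx)`.
#' @param mb CAIPI phase matrix `(Nz, Ny)`.
#' @param mask sampling mask `(Nd, Ns, Ny, Nx)` (taken from `y` when it is
#'   a [kspace_data()]).
#' @param cfg a [phase_config()].
#' @param navigator navigator phase maps `(Nd, Ns, Nz, Ny, Nx)`; returned
#'   unchanged when `cfg$method == "navigated"`.
#' @return unit-magnitude complex array `(Nd, Ns, Nz, Ny, Nx)`.
#' @export
estimate_shot_phases <- function(y, coils, mb, mask = NULL,
                                 cfg = phase_config(), navigator = NULL) {
  if (cfg$method == "navigated") {
    if (is.null(navigator)) stop("navigated mode requires navigator phase maps")
    return(navigator)
  }
  if (inherits(y, "kspace_data")) {
    mask <- y$mask
    y <- y$data
  }
  stopifnot(!is.null(mask))
  dy <- dim(y)
  Nd <- dy[1]; Ns <- dy[2]; Nc <- dy[3]; Ny <- dy[4]; Nx <- dy[5]
  Nz <- dim(coils)[2]
  phi <- array(1 + 0i, c(Nd, Ns, Nz, Ny, Nx))
  unit_phase <- array(1 + 0i, c(1, 1, Nz, Ny, Nx))
  W <- hann_window(Ny, Nx, cfg$smoothing)
  for (d in seq_len(Nd)) for (s in seq_len(Ns)) {
    if (sum(mask[d, s, , ]) == 0)
      stop(sprintf("empty shot: diffusion %d, shot %d", d, s))
    enc_ds <- encoding_operator(
      coils = coils,
      phases = unit_phase,
      mb = mb,
      mask = mask[d, s, , , drop = FALSE])
    dim(enc_ds$mask) <- c(1, 1, Ny, Nx)
    y_ds <- y[d, s, , , , drop = FALSE]
    y_ds <- aperm(y_ds, c(1, 2, 3, 4, 5))  # keep (1,1,Nc,Ny,Nx)
    shot_im <- x_update(y_ds, enc_ds, rho = 2 * cfg$lambda_l2,
                        cg_iters = cfg$cg_iters)
    for (z in seq_len(Nz)) {
      k <- cfft2(shot_im[1, z, , ])
      sm <- cfft2(k * W, inverse = TRUE)
      phi[d, s, z, , ] <- exp(1i * Arg(sm))
    }
  }
  phi
}

#' MUSE-style per-direction reconstruction
#'
#' Reconstructs every diffusion volume independently by CG-SENSE over its
#' stacked shots with Tikhonov regularization:
#' `(A_d^H A_d + lambda I) x_d = A_d^H y_d`. No coupling along the
#' diffusion dimension is imposed; shot combination relies entirely on the
#' phase maps carried by `enc`.
#'
#' @param y k-space array or [kspace_data()].
#' @param enc [encoding_operator()] with (self-gated or navigated) phase
#'   maps.
#' @param lambda_l2 Tikhonov weight (>= 0).
#' @param cg_iters CG iterations per volume.
#' @param tol optional CG relative tolerance exit.
#' @return image stack `(Nd, Nz, Ny, Nx)`.
#' @export
muse_reconstruct <- function(y, enc, lambda_l2 = 0.01, cg_iters = 30L,
                             tol = 1e-9) {
  y <- ks_array(y)
  d <- enc_dims(enc)
  x <- array(0i, unname(c(d["Nd"], d["Nz"], d["Ny"], d["Nx"])))
  for (dd in seq_len(d["Nd"])) {
    enc_d <- enc_subset_d(enc, dd)
    y_d <- y[dd, , , , , drop = FALSE]
    x[dd, , , ] <- x_update(y_d, enc_d, rho = 2 * lambda_l2,
                            cg_iters = cg_iters, tol = tol)[1, , , ]
  }
  x
}
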