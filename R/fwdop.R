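# Encoding operator for multi-band multi-shot diffusion EPI.
#
# The forward model maps the complex diffusion-weighted image stack x
# (diffusion d, slice z, y, x) to multi-coil multi-shot k-space:
#
#   A(x) = P * sum_z Theta * F( S * Phi * x )
#
# where Phi are shot-to-shot phase maps, S coil sensitivities, F the
# centered orthonormal 2D FFT over (y, x), Theta the per-slice CAIPI phase
# ramps along ky, and P the binary sampling mask. Complex arrays are
# first-class here; the real/imaginary channel split happens only at the
# denoiser boundary.
#
# Array index order: (diffusion, shot, coil, slice, y, x), subsets thereof:
#   image stack   (Nd, Nz, Ny, Nx)
#   coils         (Nc, Nz, Ny, Nx)
#   shot phases   (Nd, Ns, Nz, Ny, Nx)
#   CAIPI phases  (Nz, Ny)
#   mask          (Nd, Ns, Ny, Nx)
#   k-space       (Nd, Ns, Nc, Ny, Nx)

unit_tol <- 1e-6

as_complex_array <- function(a, rank, what) {
  if (is.null(dim(a)) || length(dim(a)) != rank)
    stop(sprintf("%s must be an array of rank %d", what, rank))
  storage.mode(a) <- "complex"
  if (any(!is.finite(Re(a))) || any(!is.finite(Im(a))))
    stop(sprintf("%s contains non-finite values", what))
  a
}

check_unit_magnitude <- function(a, what) {
  if (max(abs(Mod(a) - 1)) > unit_tol)
    stop(sprintf("%s must have unit magnitude everywhere (tolerance %g)",
                 what, unit_tol))
  invisible(a)
}

#' Bundle the components of the encoding operator
#'
#' Collects coil sensitivities `S`, shot-to-shot phase maps `Phi`, multi-band
#' CAIPI phases `Theta` and the sampling mask `P` into a validated
#' `encoding_operator` object used by [apply_forward()], [apply_adjoint()]
#' and all solvers.
#'
#' @param coils complex array `(Nc, Nz, Ny, Nx)`; sum-of-squares over coils
#'   should be 1 inside the object support.
#' @param phases complex array `(Nd, Ns, Nz, Ny, Nx)` of unit magnitude.
#' @param mb complex array `(Nz, Ny)` of unit magnitude; slice `z = 1` (the
#'   reference slice) must carry zero phase.
#' @param mask numeric 0/1 array `(Nd, Ns, Ny, Nx)`; every `(d, s)` plane
#'   must contain at least one sampled location.
#' @return an object of class `encoding_operator`.
#' @export
encoding_operator <- function(coils, phases, mb, mask) {
  coils <- as_complex_array(coils, 4L, "coils")
  phases <- as_complex_array(phases, 5L, "shot phases")
  mb <- as_complex_array(mb, 2L, "multi-band phases")
  dm <- dim(mask)
  if (is.null(dm) || length(dm) != 4L) stop("mask must be an array of rank 4")
  storage.mode(mask) <- "double"
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0 or 1")
  dc <- dim(coils); dp <- dim(phases); db <- dim(mb)
  if (!identical(dc[2:4], dp[3:5]))
    stop("coil and shot-phase dimensions inconsistent")
  if (db[1] != dc[2] || db[2] != dc[3])
    stop("multi-band phase dimensions inconsistent with coils")
  if (dm[1] != dp[1] || dm[2] != dp[2] || dm[3] != dc[3] || dm[4] != dc[4])
    stop("mask dimensions inconsistent with phases/coils")
  check_unit_magnitude(phases, "shot phases")
  check_unit_magnitude(mb, "multi-band phases")
  if (max(Mod(mb[1, ] - 1)) > unit_tol)
    stop("multi-band phases: reference slice must have zero phase")
  planes <- apply(mask, c(1, 2), sum)
  if (any(planes < 1)) stop("every (diffusion, shot) mask plane needs >= 1 sample")
  structure(list(coils = coils, phases = phases, mb = mb, mask = mask),
            class = "encoding_operator")
}

#' @export
print.encoding_operator <- function(x, ...) {
  d <- enc_dims(x)
  cat(sprintf(
    "<encoding_operator> Nd=%d shots=%d coils=%d slices=%d matrix=%dx%d, %d sampled points\n",
    d["Nd"], d["Ns"], d["Nc"], d["Nz"], d["Ny"], d["Nx"], sum(x$mask)))
  invisible(x)
}

enc_dims <- function(enc) {
  dc <- dim(enc$coils); dp <- dim(enc$phases)
  c(Nd = dp[1], Ns = dp[2], Nc = dc[1], Nz = dc[2], Ny = dc[3], Nx = dc[4])
}

#' Measured k-space container
#'
#' @param data complex array `(Nd, Ns, Nc, Ny, Nx)`; must be zero wherever
#'   the mask is zero.
#' @param mask numeric 0/1 array `(Nd, Ns, Ny, Nx)`.
#' @param noise_sd per-sample complex noise standard deviation, if known
#'   (synthetic data); `NA` otherwise.
#' @return object of class `kspace_data`.
#' @export
kspace_data <- function(data, mask, noise_sd = NA_real_) {
  data <- as_complex_array(data, 5L, "k-space data")
  dm <- dim(mask); dd <- dim(data)
  if (!identical(as.integer(dm), as.integer(dd[c(1, 2, 4, 5)])))
    stop("mask dimensions inconsistent with k-space data")
  m5 <- aperm(array(rep(mask, dd[3]), c(dm[1], dm[2], dm[3], dm[4], dd[3])),
              c(1, 2, 5, 3, 4))
  off <- data[m5 == 0]
  if (length(off) && max(Mod(off)) > 0)
    stop("k-space data must be zero outside the sampling mask")
  structure(list(data = data, mask = mask, noise_sd = noise_sd),
            class = "kspace_data")
}

check_image_stack <- function(x, enc) {
  d <- enc_dims(enc)
  x <- as_complex_array(x, 4L, "image stack")
  if (!identical(as.integer(dim(x)),
                 as.integer(c(d["Nd"], d["Nz"], d["Ny"], d["Nx"]))))
    stop("image stack dimensions inconsistent with encoding operator")
  x
}

ks_array <- function(y) if (inherits(y, "kspace_data")) y$data else y

#' Apply the forward encoding operator
#'
#' Computes `A(x) = P * sum_z Theta * F(S * Phi * x)` for every
#' (diffusion, shot, coil), using the centered orthonormal 2D FFT.
#'
#' @param x complex image stack `(Nd, Nz, Ny, Nx)`.
#' @param enc an [encoding_operator()].
#' @return complex k-space array `(Nd, Ns, Nc, Ny, Nx)`, zero outside the
#'   sampling mask.
#' @export
apply_forward <- function(x, enc) {
  stopifnot(inherits(enc, "encoding_operator"))
  x <- check_image_stack(x, enc)
  cpp_forward(x, enc$coils, enc$phases, enc$mb, enc$mask)
}

#' Apply the adjoint of the encoding operator
#'
#' Exact adjoint of [apply_forward()]: masked k-space is modulated by
#' `conj(Theta)`, inverse transformed per slice, coil-combined with
#' `conj(S)` and shot-combined with `conj(Phi)`.
#'
#' @param y complex k-space array `(Nd, Ns, Nc, Ny, Nx)` or a
#'   [kspace_data()] object.
#' @inheritParams apply_forward
#' @return complex image stack `(Nd, Nz, Ny, Nx)`.
#' @export
apply_adjoint <- function(y, enc) {
  stopifnot(inherits(enc, "encoding_operator"))
  y <- as_complex_array(ks_array(y), 5L, "k-space data")
  d <- enc_dims(enc)
  if (!identical(as.integer(dim(y)),
                 as.integer(c(d["Nd"], d["Ns"], d["Nc"], d["Ny"], d["Nx"]))))
    stop("k-space dimensions inconsistent with encoding operator")
  cpp_adjoint(y, enc$coils, enc$phases, enc$mb, enc$mask)
}

#' Normal operator of the encoding model
#'
#' Returns `A^H A x + (rho/2) x`, the self-adjoint positive semidefinite
#' operator inverted by the data-consistency (x-update) step of ADMM.
#'
#' @inheritParams apply_forward
#' @param rho non-negative ADMM penalty parameter.
#' @return complex image stack of the same shape as `x`.
#' @export
normal_op <- function(x, enc, rho = 0) {
  stopifnot(inherits(enc, "encoding_operator"))
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0)
    stop("rho must be a single non-negative number")
  x <- check_image_stack(x, enc)
  cpp_normal(x, enc$coils, enc$phases, enc$mb, enc$mask, rho)
}

# Replace the sampling mask (data-consistency mask swap used by the
# self-supervised training loop). Skips the full re-validation.
enc_with_mask <- function(enc, mask) {
  storage.mode(mask) <- "double"
  stopifnot(identical(dim(mask), dim(enc$mask)))
  enc$mask <- mask
  enc
}

# Restrict an encoding operator and k-space data to one diffusion index
# (keeps the singleton diffusion dimension).
enc_subset_d <- function(enc, d) {
  encoding_operator(
    coils = enc$coils,
    phases = enc$phases[d, , , , , drop = FALSE],
    mb = enc$mb,
    mask = enc$mask[d, , , , drop = FALSE])
}
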