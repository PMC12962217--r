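# Image-quality metrics and a minimal diffusion tensor fit for downstream
# evaluation. Metrics operate on magnitude images with the reference
# fixed: PSNR/NRMSE over the reference support, SSIM with the standard
# constants over the valid (fully windowed) region.

metric_check <- function(x, ref) {
  if (!identical(dim(x), dim(ref))) stop("shape mismatch between x and ref")
  # complex reconstructions are compared as magnitude images; real inputs
  # are assumed to be magnitudes already and pass through unchanged
  list(x = if (is.complex(x)) Mod(x) else x,
       ref = if (is.complex(ref)) Mod(ref) else ref)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `PSNR = 20 log10(max|ref| / RMSE)` computed on magnitude images over
#' the reference support (voxels where `|ref| > 0`), the reference held
#' fixed. A perfect match returns the capped sentinel value.
#'
#' @param x,ref arrays of identical shape (complex allowed; magnitudes are
#'   compared).
#' @param cap value reported when the RMSE is exactly 0 (default 300 dB).
#' @return scalar dB value.
#' @export
psnr <- function(x, ref, cap = 300) {
  m <- metric_check(x, ref)
  sup <- m$ref > 0
  if (!any(sup)) stop("reference support is empty")
  rmse <- sqrt(mean((m$x[sup] - m$ref[sup])^2))
  if (rmse == 0) return(cap)
  min(20 * log10(max(m$ref) / rmse), cap)
}

#' Normalized root-mean-square error
#'
#' `||x - ref|| / ||ref||` on magnitude images over the reference support.
#'
#' @inheritParams psnr
#' @return scalar.
#' @export
nrmse <- function(x, ref) {
  m <- metric_check(x, ref)
  sup <- m$ref > 0
  sqrt(sum((m$x[sup] - m$ref[sup])^2) / sum(m$ref[sup]^2))
}

gauss_kernel <- function(size = 11L, sigma = 1.5) {
  r <- (seq_len(size) - (size + 1) / 2)
  k <- exp(-r^2 / (2 * sigma^2))
  k2 <- outer(k, k)
  k2 / sum(k2)
}

conv2_valid <- function(a, k) {
  # 2D correlation, valid region (a filtered by kernel k)
  na <- dim(a); nk <- dim(k)
  A <- array(a, c(na[1], na[2], 1, 1))
  K <- array(k, c(nk[1], nk[2], 1, 1))
  full <- cpp_conv2d(A, K, 0)[, , 1, 1]
  h <- (nk[1] - 1) / 2
  full[(h + 1):(na[1] - h), (h + 1):(na[2] - h), drop = FALSE]
}

#' Structural similarity index (mean SSIM)
#'
#' SSIM with the standard constants `K1 = 0.01`, `K2 = 0.03`, an 11-pixel
#' Gaussian window (sigma 1.5) and dynamic range `max|ref|`, averaged over
#' the valid (fully windowed) region of each 2D plane; multi-dimensional
#' inputs are averaged over their trailing planes. Magnitude images are
#' compared with the reference fixed; the value lies in \[-1, 1\].
#'
#' @inheritParams psnr
#' @return scalar mean SSIM.
#' @export
ssim <- function(x, ref) {
  m <- metric_check(x, ref)
  L <- max(m$ref)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  w <- gauss_kernel()
  d <- dim(m$x)
  if (is.null(d)) stop("ssim needs at least a 2D image")
  # planes: treat the LAST two dims as (y, x) if input is a stack
  # (Nd, Nz, Ny, Nx); plain matrices are a single plane.
  per_plane <- function(a, b) {
    mu_x <- conv2_valid(a, w); mu_y <- conv2_valid(b, w)
    sxx <- conv2_valid(a * a, w) - mu_x^2
    syy <- conv2_valid(b * b, w) - mu_y^2
    sxy <- conv2_valid(a * b, w) - mu_x * mu_y
    s <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
      ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
    mean(s)
  }
  if (length(d) == 2) return(per_plane(m$x, m$ref))
  np <- prod(d[-c(length(d) - 1, length(d))])
  xm <- array(aperm(array(m$x, d), c(length(d) - 1, length(d),
                                     seq_len(length(d) - 2))),
              c(d[length(d) - 1], d[length(d)], np))
  rm_ <- array(aperm(array(m$ref, d), c(length(d) - 1, length(d),
                                        seq_len(length(d) - 2))),
               c(d[length(d) - 1], d[length(d)], np))
  mean(vapply(seq_len(np), function(i) per_plane(xm[, , i], rm_[, , i]),
              numeric(1)))
}

#' Fit the diffusion tensor model voxel-wise
#'
#' Unweighted log-linear least squares of
#' `log S = log S0 - b g' D g` per voxel; requires at least six
#' non-collinear directions plus a b = 0 volume. Non-positive signals are
#' clamped to `1e-6 * S0`. Returns per-voxel `S0`, tensor components,
#' sorted eigenvalues, fractional anisotropy, principal eigenvector, and
#' the colored-FA RGB map `FA * |e1|`.
#'
#' @param dwis magnitude image stack `(Nd, Nz, Ny, Nx)`.
#' @param bvals b-values (s/mm^2), length Nd.
#' @param bvecs 3 x Nd unit direction matrix.
#' @param mask optional logical `(Nz, Ny, Nx)` voxel mask (default: b0
#'   signal > 0).
#' @return object of class `tensor_map`: list with `S0` `(Nz,Ny,Nx)`,
#'   `D6` `(6,Nz,Ny,Nx)` (xx, yy, zz, xy, xz, yz), `evals` `(3,Nz,Ny,Nx)`,
#'   `fa` `(Nz,Ny,Nx)`, `e1` `(3,Nz,Ny,Nx)`, `cfa` `(3,Nz,Ny,Nx)`.
#' @export
fit_dti <- function(dwis, bvals, bvecs, mask = NULL) {
  dwis <- Mod(dwis)
  d <- dim(dwis)
  stopifnot(length(d) == 4, length(bvals) == d[1], ncol(bvecs) == d[1])
  if (sum(bvals == 0) < 1) stop("need at least one b = 0 volume")
  if (sum(bvals > 0) < 6) stop("need at least six diffusion-weighted volumes")
  X <- cbind(1, -bvals * t(rbind(bvecs[1, ]^2, bvecs[2, ]^2, bvecs[3, ]^2,
                                 2 * bvecs[1, ] * bvecs[2, ],
                                 2 * bvecs[1, ] * bvecs[3, ],
                                 2 * bvecs[2, ] * bvecs[3, ])))
  qx <- qr(X)
  if (qx$rank < 7)
    stop(paste("singular design matrix: directions",
               paste(which(bvals > 0), collapse = ", "),
               "do not span six independent tensor components"))
  Nz <- d[2]; Ny <- d[3]; Nx <- d[4]
  nvox <- Nz * Ny * Nx
  sig <- matrix(dwis, d[1], nvox)  # volumes x voxels
  s0 <- colMeans(sig[bvals == 0, , drop = FALSE])
  if (is.null(mask)) mask <- array(s0 > 0, c(Nz, Ny, Nx))
  keep <- which(as.logical(mask) & s0 > 0)
  S0 <- numeric(nvox)
  D6 <- matrix(0, 6, nvox)
  evals <- matrix(0, 3, nvox)
  fa <- numeric(nvox)
  e1 <- matrix(0, 3, nvox)
  if (length(keep)) {
    s <- sig[, keep, drop = FALSE]
    floor_ <- rep(1e-6 * s0[keep], each = d[1])
    s <- pmax(s, floor_)
    beta <- qr.coef(qx, log(s))  # 7 x nkeep
    S0[keep] <- exp(beta[1, ])
    D6[, keep] <- beta[2:7, , drop = FALSE]
    for (j in seq_along(keep)) {
      i <- keep[j]
      b6 <- beta[2:7, j]
      Dm <- matrix(c(b6[1], b6[4], b6[5],
                     b6[4], b6[2], b6[6],
                     b6[5], b6[6], b6[3]), 3, 3)
      ev <- eigen(Dm, symmetric = TRUE)
      lam <- ev$values  # decreasing
      evals[, i] <- lam
      lbar <- mean(lam)
      den <- sum(lam^2)
      fa[i] <- if (den > 0) sqrt(3 / 2) * sqrt(sum((lam - lbar)^2) / den) else 0
      e1[, i] <- ev$vectors[, 1]
    }
  }
  fa <- pmin(pmax(fa, 0), 1)
  cfa <- abs(e1) * rep(fa, each = 3)
  dim(S0) <- c(Nz, Ny, Nx)
  dim(D6) <- c(6, Nz, Ny, Nx)
  dim(evals) <- c(3, Nz, Ny, Nx)
  dim(fa) <- c(Nz, Ny, Nx)
  dim(e1) <- c(3, Nz, Ny, Nx)
  dim(cfa) <- c(3, Nz, Ny, Nx)
  structure(list(S0 = S0, D6 = D6, evals = evals, fa = fa, e1 = e1,
                 cfa = cfa, bvals = bvals, bvecs = bvecs),
            class = "tensor_map")
}

#' @export
print.tensor_map <- function(x, ...) {
  d <- dim(x$fa)
  cat(sprintf("<tensor_map> %d x %d x %d voxels; FA range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$fa), max(x$fa)))
  invisible(x)
}
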