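# Residual convolutional denoiser used as the learned regularizer in the
# unrolled ADMM. The complex diffusion stack (Nd, Nz, Ny, Nx) is split
# into real/imaginary channels and reshaped to (Ny, Nx, 2*Nd, Nz): the
# multi-band slices ride along the batch axis and the 3x3 kernels mix the
# diffusion contrasts. Forward and reverse-mode passes are written out
# explicitly (conv kernels compiled, ReLU and bookkeeping in R).

#' Initialize denoiser parameters
#'
#' A residual network: input conv + ReLU, `n_blocks` residual blocks
#' (conv-ReLU-conv with skip), and a zero-initialized output conv so the
#' network starts as the identity (when the global residual connection is
#' on) or as the zero map (when it is off).
#'
#' @param n_diff number of diffusion volumes (input/output channel count is
#'   `2 * n_diff`).
#' @param channels feature channels (default 64).
#' @param n_blocks residual blocks (default 3).
#' @param seed weight-initialization seed.
#' @param global_residual include the global skip connection (default
#'   `TRUE`); with zero weights the network is then the identity map.
#' @return a `denoiser_params` list.
#' @export
denoiser_init <- function(n_diff, channels = 64L, n_blocks = 3L, seed = 1L,
                          global_residual = TRUE) {
  cin <- 2L * as.integer(n_diff)
  he <- function(k, ci, co) {
    array(rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))), c(k, k, ci, co))
  }
  params <- with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(i) {
      list(w1 = he(3, channels, channels), b1 = numeric(channels),
           w2 = he(3, channels, channels), b2 = numeric(channels))
    })
    list(w_in = he(3, cin, channels), b_in = numeric(channels),
         blocks = blocks,
         w_out = array(0, c(3, 3, channels, cin)), b_out = numeric(cin))
  })
  params$n_diff <- as.integer(n_diff)
  params$channels <- as.integer(channels)
  params$n_blocks <- as.integer(n_blocks)
  params$global_residual <- isTRUE(global_residual)
  class(params) <- "denoiser_params"
  params
}

# zero-weight copy (e.g. for the reduction oracle: global_residual = FALSE
# and zero weights give the zero map)
denoiser_zero <- function(n_diff, channels = 8L, n_blocks = 1L,
                          global_residual = FALSE) {
  p <- denoiser_init(n_diff, channels, n_blocks, seed = 1L,
                     global_residual = global_residual)
  denoiser_map(function(a) a * 0, p)
}

# apply f to every numeric parameter array (optionally zipping extra
# parameter structures), preserving structure
denoiser_map <- function(f, p, ...) {
  extra <- list(...)
  fields <- c("w_in", "b_in", "w_out", "b_out")
  for (nm in fields)
    p[[nm]] <- do.call(f, c(list(p[[nm]]), lapply(extra, `[[`, nm)))
  for (i in seq_along(p$blocks))
    for (nm in c("w1", "b1", "w2", "b2"))
      p$blocks[[i]][[nm]] <- do.call(
        f, c(list(p$blocks[[i]][[nm]]),
             lapply(extra, function(e) e$blocks[[i]][[nm]])))
  p
}

# complex (Nd, Nz, Ny, Nx) -> real channels (Ny, Nx, 2 Nd, Nz)
stack_to_channels <- function(x) {
  d <- dim(x)
  a <- array(0, c(2 * d[1], d[2], d[3], d[4]))
  a[seq(1, 2 * d[1], 2), , , ] <- Re(x)
  a[seq(2, 2 * d[1], 2), , , ] <- Im(x)
  aperm(a, c(3, 4, 1, 2))
}

channels_to_stack <- function(X) {
  d <- dim(X)  # (Ny, Nx, 2 Nd, Nz)
  a <- aperm(X, c(3, 4, 1, 2))
  re <- a[seq(1, d[3], 2), , , , drop = FALSE]
  im <- a[seq(2, d[3], 2), , , , drop = FALSE]
  out <- re + 1i * im
  dim(out) <- c(d[3] / 2, d[4], d[1], d[2])
  out
}

relu <- function(a) {
  a[a < 0] <- 0
  a
}

# forward pass on channel layout; returns list(out, cache) when caching
denoiser_forward_ch <- function(params, X, cache = FALSE) {
  a0 <- cpp_conv2d(X, params$w_in, params$b_in)
  h <- relu(a0)
  ca <- if (cache) list(X = X, a0 = a0, blocks = vector("list", params$n_blocks))
  for (i in seq_along(params$blocks)) {
    bl <- params$blocks[[i]]
    a1 <- cpp_conv2d(h, bl$w1, bl$b1)
    r1 <- relu(a1)
    a2 <- cpp_conv2d(r1, bl$w2, bl$b2)
    if (cache) ca$blocks[[i]] <- list(h_in = h, a1 = a1, r1 = r1)
    h <- h + a2
  }
  if (cache) ca$h_last <- h
  out <- cpp_conv2d(h, params$w_out, params$b_out)
  if (params$global_residual) out <- out + X
  if (cache) list(out = out, cache = ca) else out
}

# reverse-mode pass; dOut in channel layout; returns list(dparams, dX)
denoiser_backward_ch <- function(params, ca, dOut) {
  dX <- if (params$global_residual) dOut else dOut * 0
  gp <- cpp_conv2d_bwd_params(dOut, ca$h_last, 3L)
  dparams <- list(w_out = gp$dw, b_out = gp$db, blocks = vector("list", params$n_blocks))
  dh <- cpp_conv2d_bwd_input(dOut, params$w_out)
  for (i in rev(seq_along(params$blocks))) {
    bl <- params$blocks[[i]]
    cb <- ca$blocks[[i]]
    da2 <- dh
    g2 <- cpp_conv2d_bwd_params(da2, cb$r1, 3L)
    dr1 <- cpp_conv2d_bwd_input(da2, bl$w2)
    da1 <- dr1 * (cb$a1 > 0)
    g1 <- cpp_conv2d_bwd_params(da1, cb$h_in, 3L)
    dparams$blocks[[i]] <- list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db)
    dh <- dh + cpp_conv2d_bwd_input(da1, bl$w1)
  }
  da0 <- dh * (ca$a0 > 0)
  g0 <- cpp_conv2d_bwd_params(da0, ca$X, 3L)
  dparams$w_in <- g0$dw
  dparams$b_in <- g0$db
  dX <- dX + cpp_conv2d_bwd_input(da0, params$w_in)
  list(dparams = dparams, dX = dX)
}

#' Apply the denoiser to a complex image stack
#'
#' Splits the stack into real/imaginary channels, runs the residual
#' convolutional network with the multi-band slices along the batch axis,
#' and recombines to a complex stack of identical shape.
#'
#' @param x complex image stack `(Nd, Nz, Ny, Nx)`.
#' @param params [denoiser_init()] parameters with `n_diff == Nd`.
#' @return complex image stack, same shape.
#' @export
denoise <- function(x, params) {
  stopifnot(inherits(params, "denoiser_params"))
  d <- dim(x)
  if (is.null(d) || length(d) != 4 || d[1] != params$n_diff)
    stop("image stack shape inconsistent with denoiser parameters")
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
    stop("denoise: non-finite input")
  X <- stack_to_channels(x)
  out <- denoiser_forward_ch(params, X)
  if (any(!is.finite(out))) stop("denoise: non-finite activations")
  channels_to_stack(out)
}
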