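# Scan-specific self-supervised ADMM unrolling.
#
# The acquired sampling mask P is split (12 repetitions) into disjoint
# sets T / L / V. Per repetition the unrolled ADMM reconstructs with data
# consistency restricted to T, the training loss compares predicted and
# measured k-space on L, and validation (data consistency on T union L)
# is scored on V. Training stops when the validation loss has not
# improved for `patience` consecutive epochs or at the epoch cap.
#
# The unrolled iteration (depth n_unroll, CG depth cg_iters) is
#   x_{k+1} = argmin_x ||y - A x||^2 + (rho/2) ||x - v_k + u_k||^2  (CG)
#   v_{k+1} = (lambda/rho) * D_w(x_{k+1} + u_k)
#   u_{k+1} = u_k + x_{k+1} - v_{k+1}
# with D_w the residual conv denoiser; lambda is a trainable positive
# scalar (softplus parametrization), rho is fixed. Gradients are
# hand-derived reverse mode; the CG block is differentiated by the
# implicit rule (a CG solve on the same normal operator).

#' Control parameters for self-supervised unrolled training
#'
#' Defaults follow the reference algorithm: 8 unrolls, 6 CG iterations,
#' `rho = 0.05`, `lambda` initialized at 0.05, 12 mask-split repetitions,
#' at most 100 epochs with patience 12.
#'
#' @param n_unroll unrolled ADMM iterations.
#' @param cg_iters CG iterations inside each data-consistency update.
#' @param rho fixed ADMM penalty.
#' @param lambda_init initial value of the trainable regularization
#'   strength.
#' @param n_epoch_max epoch cap.
#' @param patience consecutive non-improving validation epochs tolerated.
#' @param n_repetitions number of independent T/L/V splits.
#' @param split_ratios length-3 positive weights for T, L, V (sum 1); more
#'   data goes to the training mask than to the loss masks.
#' @param lr ADAM step size.
#' @param denoiser_channels,denoiser_blocks architecture of the residual
#'   network.
#' @param conventional_v if `TRUE`, use the plain plug-and-play update
#'   `v = D_w(x + u)` instead of the `(lambda/rho)`-scaled one (ablation).
#' @param clip_grad global gradient-norm clipping threshold applied to the
#'   combined (weights, lambda) gradient before the ADAM step; `Inf`
#'   disables clipping. Unrolled k-space losses occasionally produce
#'   exploding gradients on poorly conditioned mask splits; clipping keeps
#'   the trainable lambda alive through such steps.
#' @param precision `"single"` (default) runs the data-consistency CG in
#'   single precision (about half the memory traffic; relative differences
#'   around 1e-6, far below the measurement noise); `"double"` for
#'   oracle-grade comparisons.
#' @param seed master seed (separate streams are derived for the mask
#'   split and the weight initialization).
#' @return an `unroll_control` list.
#' @export
unroll_control <- function(n_unroll = 8L, cg_iters = 6L, rho = 0.05,
                           lambda_init = 0.05, n_epoch_max = 100L,
                           patience = 12L, n_repetitions = 12L,
                           split_ratios = c(0.6, 0.2, 0.2), lr = 1e-3,
                           denoiser_channels = 64L, denoiser_blocks = 3L,
                           conventional_v = FALSE, clip_grad = 100,
                           precision = c("single", "double"), seed = 1L) {
  stopifnot(all(split_ratios > 0), patience >= 1, n_unroll >= 1,
            cg_iters >= 1, rho > 0, lambda_init > 0)
  if (abs(sum(split_ratios) - 1) > 1e-8)
    stop("split_ratios must sum to 1")
  structure(list(
    n_unroll = as.integer(n_unroll), cg_iters = as.integer(cg_iters),
    rho = rho, lambda_init = lambda_init,
    n_epoch_max = as.integer(n_epoch_max), patience = as.integer(patience),
    n_repetitions = as.integer(n_repetitions), split_ratios = split_ratios,
    lr = lr, denoiser_channels = as.integer(denoiser_channels),
    denoiser_blocks = as.integer(denoiser_blocks),
    conventional_v = isTRUE(conventional_v), clip_grad = clip_grad,
    precision = match.arg(precision), seed = as.integer(seed)),
    class = "unroll_control")
}

#' Split the sampling mask into disjoint T/L/V sets
#'
#' For every repetition, the acquired locations of each (diffusion, shot)
#' plane are partitioned uniformly at random (seeded permutation) into the
#' data-consistency set T, the training-loss set L and the validation set
#' V at the configured ratios. The three sets are pairwise disjoint and
#' their union is exactly the acquired set; repetitions use different
#' permutations.
#'
#' @param mask 0/1 sampling mask `(Nd, Ns, Ny, Nx)`.
#' @param ratios length-3 positive weights summing to 1.
#' @param n_repetitions number of splits (default 12).
#' @param seed integer seed.
#' @return list of length `n_repetitions`; each element has 0/1 arrays
#'   `T`, `L`, `V` shaped like `mask`.
#' @export
split_mask <- function(mask, ratios = c(0.6, 0.2, 0.2), n_repetitions = 12L,
                       seed = 1L) {
  d <- dim(mask)
  stopifnot(length(d) == 4, length(ratios) == 3, all(ratios > 0))
  with_seed(seed, {
    lapply(seq_len(n_repetitions), function(rep) {
      Tm <- array(0, d); Lm <- array(0, d); Vm <- array(0, d)
      for (dd in seq_len(d[1])) for (s in seq_len(d[2])) {
        idx <- which(mask[dd, s, , ] != 0)
        n <- length(idx)
        if (n < 3)
          stop(sprintf("plane (d=%d, s=%d) has %d < 3 samples", dd, s, n))
        nt <- max(1L, round(ratios[1] * n))
        nl <- max(1L, round(ratios[2] * n))
        if (nt + nl >= n) {
          nt <- max(1L, n - 2L)
          nl <- 1L
        }
        perm <- sample(idx)
        tp <- array(0, c(d[3], d[4])); lp <- tp; vp <- tp
        tp[perm[seq_len(nt)]] <- 1
        lp[perm[nt + seq_len(nl)]] <- 1
        vp[perm[(nt + nl + 1):n]] <- 1
        Tm[dd, s, , ] <- tp; Lm[dd, s, , ] <- lp; Vm[dd, s, , ] <- vp
      }
      list(T = Tm, L = Lm, V = Vm)
    })
  })
}

# mask y (Nd,Ns,Nc,Ny,Nx) by a (Nd,Ns,Ny,Nx) mask, broadcasting over coils
mask_kspace <- function(y, mask) {
  dm <- dim(mask)
  nc <- dim(y)[3]
  m5 <- aperm(array(rep(mask, nc), c(dm, nc)), c(1, 2, 5, 3, 4))
  y * m5
}

# normalized masked k-space loss ||M(Ax - y)||^2 / ||M y||^2 and its
# gradient w.r.t. x (convention dRe + i dIm)
kspace_loss <- function(x, y, enc_loss, grad = FALSE, single = FALSE) {
  y_m <- mask_kspace(y, enc_loss$mask)
  denom <- sum(Mod(y_m)^2)
  fwd <- if (single) {
    cpp_forward_single(x, enc_loss$coils, enc_loss$phases, enc_loss$mb,
                       enc_loss$mask)
  } else {
    apply_forward(x, enc_loss)
  }
  r <- fwd - y_m
  loss <- sum(Mod(r)^2) / denom
  if (!grad) return(loss)
  gx <- if (single) {
    (2 / denom) * cpp_adjoint_single(r, enc_loss$coils, enc_loss$phases,
                                     enc_loss$mb, enc_loss$mask)
  } else {
    (2 / denom) * apply_adjoint(r, enc_loss)
  }
  list(loss = loss, gx = gx)
}

#' Unrolled ADMM reconstruction (fixed parameters)
#'
#' Runs `n_unroll` ADMM iterations with data consistency restricted to the
#' mask carried by `enc` (T while training, T union L for validation, the
#' full acquired mask at inference): `x0 = A^H y`, CG x-update, denoiser
#' v-update scaled by `lambda/rho`, dual ascent. Deterministic given
#' parameters.
#'
#' @param y k-space array or [kspace_data()] (full measured data; the
#'   operator's mask selects what is used).
#' @param enc [encoding_operator()] whose mask is the data-consistency
#'   mask.
#' @param params [denoiser_init()] parameters.
#' @param lambda regularization strength (> 0).
#' @param control an [unroll_control()].
#' @param cache keep intermediates for reverse mode (internal).
#' @return image stack `(Nd, Nz, Ny, Nx)` (plus caches when `cache =
#'   TRUE`).
#' @export
admm_unrolled <- function(y, enc, params, lambda, control = unroll_control(),
                          cache = FALSE) {
  y <- ks_array(y)
  rho <- control$rho
  scale <- if (control$conventional_v) 1 else lambda / rho
  single <- identical(control$precision, "single")
  x0 <- if (single) {
    cpp_adjoint_single(y, enc$coils, enc$phases, enc$mb, enc$mask)
  } else {
    apply_adjoint(y, enc)
  }
  v <- x0
  u <- zeros_like(x0)
  caches <- if (cache) vector("list", control$n_unroll)
  x <- x0
  for (k in seq_len(control$n_unroll)) {
    b <- x0 + (rho / 2) * (v - u)
    x <- cg_normal(b, enc, rho, control$cg_iters, single = single)
    z <- x + u
    Z <- stack_to_channels(z)
    fw <- denoiser_forward_ch(params, Z, cache = cache)
    out_ch <- if (cache) fw$out else fw
    Dz <- channels_to_stack(out_ch)
    v <- scale * Dz
    u <- u + x - v
    if (cache) caches[[k]] <- list(den = if (cache) fw$cache, Dz = Dz)
  }
  if (cache) list(x = x, caches = caches) else x
}

# reverse-mode pass through the unrolled iteration; gx_out is dLoss/dx_K.
# Returns accumulated denoiser parameter gradients and dLoss/dlambda.
unroll_backward <- function(gx_out, caches, enc, params, lambda, control) {
  rho <- control$rho
  scale <- if (control$conventional_v) 1 else lambda / rho
  gx <- gx_out
  gv <- zeros_like(gx_out)
  gu <- zeros_like(gx_out)
  glambda <- 0
  gparams <- NULL
  for (k in rev(seq_len(control$n_unroll))) {
    ck <- caches[[k]]
    # u_k = u_{k-1} + x_k - v_k
    gx <- gx + gu
    gv <- gv - gu
    gu_prev <- gu
    # v_k = scale * D(z_k)
    if (!control$conventional_v)
      glambda <- glambda + (1 / rho) *
        sum(Re(ck$Dz) * Re(gv) + Im(ck$Dz) * Im(gv))
    dOut <- stack_to_channels(gv) * scale
    bw <- denoiser_backward_ch(params, ck$den, dOut)
    gparams <- if (is.null(gparams)) bw$dparams else
      denoiser_map(function(a, b) a + b, gparams, bw$dparams)
    gz <- channels_to_stack(bw$dX)
    gx <- gx + gz
    gu_prev <- gu_prev + gz
    # x_k = CG((A^H A + rho/2), b_k): implicit adjoint via CG
    gb <- cg_normal(gx, enc, rho, control$cg_iters,
                    single = identical(control$precision, "single"))
    gv <- (rho / 2) * gb
    gu <- gu_prev - (rho / 2) * gb
    gx <- zeros_like(gx_out)
  }
  list(gparams = gparams, glambda = glambda)
}

# --- training state ------------------------------------------------------

new_train_state <- function() {
  list(epoch = 0L, best_valid = Inf, trace = 0L,
       train_loss = numeric(0), valid_loss = numeric(0),
       lambda_trace = numeric(0), best_epoch = 0L,
       valid_epoch0 = NA_real_)
}

#' Update the early-stopping state with a validation loss
#'
#' Mirrors the training bookkeeping: a loss not exceeding the best so far
#' resets the non-improvement counter (`trace`) and records the epoch;
#' otherwise the counter increments. Training stops once `trace` reaches
#' the patience or the epoch cap is hit.
#'
#' @param state list with fields `epoch`, `best_valid`, `trace`,
#'   `best_epoch` (see [unroll_train()]).
#' @param valid_loss validation loss of the epoch just finished.
#' @return updated state with `improved` attribute.
#' @export
update_train_state <- function(state, valid_loss) {
  state$epoch <- state$epoch + 1L
  improved <- valid_loss <= state$best_valid
  if (improved) {
    state$best_valid <- valid_loss
    state$best_epoch <- state$epoch
    state$trace <- 0L
  } else {
    state$trace <- state$trace + 1L
  }
  state$valid_loss <- c(state$valid_loss, valid_loss)
  attr(state, "improved") <- improved
  state
}

train_should_stop <- function(state, control) {
  state$trace >= control$patience || state$epoch >= control$n_epoch_max
}

softplus <- function(t) ifelse(t > 30, t, log1p(exp(t)))
softplus_inv <- function(l) ifelse(l > 30, l, log(expm1(l)))
sigmoid <- function(t) 1 / (1 + exp(-t))

adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  st$p <- p - lr * mh / (sqrt(vh) + eps)
  st
}

#' Train a scan-specific self-supervised unrolled ADMM model
#'
#' Fits the denoiser weights and the regularization strength `lambda` to a
#' single multi-band slice dataset by k-space mask splitting: each epoch
#' loops the repetitions, reconstructing with data consistency on T,
#' taking one ADAM step on the normalized masked k-space loss evaluated on
#' L, then scores a validation pass (data consistency on T union L,
#' loss on V, averaged over repetitions) for early stopping. The returned
#' parameters are those of the best validation epoch.
#'
#' @param y k-space array or [kspace_data()] of one multi-band slice.
#' @param enc [encoding_operator()] with the full acquired mask.
#' @param control an [unroll_control()].
#' @param verbose print per-epoch losses.
#' @return an object of class `unroll_fit` with elements `params` (best
#'   denoiser weights), `lambda`, `train_state` (loss histories, best
#'   epoch, stopping counter), `control`, `enc`, `y`, and the best-epoch
#'   validation reconstruction of the first repetition.
#' @export
unroll_train <- function(y, enc, control = unroll_control(),
                         verbose = FALSE) {
  y <- ks_array(y)
  nd <- enc_dims(enc)[["Nd"]]
  splits <- split_mask(enc$mask, control$split_ratios,
                       control$n_repetitions,
                       seed = derive_seed(control$seed, "split"))
  params <- denoiser_init(nd, control$denoiser_channels,
                          control$denoiser_blocks,
                          seed = derive_seed(control$seed, "weights"))
  theta <- softplus_inv(control$lambda_init)
  # per-repetition operators
  reps <- lapply(splits, function(sp) {
    list(enc_T = enc_with_mask(enc, sp$T),
         enc_L = enc_with_mask(enc, sp$L),
         enc_TL = enc_with_mask(enc, sp$T + sp$L),
         enc_V = enc_with_mask(enc, sp$V))
  })
  zero_params <- denoiser_map(function(a) a * 0, params)
  ad_w <- list(m = zero_params, v = zero_params)
  ad_l <- list(m = 0, v = 0)
  t_step <- 0L
  state <- new_train_state()
  validate <- function(params, lambda) {
    valid <- numeric(control$n_repetitions)
    recon1 <- NULL
    for (r in seq_len(control$n_repetitions)) {
      xv <- admm_unrolled(y, reps[[r]]$enc_TL, params, lambda, control)
      valid[r] <- kspace_loss(xv, y, reps[[r]]$enc_V,
                              single = identical(control$precision, "single"))
      if (r == 1L) recon1 <- xv
    }
    list(loss = mean(valid), recon1 = recon1)
  }
  # pre-training (epoch 0) validation baseline
  state$valid_epoch0 <- validate(params, softplus(theta))$loss
  if (verbose)
    message(sprintf("epoch   0: valid %.5f (untrained)", state$valid_epoch0))
  best <- list(params = params, lambda = softplus(theta))
  repeat {
    ep_losses <- numeric(control$n_repetitions)
    for (r in seq_len(control$n_repetitions)) {
      lambda <- softplus(theta)
      fw <- admm_unrolled(y, reps[[r]]$enc_T, params, lambda, control,
                          cache = TRUE)
      lg <- kspace_loss(fw$x, y, reps[[r]]$enc_L, grad = TRUE,
                        single = identical(control$precision, "single"))
      ep_losses[r] <- lg$loss
      if (!is.finite(lg$loss)) {
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d repetition %d",
          state$epoch + 1L, r))
      }
      bw <- unroll_backward(lg$gx, fw$caches, reps[[r]]$enc_T, params,
                            lambda, control)
      t_step <- t_step + 1L
      g <- bw$gparams
      gl_raw <- bw$glambda
      if (is.finite(control$clip_grad)) {
        gn2 <- gl_raw^2
        denoiser_map(function(a) {
          gn2 <<- gn2 + sum(a^2)
          a
        }, g)
        gn <- sqrt(gn2)
        if (gn > control$clip_grad) {
          sc <- control$clip_grad / gn
          g <- denoiser_map(function(a) a * sc, g)
          gl_raw <- gl_raw * sc
        }
      }
      # ADAM on the weights
      ad_w$m <- denoiser_map(function(m, gg) 0.9 * m + 0.1 * gg, ad_w$m, g)
      ad_w$v <- denoiser_map(function(v, gg) 0.999 * v + 0.001 * gg^2,
                             ad_w$v, g)
      bc1 <- 1 - 0.9^t_step
      bc2 <- 1 - 0.999^t_step
      params <- denoiser_map(function(p, m, v)
        p - control$lr * (m / bc1) / (sqrt(v / bc2) + 1e-8),
        params, ad_w$m, ad_w$v)
      # ADAM on theta (lambda via softplus)
      gl <- gl_raw * sigmoid(theta)
      st <- adam_step(theta, gl, list(m = ad_l$m, v = ad_l$v), control$lr,
                      t_step)
      ad_l <- list(m = st$m, v = st$v)
      theta <- st$p
      if (!is.finite(theta)) stop("training diverged: lambda became non-finite")
    }
    lambda <- softplus(theta)
    vres <- validate(params, lambda)
    vloss <- vres$loss
    valid_recon1 <- vres$recon1
    state$train_loss <- c(state$train_loss, mean(ep_losses))
    state$lambda_trace <- c(state$lambda_trace, lambda)
    state <- update_train_state(state, vloss)
    if (attr(state, "improved"))
      best <- list(params = params, lambda = lambda,
                   valid_recon = valid_recon1)
    if (verbose)
      message(sprintf(
        "epoch %3d: train %.5f  valid %.5f  lambda %.4f  trace %d",
        state$epoch, mean(ep_losses), vloss, lambda, state$trace))
    if (train_should_stop(state, control)) break
  }
  structure(list(params = best$params, lambda = best$lambda,
                 train_state = state, control = control, enc = enc, y = y,
                 valid_recon = best$valid_recon,
                 call = match.call()), class = "unroll_fit")
}

#' Regenerate the T/L/V splits used by a fit
#'
#' @param object an `unroll_fit`.
#' @return list of splits as returned by [split_mask()].
#' @export
fit_splits <- function(object) {
  split_mask(object$enc$mask, object$control$split_ratios,
             object$control$n_repetitions,
             seed = derive_seed(object$control$seed, "split"))
}

#' Reconstruct with a trained unrolled model
#'
#' Runs the unrolled ADMM with the trained weights and `lambda`, by
#' default on the training data with the full acquired mask; supply
#' `y`/`enc` of another slice with the same protocol geometry (same number
#' of diffusion volumes, shots and matrix size) for cross-slice inference.
#'
#' @param object an `unroll_fit`.
#' @param y optional k-space of another slice.
#' @param enc optional [encoding_operator()] of that slice.
#' @param mask optional data-consistency mask overriding the full acquired
#'   mask.
#' @param ... unused.
#' @return complex image stack.
#' @export
predict.unroll_fit <- function(object, y = NULL, enc = NULL, mask = NULL,
                               ...) {
  if (is.null(y) != is.null(enc))
    stop("supply both y and enc (or neither)")
  if (is.null(y)) {
    y <- object$y
    enc <- object$enc
  } else {
    y <- ks_array(y)
    d_new <- enc_dims(enc)
    d_old <- enc_dims(object$enc)
    if (!identical(d_new[c("Nd", "Ns", "Ny", "Nx")],
                   d_old[c("Nd", "Ns", "Ny", "Nx")]))
      stop("geometry mismatch: new data has a different protocol (Ndiff/shots/matrix)")
  }
  if (!is.null(mask)) enc <- enc_with_mask(enc, mask)
  admm_unrolled(y, enc, object$params, object$lambda, object$control)
}

#' @export
fitted.unroll_fit <- function(object, ...) predict(object)

#' Masked k-space residual of the reconstruction
#'
#' @param object an `unroll_fit`.
#' @param ... unused.
#' @return complex k-space residual `A x - y` on the acquired mask.
#' @export
residuals.unroll_fit <- function(object, ...) {
  x <- predict(object)
  apply_forward(x, object$enc) - mask_kspace(object$y, object$enc$mask)
}

#' @export
coef.unroll_fit <- function(object, ...) {
  n_w <- 0
  denoiser_map(function(a) {
    n_w <<- n_w + length(a)
    a
  }, object$params)
  c(lambda = object$lambda, n_weights = n_w)
}

#' @export
print.unroll_fit <- function(x, ...) {
  st <- x$train_state
  d <- enc_dims(x$enc)
  cat("Self-supervised unrolled ADMM fit\n")
  cat(sprintf("  data: %d diffusion volumes, %d shots, %d coils, %dx%d, MB %d\n",
              d["Nd"], d["Ns"], d["Nc"], d["Ny"], d["Nx"], d["Nz"]))
  cat(sprintf("  epochs run: %d (best validation %.5f at epoch %d)\n",
              st$epoch, st$best_valid, st$best_epoch))
  cat(sprintf("  learned lambda: %.4f (rho fixed at %.3g)\n", x$lambda,
              x$control$rho))
  invisible(x)
}

#' @export
summary.unroll_fit <- function(object, ...) {
  st <- object$train_state
  out <- list(
    epochs = st$epoch, best_epoch = st$best_epoch,
    best_valid = st$best_valid, final_train = tail(st$train_loss, 1),
    lambda = object$lambda, trace = st$trace,
    stopped_by = if (st$trace >= object$control$patience) "patience"
    else "epoch cap")
  class(out) <- "summary.unroll_fit"
  out
}

#' @export
print.summary.unroll_fit <- function(x, ...) {
  cat(sprintf(
    "epochs %d (best %d), best validation loss %.5f, final train loss %.5f\n",
    x$epochs, x$best_epoch, x$best_valid, x$final_train))
  cat(sprintf("lambda %.4f; stopped by %s (trace %d)\n", x$lambda,
              x$stopped_by, x$trace))
  invisible(x)
}

#' Plot training diagnostics of an unrolled fit
#'
#' Training and validation loss curves (log scale) and the learned
#' `lambda` trajectory across epochs.
#'
#' @param x an `unroll_fit`.
#' @param ... unused.
#' @export
plot.unroll_fit <- function(x, ...) {
  st <- x$train_state
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  ep <- seq_along(st$train_loss)
  matplot(ep, cbind(st$train_loss, st$valid_loss), type = "l", lty = 1,
          col = c("firebrick", "steelblue"), log = "y", xlab = "epoch",
          ylab = "normalized k-space loss", main = "self-supervised losses")
  abline(v = st$best_epoch, lty = 3)
  legend("topright", c("train (L)", "validation (V)"), lty = 1,
         col = c("firebrick", "steelblue"), bty = "n")
  plot(ep, st$lambda_trace, type = "l", xlab = "epoch",
       ylab = expression(lambda), main = "learned regularization strength")
  invisible(x)
}
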