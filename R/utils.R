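# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic named sub-streams derived from one integer seed; keeps the
# derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483629)
}

# complex inner product <a, b> = sum(conj(a) * b)
cdot <- function(a, b) sum(Conj(a) * b)

l2norm <- function(a) sqrt(sum(Mod(a)^2))

rel_err <- function(a, ref) l2norm(a - ref) / l2norm(ref)

zeros_like <- function(a) array(0i, dim = dim(a))

#' Centered orthonormal 2D FFT
#'
#' Applies the centered (DC at the middle of the grid), orthonormally scaled
#' two-dimensional discrete Fourier transform to the first two dimensions of
#' a complex array, plane by plane. This is the FFT convention used by the
#' encoding operator: with full sampling and identity encodings the operator
#' is unitary, which keeps the regularization scales stable.
#'
#' @param x complex matrix or array with the transformed plane in the first
#'   two dimensions.
#' @param inverse logical; apply the inverse transform.
#' @return array of the same shape.
#' @export
cfft2 <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("x must be a matrix or array")
  storage.mode(x) <- "complex"
  cpp_cfft2(x, inverse)
}
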