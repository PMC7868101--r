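## Internal helpers: error signalling, RNG scoping, norms, centred FFTs.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("starperf_invalid_argument", "starperf_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("starperf_format_error", "starperf_error")))
}

## Evaluate `code` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

l2norm <- function(x) sqrt(sum(Mod(x)^2))

rel_l2 <- function(x, ref) l2norm(x - ref) / l2norm(ref)

## fftshift index permutation; for even n the shift and its inverse coincide.
## Centre-origin DFT conventions put DC at index n/2 (0-based), so even extents
## are required (a single-partition stack is the one admissible odd case).
.swap <- function(n) {
  if (n == 1L) return(1L)
  if (n %% 2L != 0L) stop_invalid("centred FFT requires an even extent, got %d", n)
  c((n / 2 + 1):n, 1:(n / 2))
}

## Batched in-plane FFT over dims 1 and 2 of an array of any rank >= 2.
.fft2_many <- function(a, inverse = FALSE) {
  d <- dim(a)
  n1 <- d[1]; n2 <- d[2]; K <- prod(d) / (n1 * n2)
  dim(a) <- c(n1, n2 * K)
  a <- stats::mvfft(a, inverse = inverse)
  dim(a) <- c(n1, n2, K)
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(n2, n1 * K)
  a <- stats::mvfft(a, inverse = inverse)
  dim(a) <- c(n2, n1, K)
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- d
  a
}

## Centre-origin in-plane DFT: DC sits at index (n/2, n/2) (0-based) in both
## domains. The inverse flag gives the unnormalised conjugate transpose.
.fft2_centered <- function(a, inverse = FALSE) {
  d <- dim(a)
  K <- prod(d) / (d[1] * d[2])
  s1 <- .swap(d[1]); s2 <- .swap(d[2])
  a3 <- array(a, c(d[1], d[2], K))
  a3 <- a3[s1, s2, , drop = FALSE]
  a3 <- .fft2_many(a3, inverse = inverse)
  array(a3[s1, s2, , drop = FALSE], d)
}

## Centre-origin DFT along the partition (3rd) axis, batched over all others.
.fftz_centered <- function(a, inverse = FALSE) {
  d <- dim(a)
  nz <- d[3]
  if (nz == 1L) return(a)
  K1 <- d[1] * d[2]; K2 <- prod(d) / (K1 * nz)
  s <- .swap(nz)
  a3 <- aperm(array(a, c(K1, nz, K2)), c(2, 1, 3))
  a3 <- a3[s, , , drop = FALSE]
  a3 <- array(stats::mvfft(matrix(a3, nz), inverse = inverse), c(nz, K1, K2))
  a3 <- a3[s, , , drop = FALSE]
  array(aperm(a3, c(2, 1, 3)), d)
}
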