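# Orthogonal periodised discrete wavelet transform, used by the denoiser
# and the wavelet envelope feature. Hand-implemented (the installed stack
# has no wavelet package); filters are the standard Daubechies
# orthonormal coefficients.

.dbFilters <- list(
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
          0.0328830116668852, -0.0105974017850690),
  db6 = c(0.1115407433501095, 0.4946238903984533, 0.7511339080210954,
          0.3152503517091976, -0.2262646939654398, -0.1297668675672619,
          0.0975016055873230, 0.0275228655303057, -0.0315820393174862,
          0.0005538422011614, 0.0047772575109455, -0.0010773010853085))

.waveletFilter <- function(name) {
  h <- .dbFilters[[name]]
  if (is.null(h)) stop("unknown wavelet: ", name)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

# one analysis step, periodised: a[k] = sum_n h[n] x[(2k-1+n-1) mod N + 1]
.dwtStep <- function(x, flt) {
  N <- length(x)
  L <- length(flt$h)
  half <- N / 2
  idx <- outer(seq(1, N, by = 2), 0:(L - 1), function(s, n) (s + n - 1) %% N + 1)
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% flt$h), d = drop(xm %*% flt$g))
}

.idwtStep <- function(a, d, flt) {
  N <- 2 * length(a)
  L <- length(flt$h)
  x <- numeric(N)
  for (k in seq_along(a)) {
    pos <- ((2 * (k - 1) + 0:(L - 1)) %% N) + 1
    x[pos] <- x[pos] + a[k] * flt$h + d[k] * flt$g
  }
  x
}

#' Periodised discrete wavelet transform
#'
#' @param x numeric signal; the length is padded internally to a multiple of
#'   `2^levels` by symmetric reflection.
#' @param wavelet `"db4"` or `"db6"`.
#' @param levels decomposition depth.
#' @return list with approximation `a`, detail list `d` (level 1 =
#'   finest), original length `n` and padding used.
#' @export
pcgDWT <- function(x, wavelet = "db6", levels = 5) {
  if (levels < 1) stop("levels must be >= 1")
  flt <- .waveletFilter(wavelet)
  n <- length(x)
  block <- 2^levels
  pad <- (block - n %% block) %% block
  if (n <= 2^levels) stop("signal too short for requested decomposition")
  if (pad > 0) {
    refl <- rev(x)[seq_len(min(pad, n))]
    while (length(refl) < pad) refl <- c(refl, rev(refl))[seq_len(pad)]
    x <- c(x, refl)
  }
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- .dwtStep(a, flt)
    a <- st$a
    d[[j]] <- st$d
  }
  list(a = a, d = d, n = n, pad = pad, wavelet = wavelet)
}

#' Inverse of [pcgDWT()]
#'
#' @param w a decomposition from [pcgDWT()].
#' @return the reconstructed signal, trimmed to the original length.
#' @export
pcgIDWT <- function(w) {
  flt <- .waveletFilter(w$wavelet)
  a <- w$a
  for (j in rev(seq_along(w$d))) a <- .idwtStep(a, w$d[[j]], flt)
  a[seq_len(w$n)]
}
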