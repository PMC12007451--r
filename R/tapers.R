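# Discrete prolate spheroidal (Slepian) sequences.
#
# Eigenvectors of the symmetric tridiagonal matrix that commutes with the
# time-band-limiting operator (diagonal ((N-1-2t)/2)^2 cos(2*pi*W),
# off-diagonal t(N-t)/2). For long sequences the tapers are computed on a
# 1025-point grid and spline-interpolated, then re-orthonormalized; the
# low-order tapers are smooth so the interpolation error is ~1e-7.

dpss_tridiag <- function(n, nw, k) {
  w <- nw / n
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  a <- diag(d)
  a[cbind(1:(n - 1), 2:n)] <- e
  a[cbind(2:n, 1:(n - 1))] <- e
  v <- eigen(a, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  fix_dpss_signs(v)
}

fix_dpss_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    if (j %% 2 == 1) {             # symmetric orders: positive mean
      if (sum(v[, j]) < 0) v[, j] <- -v[, j]
    } else {                       # antisymmetric orders: positive initial slope
      if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
    }
  }
  v
}

taper_cache <- new.env(parent = emptyenv())

#' DPSS (Slepian) tapers
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers; must satisfy \code{k <= 2 nw - 1}.
#' @return n x k matrix of orthonormal tapers (columns), unit energy.
#' @export
dpss_tapers <- function(n, nw, k) {
  assert_that(n >= 8, "taper length too short")
  assert_that(k >= 1 && k <= 2 * nw - 1,
              "number of tapers must satisfy k <= 2*NW - 1")
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(taper_cache[[key]])) return(taper_cache[[key]])
  base_n <- 1025L
  v <- if (n <= base_n) {
    dpss_tridiag(n, nw, k)
  } else {
    vb <- dpss_tridiag(base_n, nw, k)
    xb <- (seq_len(base_n) - 0.5) / base_n
    xn <- (seq_len(n) - 0.5) / n
    vi <- vapply(seq_len(k), function(j)
      stats::spline(xb, vb[, j], xout = xn)$y, numeric(n))
    vi <- matrix(vi, ncol = k)
    q <- qr.Q(qr(vi))
    for (j in seq_len(k)) if (sum(q[, j] * vi[, j]) < 0) q[, j] <- -q[, j]
    fix_dpss_signs(q)
  }
  taper_cache[[key]] <- v
  v
}
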