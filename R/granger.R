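#' Fit a bivariate vector autoregression by ordinary least squares
#'
#' Demeans both signals and solves the stacked-lag OLS problem for the
#' coefficient matrices; the residual covariance comes from the OLS
#' residuals. The fitted model is checked for stability (companion-matrix
#' spectral radius < 1).
#'
#' @param x,y equal-length numeric signals.
#' @param rate sampling rate, Hz.
#' @param order model order in lags (default 50).
#' @return object of class \code{var_model}: \code{coefs} (2 x 2 x order
#'   array), \code{sigma} (2 x 2 residual covariance), \code{order},
#'   \code{sample_rate}, \code{spectral_radius}.
#' @export
fit_var <- function(x, y, rate, order = 50) {
  assert_that(length(x) == length(y), "signals must have equal length")
  n <- length(x)
  assert_that(n >= 10 * order, "need at least 10x order samples", "too_short_error")
  x <- x - mean(x); y <- y - mean(y)
  dat <- cbind(x, y)
  nt <- n - order
  # regressor matrix: [x(t-1) y(t-1) x(t-2) y(t-2) ...]
  reg <- matrix(0, nt, 2 * order)
  for (k in seq_len(order)) {
    reg[, 2 * k - 1] <- x[(order - k + 1):(n - k)]
    reg[, 2 * k] <- y[(order - k + 1):(n - k)]
  }
  resp <- dat[(order + 1):n, , drop = FALSE]
  xtx <- crossprod(reg)
  qrx <- qr(xtx)
  if (qrx$rank < ncol(reg))
    stop_ictalysis("rank-deficient regressor matrix (constant or collinear signals)",
                   "rank_error")
  beta <- solve(qrx, crossprod(reg, resp))   # (2*order) x 2
  resid <- resp - reg %*% beta
  sigma <- crossprod(resid) / (nt - 2 * order)
  coefs <- array(0, dim = c(2, 2, order))
  for (k in seq_len(order)) coefs[, , k] <- t(beta[c(2 * k - 1, 2 * k), ])
  # companion matrix stability
  comp <- matrix(0, 2 * order, 2 * order)
  for (k in seq_len(order)) comp[1:2, (2 * k - 1):(2 * k)] <- coefs[, , k]
  if (order > 1) comp[3:(2 * order), 1:(2 * order - 2)] <- diag(2 * order - 2)
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    stop_ictalysis(sprintf("fitted VAR is unstable (spectral radius %.4f)", rho),
                   "unstable_model_error")
  structure(list(coefs = coefs, sigma = sigma, order = order,
                 sample_rate = rate, spectral_radius = rho),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> bivariate VAR(%d) @ %g Hz, spectral radius %.4f\n",
              x$order, x$sample_rate, x$spectral_radius))
  invisible(x)
}

#' Frequency-domain (Geweke) Granger causality from a VAR model
#'
#' Computes the transfer function \code{H(f) = A(f)^-1}, the spectral
#' matrix \code{S(f) = H Sigma H*}, and the Geweke directed measures
#' \code{F(x->y) = ln(Syy / (Syy - (Sxx.r) |Hyx|^2))} where \code{Sxx.r}
#' is the partial residual variance \code{Sigma_xx - Sigma_xy^2/Sigma_yy},
#' and symmetrically for y->x, on a uniform grid in (0, Nyquist].
#'
#' @param model a \code{\link{fit_var}} result (or a list with the same
#'   fields, e.g. a ground-truth generating model).
#' @param n_freqs number of frequency points (default 1000).
#' @return object of class \code{granger_spectrum}: \code{freqs},
#'   \code{gc_xy} (x drives y), \code{gc_yx}, \code{gc_inst}
#'   (instantaneous), \code{total} (total interdependence), \code{flagged}
#'   (frequencies where the spectral matrix was near singular).
#' @export
spectral_granger <- function(model, n_freqs = 1000) {
  sigma <- model$sigma
  order <- model$order
  rate <- model$sample_rate
  freqs <- seq_len(n_freqs) / n_freqs * rate / 2
  sxx_r <- sigma[1, 1] - sigma[1, 2]^2 / sigma[2, 2]
  syy_r <- sigma[2, 2] - sigma[1, 2]^2 / sigma[1, 1]
  gc_xy <- gc_yx <- gc_inst <- total <- numeric(n_freqs)
  flagged <- logical(n_freqs)
  for (i in seq_len(n_freqs)) {
    z <- exp(-2i * pi * freqs[i] / rate * seq_len(order))
    a <- diag(2) + 0i
    for (k in seq_len(order)) a <- a - model$coefs[, , k] * z[k]
    h <- solve(a)
    s <- h %*% sigma %*% Conj(t(h))
    sxx <- Re(s[1, 1]); syy <- Re(s[2, 2])
    dets <- Re(s[1, 1] * s[2, 2] - s[1, 2] * s[2, 1])
    if (dets <= 0 || sxx <= 0 || syy <= 0) {
      flagged[i] <- TRUE
      gc_xy[i] <- gc_yx[i] <- gc_inst[i] <- total[i] <- NA_real_
      next
    }
    den_y <- syy - sxx_r * Mod(h[2, 1])^2
    den_x <- sxx - syy_r * Mod(h[1, 2])^2
    gc_xy[i] <- if (den_y > 0) log(syy / den_y) else NA_real_
    gc_yx[i] <- if (den_x > 0) log(sxx / den_x) else NA_real_
    total[i] <- log(sxx * syy / dets)
    gc_inst[i] <- if (den_x > 0 && den_y > 0) log(den_x * den_y / dets)
                  else NA_real_
    flagged[i] <- is.na(gc_xy[i]) || is.na(gc_yx[i])
  }
  gc_xy[!is.na(gc_xy) & gc_xy < 0] <- 0
  gc_yx[!is.na(gc_yx) & gc_yx < 0] <- 0
  structure(list(freqs = freqs, gc_xy = gc_xy, gc_yx = gc_yx,
                 gc_inst = gc_inst, total = total, flagged = flagged,
                 sample_rate = rate),
            class = "granger_spectrum")
}

#' @export
print.granger_spectrum <- function(x, ...) {
  cat(sprintf("<granger_spectrum> %d frequencies to %.1f Hz; mean x->y %.4g, y->x %.4g\n",
              length(x$freqs), max(x$freqs),
              mean(x$gc_xy, na.rm = TRUE), mean(x$gc_yx, na.rm = TRUE)))
  invisible(x)
}

#' Band summary of a Granger spectrum
#'
#' Mean causality over grid points in each half-open band, per direction.
#'
#' @param gs a \code{\link{granger_spectrum}}.
#' @param bands named list of \code{c(low, high)} Hz pairs.
#' @return data.frame with band, direction ("xy", "yx") and mean gc.
#' @export
granger_band_summary <- function(gs, bands = analysis_config()$bands) {
  rows <- lapply(names(bands), function(b) {
    sel <- in_half_open(gs$freqs, bands[[b]][1], bands[[b]][2])
    assert_that(any(sel), sprintf("band '%s' contains no grid points", b),
                "empty_band_error")
    data.frame(band = b,
               direction = c("xy", "yx"),
               gc = c(mean(gs$gc_xy[sel], na.rm = TRUE),
                      mean(gs$gc_yx[sel], na.rm = TRUE)))
  })
  do.call(rbind, rows)
}

#' Per-frequency false-discovery-rate mask
#'
#' Benjamini-Hochberg adjustment of per-frequency p-values across the
#' grid, as used when comparing causality or coherence spectra between
#' conditions.
#'
#' @param p numeric vector of per-frequency p-values.
#' @param q FDR level (default 0.05).
#' @return logical vector: TRUE where the adjusted p-value is below q.
#' @export
fdr_mask <- function(p, q = 0.05) stats::p.adjust(p, method = "BH") < q
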