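#' Two-sided discrete Fourier spectrum of a complex trace
#'
#' Computes the discrete Fourier transform of a uniformly sampled complex
#' trace, normalized so the synthesis relation
#' \deqn{z(t_j) = \sum_{n=-N/2}^{N/2-1} Z_n e^{i 2 \pi f_n t_j}}
#' holds exactly, with discrete frequencies \eqn{f_n = n / (N \Delta t)}.
#' The forward transform therefore carries the 1/N factor (the common
#' unnormalized-library convention divides by N and rotates to put negative
#' frequencies first, which is exactly the mapping applied here).
#' Coefficients are returned in ascending-frequency order, negative
#' frequencies first (`n = -N/2 .. N/2 - 1`). No demeaning or detrending is
#' applied; the DC bin is retained.
#'
#' @param trace A [uniform_trace()] (even length).
#' @return An object of class `mouse_spectrum` with fields `Z` (complex
#'   coefficients), `n_idx` (integer bin indices), `f_hz` (frequencies in
#'   Hz, computed from `dt` in ms), `n`, `dt`, `t0`, `participant_id`,
#'   `accuracy`.
#' @seealso [spectrum_synthesize()] for the inverse, [power_spectrum()].
#' @export
spectrum_dft <- function(trace) {
  stopifnot(inherits(trace, "uniform_trace"))
  z <- trace$z
  stopifnot_finite(z, "z")
  n <- length(z)
  if (n %% 2L != 0L) stop("spectrum requires an even-length trace",
                          call. = FALSE)
  z_full <- stats::fft(z) / n                       # bins n = 0 .. N-1
  ord <- c((n / 2 + 1):n, 1:(n / 2))                # negative frequencies first
  n_idx <- seq.int(-n / 2, n / 2 - 1)
  structure(list(Z = z_full[ord],
                 n_idx = n_idx,
                 f_hz = n_idx / (n * trace$dt) * 1000,
                 n = n, dt = trace$dt, t0 = trace$t0,
                 participant_id = trace$participant_id,
                 accuracy = trace$accuracy),
            class = "mouse_spectrum")
}

#' @export
print.mouse_spectrum <- function(x, ...) {
  cat(sprintf("<mouse_spectrum> %s: N = %d, dt = %g ms, f in [%.4g, %.4g] Hz\n",
              x$participant_id, x$n, x$dt, min(x$f_hz), max(x$f_hz)))
  invisible(x)
}

#' Reconstruct the time series from its spectrum
#'
#' Evaluates the synthesis sum, i.e. inverts [spectrum_dft()]. Round trips
#' reconstruct the input to within 1e-9 relative error.
#'
#' @param spec A `mouse_spectrum`.
#' @return A complex vector of length `spec$n`.
#' @export
spectrum_synthesize <- function(spec) {
  stopifnot(inherits(spec, "mouse_spectrum"))
  n <- spec$n
  z_full <- complex(n)
  ord <- c((n / 2 + 1):n, 1:(n / 2))
  z_full[ord] <- spec$Z
  stats::fft(z_full, inverse = TRUE)
}

#' Power spectral density
#'
#' The power at each bin is the squared modulus of the coefficient,
#' `p_n = |Z_n|^2`. Works on a fitted `mouse_spectrum`, on a column of a
#' reference subspace basis, or on any complex vector with frequencies
#' supplied.
#'
#' @param x A `mouse_spectrum`, or a complex vector of coefficients.
#' @param f Frequencies (Hz) when `x` is a bare vector.
#' @param ... Unused.
#' @return An object of class `power_spectrum`: list with `f` (Hz) and `p`
#'   (nonnegative power).
#' @export
power_spectrum <- function(x, ...) UseMethod("power_spectrum")

#' @rdname power_spectrum
#' @export
power_spectrum.mouse_spectrum <- function(x, ...) {
  structure(list(f = x$f_hz, p = Mod(x$Z)^2), class = "power_spectrum")
}

#' @rdname power_spectrum
#' @export
power_spectrum.default <- function(x, f = NULL, ...) {
  p <- Mod(as.complex(x))^2
  if (is.null(f)) f <- seq_along(p) - 1
  if (length(f) != length(p)) stop("f and x must have equal length",
                                   call. = FALSE)
  structure(list(f = f, p = p), class = "power_spectrum")
}

#' @export
plot.power_spectrum <- function(x, ..., log = "xy") {
  keep <- x$f > 0 & x$p > 0
  graphics::plot(x$f[keep], x$p[keep], log = log, xlab = "frequency (Hz)",
                 ylab = "power", type = "l", ...)
  invisible(x)
}

#' Log-log slope of a power spectrum
#'
#' Ordinary least squares of `log(p)` on `log(f)` over positive-frequency
#' bins in `(fmin, fmax]`. A slope near -1 indicates 1/f noise. Zero-power
#' bins cannot enter the log fit; they are excluded and counted.
#'
#' @param ps A `power_spectrum` (or anything [power_spectrum()] accepts).
#' @param fmin,fmax Frequency band; bins with `fmin < f <= fmax` (and
#'   `f > 0`, `p > 0`) are used.
#' @return A list with `slope`, `intercept`, `r_squared`, `n_used`,
#'   `n_zero_dropped`, and the band actually fitted (`f_range`).
#' @export
loglog_slope <- function(ps, fmin = 0, fmax = Inf) {
  if (!inherits(ps, "power_spectrum")) ps <- power_spectrum(ps)
  in_band <- ps$f > max(fmin, 0) & ps$f <= fmax
  zero <- in_band & ps$p <= 0
  use <- in_band & ps$p > 0
  if (sum(use) < 3L) {
    stop("need at least 3 positive-power bins in the band, got ", sum(use),
         call. = FALSE)
  }
  fit <- stats::lm(lp ~ lf, data = data.frame(lf = log(ps$f[use]),
                                              lp = log(ps$p[use])))
  ss_tot <- sum((log(ps$p[use]) - mean(log(ps$p[use])))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       n_used = sum(use),
       n_zero_dropped = sum(zero),
       f_range = range(ps$f[use]))
}
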