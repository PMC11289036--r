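#' Centered profile and cumulative sum for DFA
#'
#' Subtracts the (complex) mean from the series and accumulates it:
#' \eqn{\xi_n = z_n - \bar z}, \eqn{C_n = \sum_{j \le n} \xi_j}. By
#' construction the final cumulative value telescopes to zero. A constant
#' input gives an identically zero profile and is flagged degenerate;
#' downstream fluctuation computations refuse it.
#'
#' @param z Complex (or numeric) vector, length >= 8.
#' @return A list of class `dfa_profile`: `xi`, `C`, `degenerate`.
#' @export
dfa_profile <- function(z) {
  if (inherits(z, "uniform_trace")) z <- z$z
  z <- as.complex(z)
  if (length(z) < 8L) stop("need at least 8 samples for DFA", call. = FALSE)
  stopifnot_finite(z, "z")
  xi <- z - mean(z)
  C <- cumsum(xi)
  structure(list(xi = xi, C = C,
                 degenerate = all(Mod(xi) <= 1e-12 * max(1, max(Mod(z))))),
            class = "dfa_profile")
}

#' Geometric DFA scale grid
#'
#' Integer window sizes, approximately geometrically spaced. The minimum
#' defaults to 4 (window sizes of 2 are too small to detrend against) and
#' the maximum to N/4, which keeps at least four windows at the largest
#' scale.
#'
#' @param n Series length.
#' @param min_scale Smallest window (>= 4).
#' @param max_scale Largest window; default `floor(n / 4)`.
#' @param n_scales Approximate number of scales (default 20; duplicates
#'   after rounding are removed).
#' @return Strictly increasing integer vector of window sizes.
#' @export
dfa_scales <- function(n, min_scale = 4, max_scale = NULL, n_scales = 20) {
  if (is.null(max_scale)) max_scale <- floor(n / 4)
  min_scale <- as.integer(min_scale)
  max_scale <- as.integer(max_scale)
  if (min_scale < 4L) stop("min_scale must be at least 4", call. = FALSE)
  if (max_scale > n) stop("max_scale cannot exceed the series length",
                          call. = FALSE)
  if (max_scale < min_scale) stop("max_scale must be >= min_scale",
                                  call. = FALSE)
  s <- exp(seq(log(min_scale), log(max_scale), length.out = n_scales))
  sort(unique(as.integer(round(s))))
}

#' Fluctuation function at one window size
#'
#' Partitions the cumulative profile into `floor(N/s)` consecutive
#' non-overlapping windows (from the start; remainder points beyond
#' `floor(N/s) * s` are excluded), least-squares fits a degree-`d`
#' polynomial in the time index to each window (one complex fit,
#' equivalently independent fits to the real and imaginary parts with a
#' shared design), and returns the root mean square of the residual moduli
#' over all covered points:
#' \deqn{F_s = \sqrt{\frac{1}{M} \sum |r_j|^2}.}
#' Residual *moduli* are squared because the profile is complex valued.
#' With `ends = "both"` a second pass partitions from the end of the series
#' and the RMS pools both passes, so no points are discarded.
#'
#' @param profile A [dfa_profile()] (or a complex vector taken as the
#'   cumulative profile `C`).
#' @param s Window size, `4 <= s <= N`.
#' @param d Detrending polynomial degree (default 1, linear).
#' @param ends `"forward"` (default) or `"both"`.
#' @return The scalar fluctuation value `F_s >= 0`.
#' @export
fluctuation <- function(profile, s, d = 1, ends = c("forward", "both")) {
  ends <- match.arg(ends)
  if (inherits(profile, "dfa_profile")) {
    if (profile$degenerate) {
      stop("degenerate (constant) series: fluctuation undefined",
           call. = FALSE)
    }
    C <- profile$C
  } else {
    C <- as.complex(profile)
  }
  n <- length(C)
  s <- as.integer(s)
  if (s > n) stop("window size s = ", s, " exceeds series length ", n,
                  call. = FALSE)
  if (s < 4L) stop("window size must be at least 4", call. = FALSE)
  m <- n %/% s
  sq <- window_residual_sq(C[seq_len(m * s)], s, d)
  total <- sq
  npts <- m * s
  if (ends == "both") {
    sq2 <- window_residual_sq(C[(n - m * s + 1L):n], s, d)
    total <- total + sq2
    npts <- npts + m * s
  }
  sqrt(total / npts)
}

# Sum of squared residual moduli of per-window degree-d polynomial fits,
# for a profile segment whose length is a multiple of s. Columns of the
# s x m reshape are windows; the shared orthonormal design makes the
# residual projector a single matrix product.
window_residual_sq <- function(Cseg, s, d) {
  m <- length(Cseg) %/% s
  X <- cbind(rep(1 / sqrt(s), s), stats::poly(seq_len(s), degree = d))
  Cm <- matrix(Cseg, nrow = s, ncol = m)
  coefs <- t(X) %*% Cm
  R <- Cm - X %*% coefs
  sum(Mod(R)^2)
}

#' Detrended fluctuation analysis of a complex series
#'
#' Fits the scaling exponent alpha of a (possibly complex-valued) series:
#' the series is centered and cumulatively summed ([dfa_profile()]), the
#' fluctuation function is evaluated over a geometric grid of window sizes
#' ([fluctuation()]), and alpha is the ordinary least-squares slope of
#' `log(F_s)` on `log(s)` (natural logs; the base is immaterial to the
#' slope). Scales with exactly zero fluctuation cannot enter the log fit;
#' they are dropped with a warning rather than floored.
#'
#' The exponent is interpreted through [hurst_interpret()]: alpha <= 1
#' indicates a stationary, fractional-Gaussian-noise-like series with Hurst
#' parameter H = alpha; alpha > 1 indicates a non-stationary,
#' fractional-Brownian-motion-like series with H = alpha - 1.
#'
#' @param z A [uniform_trace()] or complex/numeric vector.
#' @param scales Integer window sizes; default [dfa_scales()] of the series
#'   length.
#' @param degree Detrending polynomial degree (default 1).
#' @param ends Window partition scheme, see [fluctuation()].
#' @return An object of class `dfa`: list with `s`, `F`, `alpha`,
#'   `intercept`, `H`, `classification`, `stationarity`, `degree`, `ends`,
#'   `n`, `n_scales_used`, `dropped_scales`, `r_squared`,
#'   `participant_id`.
#' @export
#' @examples
#' set.seed(1)
#' fit <- dfa(complex(real = rnorm(1024), imaginary = rnorm(1024)))
#' fit$alpha  # near 0.5 for white noise
dfa <- function(z, scales = NULL, degree = 1, ends = c("forward", "both")) {
  ends <- match.arg(ends)
  id <- NA_character_
  if (inherits(z, "uniform_trace")) {
    id <- z$participant_id
    z <- z$z
  }
  prof <- dfa_profile(z)
  if (prof$degenerate) {
    stop("degenerate (constant) series: DFA undefined", call. = FALSE)
  }
  n <- length(prof$C)
  if (is.null(scales)) scales <- dfa_scales(n)
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 4L) || any(scales > n)) {
    stop("scales must lie in [4, N]", call. = FALSE)
  }
  F_s <- vapply(scales, function(s) fluctuation(prof, s, d = degree,
                                                ends = ends), numeric(1))
  usable <- F_s > 0
  if (sum(!usable) > 0L) {
    warning(sum(!usable), " scale(s) with zero fluctuation dropped from the ",
            "log-log fit", call. = FALSE)
  }
  if (sum(usable) < 4L) {
    stop("need at least 4 scales with positive fluctuation, got ",
         sum(usable), call. = FALSE)
  }
  fit <- stats::lm(lF ~ ls, data = data.frame(ls = log(scales[usable]),
                                              lF = log(F_s[usable])))
  alpha <- unname(stats::coef(fit)[2L])
  interp <- hurst_interpret(alpha)
  structure(list(s = scales, F = F_s, alpha = alpha,
                 intercept = unname(stats::coef(fit)[1L]),
                 H = interp$H, classification = interp$classification,
                 stationarity = interp$stationarity,
                 degree = degree, ends = ends, n = n,
                 n_scales_used = sum(usable),
                 dropped_scales = scales[!usable],
                 r_squared = summary(fit)$r.squared,
                 participant_id = id),
            class = "dfa")
}

#' Hurst interpretation of a DFA exponent
#'
#' For alpha <= 1 the series behaves like a stationary
#' fractional-Gaussian-noise process with Hurst parameter H = alpha; for
#' alpha > 1 it behaves like non-stationary fractional Brownian motion with
#' H = alpha - 1. Within each regime H < 0.5 means anti-correlated
#' increments, H = 0.5 (to within 1e-6) uncorrelated, and H > 0.5
#' positively correlated; equivalently for the non-stationary regime,
#' 1 < alpha < 1.5 is anti-correlated, alpha = 1.5 uncorrelated and
#' 1.5 < alpha < 2 positively correlated. Exponents outside \[0, 2) fall
#' outside both model regimes; H is still reported, with a warning.
#'
#' @param alpha Finite DFA scaling exponent.
#' @return List with `H`, `classification` (one of `"anti-correlated"`,
#'   `"uncorrelated"`, `"positively-correlated"`) and `stationarity`
#'   (`"stationary"` or `"non-stationary"`).
#' @export
hurst_interpret <- function(alpha) {
  if (!is_number(alpha)) stop("alpha must be a finite number", call. = FALSE)
  if (alpha < 0 || alpha >= 2) {
    warning("alpha = ", signif(alpha, 4),
            " is outside the fGn/fBm model range [0, 2); ",
            "H reported anyway", call. = FALSE)
  }
  if (alpha <= 1) {
    H <- alpha
    stationarity <- "stationary"
  } else {
    H <- alpha - 1
    stationarity <- "non-stationary"
  }
  classification <- if (abs(H - 0.5) <= 1e-6) {
    "uncorrelated"
  } else if (H < 0.5) {
    "anti-correlated"
  } else {
    "positively-correlated"
  }
  list(H = H, classification = classification, stationarity = stationarity)
}

#' @export
print.dfa <- function(x, ...) {
  cat(sprintf(
    "<dfa> alpha = %.3f (H = %.3f, %s, %s), %d scales in [%d, %d], N = %d\n",
    x$alpha, x$H, x$classification, x$stationarity, x$n_scales_used,
    min(x$s), max(x$s), x$n))
  invisible(x)
}

#' @export
summary.dfa <- function(object, ...) {
  cat("Detrended fluctuation analysis (complex-valued)\n")
  cat(sprintf("  series length:    %d\n", object$n))
  cat(sprintf("  detrending:       degree-%d polynomial, %s windows\n",
              object$degree, object$ends))
  cat(sprintf("  scales:           %d used (%d dropped), range [%d, %d]\n",
              object$n_scales_used, length(object$dropped_scales),
              min(object$s), max(object$s)))
  cat(sprintf("  alpha:            %.4f (log-log fit R^2 = %.4f)\n",
              object$alpha, object$r_squared))
  cat(sprintf("  Hurst parameter:  %.4f (%s, %s)\n", object$H,
              object$classification, object$stationarity))
  invisible(object)
}

#' @export
coef.dfa <- function(object, ...) {
  c(alpha = object$alpha, intercept = object$intercept)
}

#' @export
plot.dfa <- function(x, ...) {
  graphics::plot(x$s, x$F, log = "xy", xlab = "window size s",
                 ylab = expression(F[s]), ...)
  keep <- x$F > 0
  graphics::lines(x$s[keep], exp(x$intercept + x$alpha * log(x$s[keep])),
                  lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("alpha = %.3f", x$alpha))
  invisible(x)
}

#' @export
residuals.dfa <- function(object, ...) {
  keep <- object$F > 0
  log(object$F[keep]) - (object$intercept + object$alpha *
                           log(object$s[keep]))
}
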