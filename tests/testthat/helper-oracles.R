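# Independent oracle implementations used to cross-check the package.
# These deliberately use naive algorithms (explicit loops, normal
# equations, per-window lm fits) so they share no code path with the
# implementations they verify.

# Direct O(N^2) evaluation of the two-sided DFT with the synthesis
# normalization: Z_n = (1/N) sum_j z_j exp(-i 2 pi n j / N),
# n = -N/2 .. N/2 - 1.
oracle_dft <- function(z) {
  n <- length(z)
  idx <- seq.int(-n / 2, n / 2 - 1)
  vapply(idx, function(k) {
    sum(z * exp(-1i * 2 * pi * k * (0:(n - 1)) / n)) / n
  }, complex(1))
}

# Piecewise-linear evaluator: y at query points xq given knots (x, y),
# bracketing each query by scanning.
oracle_interp <- function(x, y, xq) {
  vapply(xq, function(q) {
    if (q <= x[1]) return(y[1])
    i <- max(which(x <= q))
    if (i == length(x)) return(y[length(y)])
    w <- (q - x[i]) / (x[i + 1] - x[i])
    (1 - w) * y[i] + w * y[i + 1]
  }, numeric(1))
}

# Classical real-valued DFA, written independently: per-window lm() fits
# and an explicit loop over windows.
oracle_real_dfa <- function(x, scales, degree = 1) {
  stopifnot(is.numeric(x))
  C <- cumsum(x - mean(x))
  n <- length(C)
  F_s <- vapply(scales, function(s) {
    m <- n %/% s
    ssq <- 0
    for (w in seq_len(m)) {
      idx <- ((w - 1) * s + 1):(w * s)
      tt <- seq_len(s)
      fit <- stats::lm(C[idx] ~ stats::poly(tt, degree, raw = TRUE))
      ssq <- ssq + sum(stats::residuals(fit)^2)
    }
    sqrt(ssq / (m * s))
  }, numeric(1))
  keep <- F_s > 0
  fit <- stats::lm(log(F_s[keep]) ~ log(scales[keep]))
  list(F = F_s, alpha = unname(coef(fit)[2]))
}

# Least-squares projection via the normal equations on a (possibly
# non-orthonormal) complex basis B: fraction of Z explained by span(B).
oracle_eta <- function(B, Z) {
  G <- Conj(t(B)) %*% B
  coef <- solve(G, Conj(t(B)) %*% Z)
  proj <- B %*% coef
  sqrt(sum(Mod(proj)^2)) / sqrt(sum(Mod(Z)^2))
}

# Principal angles (radians) between the column spans of two orthonormal
# complex bases.
principal_angles <- function(U1, U2) {
  sv <- svd(Conj(t(U1)) %*% U2)$d
  acos(pmin(1, sv))
}

# Random complex standard-normal vector.
rand_cvec <- function(n) {
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
}

# A generic wiggly raw trace for preprocessing tests.
make_raw <- function(n = 200, seed = 1, id = "p1", accuracy = NULL) {
  set.seed(seed)
  t <- cumsum(stats::runif(n, 8, 12))
  raw_trace(t, cumsum(stats::rnorm(n)), cumsum(stats::rnorm(n)),
            participant_id = id, accuracy = accuracy)
}

# Build a uniform_trace directly from white noise.
make_uniform <- function(n = 64, seed = 1, id = "p1", accuracy = NULL) {
  set.seed(seed)
  uniform_trace(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
                dt = 20, participant_id = id, accuracy = accuracy)
}
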