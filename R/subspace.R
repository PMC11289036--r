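#' Assemble a cohort spectra matrix
#'
#' Stacks the spectra of a cohort column-wise into the N x P complex matrix
#' A whose p-th column is participant p's two-sided Fourier spectrum. The
#' analysis assumes fewer participants than frequency bins (P < N).
#'
#' @param spectra A non-empty list of `mouse_spectrum` objects sharing `n`,
#'   `dt` and bin ordering.
#' @return An object of class `spectra_matrix`: list with `A` (N x P
#'   complex), `participant_ids`, `accuracy` (per column, NA when unknown),
#'   `n_idx`, `f_hz`, `n`, `dt`.
#' @export
spectra_matrix <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("spectra must be a non-empty list", call. = FALSE)
  }
  stopifnot(all(vapply(spectra, inherits, logical(1), "mouse_spectrum")))
  ns <- vapply(spectra, function(s) s$n, numeric(1))
  dts <- vapply(spectra, function(s) s$dt, numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("all spectra must share N (got: ",
         paste(unique(ns), collapse = ", "),
         "); trim the cohort jointly before transforming", call. = FALSE)
  }
  if (length(unique(dts)) != 1L) {
    stop("all spectra must share dt", call. = FALSE)
  }
  n <- ns[1L]
  p <- length(spectra)
  if (p >= n) {
    stop("need fewer participants than frequency bins (P < N); got P = ", p,
         ", N = ", n, call. = FALSE)
  }
  A <- vapply(spectra, function(s) s$Z, complex(n))
  if (any(colSums(Mod(A)) == 0)) {
    stop("all-zero spectrum column in cohort", call. = FALSE)
  }
  structure(list(A = A,
                 participant_ids = vapply(spectra, function(s)
                   s$participant_id, character(1)),
                 accuracy = vapply(spectra, function(s)
                   if (is.null(s$accuracy)) NA_real_ else s$accuracy,
                   numeric(1)),
                 n_idx = spectra[[1L]]$n_idx, f_hz = spectra[[1L]]$f_hz,
                 n = n, dt = dts[1L]),
            class = "spectra_matrix")
}

#' Cumulative variance fractions from singular values
#'
#' Singular values are proportional to the square roots of the variance
#' captured by the corresponding singular vectors, so the cumulative sum of
#' their squares, normalized by the total, gives the cumulative fraction of
#' variance explained.
#'
#' @param sv Numeric vector of singular values (descending), or the list
#'   returned by [base::svd()].
#' @return Nondecreasing fractions ending at 1.
#' @export
cumulative_variance <- function(sv) {
  if (is.list(sv)) sv <- sv$d
  if (length(sv) == 0L || all(sv == 0)) {
    stop("need at least one positive singular value", call. = FALSE)
  }
  cumsum(sv^2) / sum(sv^2)
}

#' Smallest k reaching a cumulative-variance threshold
#'
#' @param fractions Nondecreasing cumulative variance fractions.
#' @param threshold Target fraction in (0, 1\]; default 0.5.
#' @return The smallest k with `fractions[k] >= threshold`.
#' @export
choose_k <- function(fractions, threshold = 0.5) {
  if (!is_number(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  which(fractions >= threshold)[1L]
}

#' Fit a reference subspace to a cohort of spectra
#'
#' Computes the (thin) singular value decomposition A = U Sigma V* of the
#' cohort spectra matrix and keeps the first k left singular vectors, where
#' k is the smallest number of components whose cumulative squared singular
#' values reach `threshold` (default 50%) of the total variance. When the
#' cohort consists of high performers the result is their *accuracy
#' subspace*: the dominant spectral structure shared by that group. New
#' spectra are scored against it with [eta()] or `predict()`.
#'
#' A is decomposed as-is: no column/row centering is applied by default, so
#' the decomposition follows the matrix algebra literally; set
#' `center = TRUE` to subtract the cohort mean spectrum first (classical
#' PCA-style centering).
#'
#' Singular-vector phases are normalized so each basis column's
#' largest-magnitude entry is real and positive; the spanned subspace (the
#' actual contract) is unaffected.
#'
#' @param spectra List of `mouse_spectrum` objects, or a `spectra_matrix`.
#' @param threshold Cumulative variance threshold in (0, 1\]; default 0.5.
#' @param k Explicit number of components, overriding the threshold rule.
#' @param center Subtract the mean spectrum before decomposing? Default
#'   `FALSE`.
#' @return An object of class `reference_subspace` with fields `U` (N x k
#'   orthonormal complex basis), `k`, `sv` (all P singular values),
#'   `fractions` (cumulative variance), `variance_fraction` (at k),
#'   `threshold`, `center`, `centering_mean`, `n`, `dt`, `f_hz`,
#'   `participant_ids` (fitting cohort), `provenance` (hash of cohort +
#'   config).
#' @export
reference_subspace <- function(spectra, threshold = 0.5, k = NULL,
                               center = FALSE) {
  sm <- if (inherits(spectra, "spectra_matrix")) spectra
        else spectra_matrix(spectra)
  A <- sm$A
  mu <- NULL
  if (isTRUE(center)) {
    mu <- rowMeans(A)
    A <- A - mu
  }
  dec <- tryCatch(svd(A), error = function(e) {
    stop("SVD failed (", conditionMessage(e), "); matrix is ", nrow(A), " x ",
         ncol(A), " with norm ", signif(sqrt(sum(Mod(A)^2)), 4),
         call. = FALSE)
  })
  fractions <- cumulative_variance(dec$d)
  if (is.null(k)) {
    k <- choose_k(fractions, threshold)
  } else {
    if (k < 1L || k > ncol(A)) stop("k must be in 1..P", call. = FALSE)
    k <- as.integer(k)
  }
  U <- dec$u[, seq_len(k), drop = FALSE]
  # phase normalization: largest-magnitude entry of each column real-positive
  for (j in seq_len(k)) {
    m <- which.max(Mod(U[, j]))
    ph <- U[m, j] / Mod(U[m, j])
    U[, j] <- U[, j] * Conj(ph)
  }
  structure(list(U = U, k = k, sv = dec$d, fractions = fractions,
                 variance_fraction = fractions[k],
                 threshold = if (is.null(threshold)) NA_real_ else threshold,
                 center = isTRUE(center), centering_mean = mu,
                 n = sm$n, dt = sm$dt, f_hz = sm$f_hz,
                 participant_ids = sm$participant_ids,
                 provenance = provenance_hash(c(sm$participant_ids,
                                                format(threshold),
                                                format(k), format(center),
                                                format(sm$n),
                                                format(sm$dt)))),
            class = "reference_subspace")
}

#' @export
print.reference_subspace <- function(x, ...) {
  cat(sprintf(
    "<reference_subspace> k = %d of P = %d components (%.1f%% variance), N = %d, fitted on %d spectra [%s]\n",
    x$k, length(x$sv), 100 * x$variance_fraction, x$n,
    length(x$participant_ids), x$provenance))
  invisible(x)
}

#' @export
summary.reference_subspace <- function(object, ...) {
  cat(sprintf("Reference subspace: k = %d components of P = %d\n",
              object$k, length(object$sv)))
  cat(sprintf("Cumulative variance at k: %.3f (threshold %.3f)\n",
              object$variance_fraction, object$threshold))
  cat(sprintf("Centering: %s; N = %d bins, dt = %g ms\n",
              if (object$center) "mean spectrum removed" else "none",
              object$n, object$dt))
  cat("Leading singular values:\n")
  print(utils::head(signif(object$sv, 4), 10))
  invisible(object)
}

#' @export
plot.reference_subspace <- function(x, ...) {
  graphics::plot(seq_along(x$fractions), x$fractions, type = "b",
                 xlab = "components", ylab = "cumulative variance fraction",
                 ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  graphics::abline(v = x$k, lty = 3)
  invisible(x)
}

#' Projection diagnostic eta
#'
#' The fraction of a spectrum lying in a reference subspace:
#' \deqn{\eta = \| \tilde{U} \tilde{U}^* Z \| / \| Z \| \in [0, 1].}
#' `eta = 1` iff Z lies entirely in the subspace; `eta = 0` iff Z is
#' orthogonal to it. Eta is invariant to rescaling of Z and nondecreasing in
#' k for nested subspaces from one SVD.
#'
#' @param sub A [reference_subspace()].
#' @param Z A `mouse_spectrum`, or a complex vector of length `sub$n`.
#' @return A list of class `eta_score`: `participant_id`, `eta`.
#' @export
eta <- function(sub, Z) {
  stopifnot(inherits(sub, "reference_subspace"))
  id <- NA_character_
  if (inherits(Z, "mouse_spectrum")) {
    id <- Z$participant_id
    Z <- Z$Z
  }
  Z <- as.complex(Z)
  if (length(Z) != sub$n) {
    stop("spectrum length ", length(Z), " does not match subspace rows ",
         sub$n, call. = FALSE)
  }
  if (!is.null(sub$centering_mean)) Z <- Z - sub$centering_mean
  nz <- cnorm(Z)
  if (nz == 0) stop("eta is undefined for an all-zero spectrum",
                    call. = FALSE)
  coords <- Conj(t(sub$U)) %*% Z          # U* Z; projection norm = ||U* Z||
  val <- min(1, cnorm(coords) / nz)
  structure(list(participant_id = id, eta = val), class = "eta_score")
}

#' @export
print.eta_score <- function(x, ...) {
  cat(sprintf("<eta_score> %s: eta = %.4f\n", x$participant_id, x$eta))
  invisible(x)
}

#' Score spectra against a fitted reference subspace
#'
#' @param object A [reference_subspace()].
#' @param newdata A `mouse_spectrum` or list of them.
#' @param ... Unused.
#' @return A data frame with `participant_id`, `eta` and `accuracy` (NA
#'   when unknown).
#' @export
predict.reference_subspace <- function(object, newdata, ...) {
  if (inherits(newdata, "mouse_spectrum")) newdata <- list(newdata)
  stopifnot(all(vapply(newdata, inherits, logical(1), "mouse_spectrum")))
  data.frame(
    participant_id = vapply(newdata, function(s) s$participant_id,
                            character(1)),
    eta = vapply(newdata, function(s) eta(object, s)$eta, numeric(1)),
    accuracy = vapply(newdata, function(s)
      if (is.null(s$accuracy)) NA_real_ else s$accuracy, numeric(1)),
    stringsAsFactors = FALSE
  )
}
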