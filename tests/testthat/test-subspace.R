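spec_of <- function(Z, id = "p", accuracy = NULL) {
  # wrap bare coefficients as a mouse_spectrum via the pipeline path,
  # without touching the RNG stream
  n <- length(Z)
  tr <- uniform_trace(complex(real = seq_len(n), imaginary = 0), dt = 20,
                      participant_id = id)
  sp <- spectrum_dft(tr)
  sp$Z <- Z
  sp$participant_id <- id
  sp$accuracy <- accuracy
  sp
}

test_that("spectra_matrix stacks cohort spectra column-wise", {
  set.seed(20)
  s1 <- spec_of(rand_cvec(8), "a")
  s2 <- spec_of(rand_cvec(8), "b")
  sm <- spectra_matrix(list(s1, s2))
  expect_equal(dim(sm$A), c(8L, 2L))
  expect_equal(sm$participant_ids, c("a", "b"))
  # storage contract: column p is spectrum p, exactly
  expect_identical(sm$A[, 1], s1$Z)
  expect_identical(sm$A[, 2], s2$Z)

  s3 <- spec_of(rand_cvec(10), "c")
  expect_error(spectra_matrix(list(s1, s3)), "share N")
  # P >= N violates the design assumption
  many <- lapply(1:8, function(i) spec_of(rand_cvec(8), paste0("p", i)))
  expect_error(spectra_matrix(many), "P < N")
})

test_that("singular values match construction and an eigen-oracle", {
  # orthogonal columns with norms 3 and 2
  A1 <- cbind(c(3, 0, 0, 0) + 0i, c(0, 2i, 0, 0))
  sv <- svd(A1)$d
  expect_equal(sv, c(3, 2), tolerance = 1e-12)

  # rank-1 matrix: second singular value collapses
  u <- rand_cvec(16); u <- u / sqrt(sum(Mod(u)^2))
  v <- rand_cvec(3); v <- v / sqrt(sum(Mod(v)^2))
  A2 <- 5 * u %*% Conj(t(v))
  sv2 <- svd(A2)$d
  expect_equal(sv2[1], 5, tolerance = 1e-10)
  expect_lt(sv2[2], 1e-10 * 5)

  # random complex 32 x 6: singular values = sqrt of eigenvalues of A* A
  set.seed(21)
  specs <- lapply(1:6, function(i) spec_of(rand_cvec(32), paste0("p", i)))
  sub <- reference_subspace(specs, threshold = 1)
  A <- spectra_matrix(specs)$A
  ev <- sort(Re(eigen(Conj(t(A)) %*% A, symmetric = TRUE)$values),
             decreasing = TRUE)
  expect_lt(max(abs(sub$sv - sqrt(ev)) / sqrt(ev[1])), 1e-8)
  # orthonormality and reconstruction of the kept basis
  G <- Conj(t(sub$U)) %*% sub$U
  expect_lt(max(Mod(G - diag(sub$k))), 1e-8)
})

test_that("cumulative variance and k-selection follow the squared-sv rule", {
  expect_equal(cumulative_variance(c(2, 1)), c(0.8, 1.0))
  expect_equal(cumulative_variance(c(1, 0, 0)), c(1, 1, 1))
  set.seed(22)
  fr <- cumulative_variance(sort(runif(10), decreasing = TRUE))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[10], 1)
  expect_error(cumulative_variance(c(0, 0)), "positive")

  expect_equal(choose_k(c(0.3, 0.45, 0.55), 0.5), 3L)
  expect_equal(choose_k(c(0.3, 0.45, 0.55, 0.9, 1), 1.0), 5L)
  expect_equal(choose_k(c(0.6, 0.8, 1), 0.5), 1L)
})

test_that("reference subspace: rank-1 cohorts and planted bases recover", {
  set.seed(23)
  base <- rand_cvec(32)
  same <- lapply(1:3, function(i) spec_of(base, paste0("p", i)))
  sub1 <- reference_subspace(same, threshold = 0.5)
  expect_equal(sub1$k, 1L)
  expect_lt(abs(eta(sub1, same[[1]])$eta - 1), 1e-8)

  # cohort drawn from a planted 4-dim basis plus tiny noise
  pc <- gen_planted_cohort(n = 64, k_true = 4, p_in = 12, p_out = 4,
                           noise_level = 1e-8, seed = 24)
  sub4 <- reference_subspace(pc$in_cohort, threshold = 0.5)
  expect_lte(sub4$k, 4L)
  ang <- principal_angles(sub4$U, pc$basis)
  expect_lt(max(ang), 1e-3)
})

test_that("provenance hash tracks the fitting configuration", {
  set.seed(25)
  specs <- lapply(1:5, function(i) spec_of(rand_cvec(16), paste0("p", i)))
  a <- reference_subspace(specs, threshold = 0.5)
  b <- reference_subspace(specs, threshold = 0.9)
  expect_false(identical(a$provenance, b$provenance))
  expect_identical(a$provenance,
                   reference_subspace(specs, threshold = 0.5)$provenance)
})

test_that("eta satisfies its span contracts and matches the LS oracle", {
  set.seed(26)
  specs <- lapply(1:6, function(i) spec_of(rand_cvec(16), paste0("p", i)))
  sub <- reference_subspace(specs, k = 2)

  # in-span vector (scaled basis column) scores exactly 1
  expect_lt(abs(eta(sub, 3 * sub$U[, 1])$eta - 1), 1e-8)
  # orthogonal vector scores 0
  w <- rand_cvec(16)
  w <- w - sub$U %*% (Conj(t(sub$U)) %*% w)
  expect_lt(eta(sub, as.complex(w))$eta, 1e-8)

  # random 2-dim subspace in dimension 6: eta equals the normal-equations
  # least-squares fraction
  B <- cbind(rand_cvec(6), rand_cvec(6))
  Q <- qr.Q(qr(B))
  sub6 <- structure(list(U = Q, k = 2L, n = 6L, centering_mean = NULL),
                    class = "reference_subspace")
  for (i in 1:20) {
    Z <- rand_cvec(6)
    expect_lt(abs(eta(sub6, Z)$eta - oracle_eta(B, Z)), 1e-10)
  }

  expect_error(eta(sub, rep(0 + 0i, 16)), "all-zero")
  expect_error(eta(sub, rand_cvec(8)), "does not match")
})

test_that("eta is scale-invariant and nondecreasing in k", {
  set.seed(27)
  specs <- lapply(1:8, function(i) spec_of(rand_cvec(24), paste0("p", i)))
  Z <- rand_cvec(24)
  subs <- lapply(1:8, function(k) reference_subspace(specs, k = k))
  etas <- vapply(subs, function(s) eta(s, Z)$eta, numeric(1))
  expect_true(all(diff(etas) >= -1e-12))

  s3 <- subs[[3]]
  expect_equal(eta(s3, (2 - 5i) * Z)$eta, eta(s3, Z)$eta, tolerance = 1e-12)
})

test_that("predict() scores cohorts and carries accuracy labels", {
  set.seed(28)
  fit_specs <- lapply(1:5, function(i) spec_of(rand_cvec(16), paste0("f", i)))
  sub <- reference_subspace(fit_specs, threshold = 0.5)
  new_specs <- lapply(1:4, function(i)
    spec_of(rand_cvec(16), paste0("n", i), accuracy = i / 10))
  tab <- predict(sub, new_specs)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$accuracy, (1:4) / 10)
  expect_true(all(tab$eta >= 0 & tab$eta <= 1))
})

test_that("optional centering subtracts the cohort mean spectrum", {
  set.seed(29)
  mu <- 10 * rand_cvec(16)
  specs <- lapply(1:6, function(i)
    spec_of(mu + 0.1 * rand_cvec(16), paste0("p", i)))
  plain <- reference_subspace(specs, threshold = 0.5)
  cent <- reference_subspace(specs, threshold = 0.5, center = TRUE)
  # uncentered: the shared mean dominates, one component suffices
  expect_equal(plain$k, 1L)
  # centered: the mean direction is removed before decomposing
  expect_false(identical(plain$U[, 1], cent$U[, 1]))
  expect_true(cent$center)
})
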