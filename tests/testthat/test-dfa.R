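test_that("dfa_profile centers, accumulates and telescopes", {
  p <- dfa_profile(c(1, -1, 1, -1, 1, -1, 1, -1))
  expect_equal(p$xi, as.complex(c(1, -1, 1, -1, 1, -1, 1, -1)))
  expect_equal(p$C, as.complex(c(1, 0, 1, 0, 1, 0, 1, 0)))
  expect_false(p$degenerate)

  # constant series: identically-zero profile, flagged degenerate
  pc <- dfa_profile(rep(4 + 2i, 16))
  expect_true(pc$degenerate)
  expect_true(all(Mod(pc$C) == 0))
  expect_error(fluctuation(pc, 4), "degenerate")

  set.seed(30)
  z <- rand_cvec(512)
  pr <- dfa_profile(z)
  expect_lt(Mod(pr$C[512]), 1e-10 * sqrt(sum(Mod(z)^2)))
  expect_lt(Mod(mean(pr$xi)), 1e-12)
})

test_that("fluctuation vanishes for exactly-linear profiles", {
  # C_n = (2 + 3i) n is linear in every window: perfect detrend
  C <- (2 + 3i) * (1:64)
  for (s in c(4, 8, 16)) {
    expect_lt(fluctuation(C, s), 1e-10)
  }
})

test_that("fluctuation matches a per-window least-squares hand oracle", {
  C <- as.complex(c(0, 1, 0, 1, 0, 2, 0, 2))
  # window 1: C = 0,1,0,1; window 2: C = 0,2,0,2; fit a + b t by hand
  res_sq <- 0
  for (w in list(c(0, 1, 0, 1), c(0, 2, 0, 2))) {
    tt <- 1:4
    fit <- lm(w ~ tt)
    res_sq <- res_sq + sum(residuals(fit)^2)
  }
  expected <- sqrt(res_sq / 8)
  expect_lt(abs(fluctuation(C, 4) - expected), 1e-12)
})

test_that("complex DFA reduces exactly to classical real DFA on real input", {
  set.seed(31)
  x <- cumsum(rnorm(600))
  scales <- dfa_scales(600)
  ref <- oracle_real_dfa(x, scales)
  prof <- dfa_profile(complex(real = x, imaginary = 0))
  F_pkg <- vapply(scales, function(s) fluctuation(prof, s), numeric(1))
  expect_lt(max(abs(F_pkg - ref$F) / ref$F), 1e-12)
  fit <- dfa(complex(real = x, imaginary = 0), scales = scales)
  expect_lt(abs(fit$alpha - ref$alpha), 1e-12)
})

test_that("fluctuation is shift-invariant and absolutely homogeneous", {
  set.seed(32)
  z <- rand_cvec(256)
  F1 <- fluctuation(dfa_profile(z), 16)
  F2 <- fluctuation(dfa_profile(z + (100 - 250i)), 16)
  expect_equal(F1, F2, tolerance = 1e-10)
  c0 <- 3 - 4i   # |c0| = 5
  F3 <- fluctuation(dfa_profile(c0 * z), 16)
  expect_equal(F3, 5 * F1, tolerance = 1e-10)
  # alpha unchanged under rescaling
  a1 <- dfa(z)$alpha
  a2 <- dfa(c0 * z)$alpha
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("both-ends windowing covers the remainder points", {
  set.seed(33)
  z <- rand_cvec(203)  # 203 %/% 16 leaves a remainder
  prof <- dfa_profile(z)
  f_fwd <- fluctuation(prof, 16)
  f_both <- fluctuation(prof, 16, ends = "both")
  expect_true(is.finite(f_both) && f_both > 0)
  expect_false(isTRUE(all.equal(f_fwd, f_both)))
})

test_that("white complex noise scales with alpha near 0.5", {
  set.seed(34)
  z <- rand_cvec(8192)
  fit <- dfa(z, scales = dfa_scales(8192, n_scales = 20))
  expect_lt(abs(fit$alpha - 0.5), 0.05)
  expect_equal(fit$stationarity, "stationary")
  expect_equal(fit$n_scales_used, length(fit$s))
})

test_that("dfa recovers the Hurst exponent of synthetic fGn", {
  set.seed(35)
  alphas <- replicate(8, dfa(gen_fgn_complex(4096, 0.8)$z)$alpha)
  # frozen band computed from this generator at these settings; fGn with
  # H = 0.8 must average near alpha = 0.8
  expect_gt(mean(alphas), 0.72)
  expect_lt(mean(alphas), 0.88)
})

test_that("F_s grows with window size on fractional-noise input", {
  set.seed(36)
  ok <- replicate(5, {
    fit <- dfa(gen_fgn_complex(2048, 0.7)$z)
    mean(diff(fit$F) >= 0)
  })
  expect_gt(mean(ok), 0.9)  # monotone in nearly every scale step
})

test_that("hurst_interpret maps alpha to H and correlation class", {
  h1 <- hurst_interpret(0.5)
  expect_equal(h1$H, 0.5)
  expect_equal(h1$classification, "uncorrelated")
  expect_equal(h1$stationarity, "stationary")

  h2 <- hurst_interpret(1.3)
  expect_equal(h2$H, 0.3, tolerance = 1e-12)
  expect_equal(h2$classification, "anti-correlated")
  expect_equal(h2$stationarity, "non-stationary")

  h3 <- hurst_interpret(1.5)
  expect_equal(h3$H, 0.5)
  expect_equal(h3$classification, "uncorrelated")
  expect_equal(h3$stationarity, "non-stationary")

  expect_equal(hurst_interpret(0.2)$classification, "anti-correlated")
  expect_equal(hurst_interpret(1.8)$classification, "positively-correlated")
  expect_warning(h4 <- hurst_interpret(-0.1), "outside")
  expect_equal(h4$H, -0.1)
  expect_warning(hurst_interpret(2.4), "outside")
})

test_that("dfa guards its preconditions and reports dropped scales", {
  expect_error(dfa(rep(1 + 1i, 64)), "degenerate")
  expect_error(dfa_profile(rand_cvec(4)), "at least 8")
  expect_error(fluctuation(rand_cvec(16) , 32), "exceeds")
  expect_error(dfa(rand_cvec(64), scales = c(4, 6, 8)), "at least 4 scales|positive fluctuation")

  s <- dfa_scales(1000)
  expect_true(all(diff(s) > 0))
  expect_gte(min(s), 4)
  expect_lte(max(s), 250)
})
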