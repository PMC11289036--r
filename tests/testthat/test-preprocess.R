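test_that("read_trace_log parses, sorts, and deduplicates cursor logs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,x,y\n0,0,0\n10,5,5\n20,10,0", path)
  tr <- read_trace_log(path)
  expect_s3_class(tr, "raw_trace")
  expect_equal(tr$t, c(0, 10, 20))
  expect_equal(tr$x, c(0, 5, 10))

  # rows out of order are sorted by timestamp
  writeLines("t,x,y\n0,0,0\n20,10,0\n10,5,5", path)
  tr2 <- read_trace_log(path)
  expect_equal(tr2$t, c(0, 10, 20))
  expect_equal(tr2$y, c(0, 5, 0))

  # duplicate timestamps: last row wins
  writeLines("t,x,y\n0,0,0\n10,1,1\n10,2,2\n20,3,3", path)
  tr3 <- read_trace_log(path)
  expect_equal(tr3$t, c(0, 10, 20))
  expect_equal(tr3$x, c(0, 2, 3))

  # header-only file and missing columns are errors
  writeLines("t,x,y", path)
  expect_error(read_trace_log(path), "insufficient")
  writeLines("t,x\n0,0\n10,5", path)
  expect_error(read_trace_log(path), "missing column")
})

test_that("read_cohort_log splits a long-format file by participant", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,t,x,y",
               "a,0,0,0", "a,10,1,1", "a,20,2,2",
               "b,0,5,5", "b,15,6,6", "b,30,7,7"), path)
  cohort <- read_cohort_log(path, accuracy = c(a = 0.9, b = 0.1))
  expect_named(cohort, c("a", "b"))
  expect_equal(cohort$a$accuracy, 0.9)
  expect_equal(cohort$b$t, c(0, 15, 30))
})

test_that("complex_embed is the definitional embedding and round-trips", {
  z <- complex_embed(c(1, 2), c(3, 4))
  expect_equal(z, c(1 + 3i, 2 + 4i))
  expect_equal(complex_embed(c(1, 2), c(0, 0)), c(1 + 0i, 2 + 0i))
  x <- rnorm(10); y <- rnorm(10)
  z <- complex_embed(x, y)
  expect_identical(Re(z), x)
  expect_identical(Im(z), y)
  expect_error(complex_embed(1:3, 1:2), "equal length")
})

test_that("resample_uniform interpolates linearly onto the grid", {
  raw <- raw_trace(c(0, 40), c(0, 40), c(0, 40))
  u <- resample_uniform(raw, dt = 20)
  # grid is 0, 20, 40; midpoint interpolated; odd length trimmed to even
  expect_equal(u$z, c(0 + 0i, 20 + 20i))
  expect_equal(u$dt, 20)

  # already-uniform data passes through unchanged (up to even trim)
  t <- seq(0, 199 * 20, by = 20)
  set.seed(4)
  x <- rnorm(200); y <- rnorm(200)
  u2 <- resample_uniform(raw_trace(t, x, y), dt = 20)
  expect_equal(u2$z, complex_embed(x, y))

  expect_error(resample_uniform(raw_trace(c(0, 30), 0:1, 0:1), dt = 20),
               "insufficient")
})

test_that("resampling matches an independent piecewise-linear oracle", {
  set.seed(42)
  n <- 1000
  t <- cumsum(runif(n, 8, 12))
  x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
  u <- resample_uniform(raw_trace(t, x, y), dt = 20)
  grid <- u$t0 + u$dt * (0:(length(u$z) - 1))
  expect_lt(max(abs(Re(u$z) - oracle_interp(t, x, grid))), 1e-9)
  expect_lt(max(abs(Im(u$z) - oracle_interp(t, y, grid))), 1e-9)
})

test_that("resampling is idempotent and never overshoots the raw range", {
  raw <- make_raw(n = 500, seed = 7)
  u <- resample_uniform(raw, dt = 20)
  # interpolation is a convex combination of raw values
  expect_gte(min(Re(u$z)), min(raw$x))
  expect_lte(max(Re(u$z)), max(raw$x))
  expect_gte(min(Im(u$z)), min(raw$y))
  expect_lte(max(Im(u$z)), max(raw$y))
  # resampling the already-uniform output reproduces it exactly
  raw2 <- raw_trace(u$t0 + u$dt * (0:(length(u$z) - 1)), Re(u$z), Im(u$z))
  u2 <- resample_uniform(raw2, dt = 20)
  expect_equal(u2$z, u$z)
  expect_equal(u2$t0, u$t0)
})

test_that("trim_cohort cuts every trace to the common even length", {
  traces <- list(make_uniform(10, 1, "a"), make_uniform(8, 2, "b"),
                 make_uniform(12, 3, "c"))
  trimmed <- trim_cohort(traces)
  expect_true(all(vapply(trimmed, length, integer(1)) == 8L))
  expect_equal(trimmed[[3]]$z, traces[[3]]$z[1:8])  # first samples kept

  # single trace unchanged
  one <- trim_cohort(list(make_uniform(16, 1)))
  expect_equal(length(one[[1]]), 16L)

  # joint trimming across two cohorts uses the union minimum
  c1 <- list(make_uniform(32, 1), make_uniform(20, 2))
  c2 <- list(make_uniform(26, 3))
  joint <- trim_cohort(c(c1, c2))
  expect_true(all(vapply(joint, length, integer(1)) == 20L))

  # odd minimum is forced even
  mixed <- trim_cohort(list(make_uniform(14, 1),
                            uniform_trace(complex(real = rnorm(10),
                                                  imaginary = rnorm(10)),
                                          dt = 20)))
  expect_true(all(vapply(mixed, length, integer(1)) %% 2L == 0L))

  bad <- list(make_uniform(10, 1),
              uniform_trace(c(1 + 1i, 2 + 2i, 3 + 3i, 4 + 4i), dt = 10))
  expect_error(trim_cohort(bad), "same dt")
})

test_that("uniform-trace CSV writer and reader round-trip exactly", {
  traces <- list(make_uniform(64, 1, "a", accuracy = 0.73),
                 make_uniform(64, 2, "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_uniform_csv(traces, path)
  back <- read_uniform_csv(path)
  for (i in seq_along(traces)) {
    orig <- traces[[i]]; got <- back[[orig$participant_id]]
    expect_lt(max(Mod(got$z - orig$z)) / max(Mod(orig$z)), 1e-12)
    expect_equal(got$dt, orig$dt)
    expect_equal(got$accuracy, orig$accuracy)
  }
})

test_that("trace constructors enforce their invariants", {
  expect_error(raw_trace(c(0, 10), c(1, 2, 3), c(1, 2, 3)), "equal length")
  expect_error(raw_trace(c(0, NA), c(1, 2), c(1, 2)), "non-finite")
  expect_error(raw_trace(c(0, 10), c(1, 2), c(1, 2), accuracy = 1.2),
               "accuracy")
  expect_error(uniform_trace(complex(real = rnorm(5), imaginary = rnorm(5))),
               "even")
})
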