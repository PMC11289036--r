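#' Complex fractional Gaussian noise trace
#'
#' Generates a complex series whose real and imaginary parts are
#' independent fractional Gaussian noise (fGn) with Hurst exponent H,
#' synthesized by circulant embedding of the exact fGn autocovariance
#' \deqn{\gamma(k) = \tfrac{\sigma^2}{2}(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}),}
#' so the sample has the target covariance exactly (no approximation bias).
#' Useful as a ground-truth input for [dfa()]: the expected scaling
#' exponent of fGn is alpha = H.
#'
#' @param n Series length (>= 16).
#' @param H Target Hurst exponent in (0, 1).
#' @param dt Sampling interval in ms (metadata for the returned trace).
#' @param sigma Marginal standard deviation of each coordinate (px).
#' @param seed Optional integer; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @param participant_id Id for the returned trace.
#' @return A [uniform_trace()] of length `n` (forced even).
#' @export
gen_fgn_complex <- function(n, H, dt = 20, sigma = 1, seed = NULL,
                            participant_id = "fgn") {
  if (!is_number(H) || H <= 0 || H >= 1) {
    stop("H must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 16L) stop("n must be at least 16", call. = FALSE)
  n <- n - n %% 2L
  with_seed(seed, {
    parts <- fgn_pair(n, H)
    z <- sigma * complex(real = parts$a, imaginary = parts$b)
    uniform_trace(z, dt = dt, t0 = 0, participant_id = participant_id)
  })
}

# Two independent unit-variance fGn samples of length n via
# Davies-Harte / circulant embedding. The 2n x 2n circulant of the
# autocovariance has real nonnegative eigenvalues (its fft); coloring
# complex white noise by their square roots and transforming back gives a
# complex Gaussian vector whose real and imaginary parts are independent
# fGn(H) samples.
fgn_pair <- function(n, H) {
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  row1 <- c(g[1:n], g[n + 1L], g[n:2])              # circulant first row, 2n
  lambda <- Re(stats::fft(row1))
  lambda[lambda < 0] <- 0                            # clip tiny negatives
  m <- 2L * n
  w <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  y <- stats::fft(sqrt(lambda) * w) / sqrt(m)
  list(a = Re(y[1:n]), b = Im(y[1:n]))
}

#' Cohort of spectra with a planted low-dimensional subspace
#'
#' Builds two synthetic cohorts of length-N spectra: the in-cohort lies (up
#' to noise) in the span of `k_true` random orthonormal complex basis
#' vectors; the out-cohort lies in a `k_true`-dimensional subspace of the
#' orthogonal complement, with the same noise. This is the controlled
#' analogue of a study in which high performers share spectral structure
#' that low performers lack: a subspace fitted on the in-cohort should give
#' high [eta()] for in-cohort members and low eta for out-cohort members.
#'
#' Coefficients are standard complex Gaussian, so the expected signal
#' energy per spectrum is `k_true`; noise is i.i.d. complex Gaussian scaled
#' so its expected norm is `noise_level` times the expected signal norm.
#'
#' @param n Spectrum length N (> 2 * k_true).
#' @param k_true Planted basis dimension.
#' @param p_in,p_out Cohort sizes (`k_true < p_in < n`).
#' @param noise_level Relative noise (>= 0); 0 plants the subspace exactly.
#' @param dt Nominal sampling interval in ms (spectrum metadata).
#' @param seed Optional integer seed.
#' @return List with `in_cohort` and `out_cohort` (lists of
#'   `mouse_spectrum`), `basis` (N x k_true complex matrix spanning the
#'   planted subspace) and `basis_out`.
#' @export
gen_planted_cohort <- function(n, k_true, p_in, p_out, noise_level = 0,
                               dt = 20, seed = NULL) {
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("n must be even", call. = FALSE)
  if (!(k_true < p_in && p_in < n)) {
    stop("need k_true < p_in < n", call. = FALSE)
  }
  if (2L * k_true > n) stop("need 2 * k_true <= n for an orthogonal ",
                            "out-of-subspace cohort", call. = FALSE)
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  with_seed(seed, {
    # orthonormalize 2*k_true random complex directions; first k_true span
    # the planted subspace, the rest live in its orthogonal complement
    Braw <- matrix(rcnorm(n * 2L * k_true), nrow = n)
    Q <- qr.Q(qr(Braw))
    B_in <- Q[, 1:k_true, drop = FALSE]
    B_out <- Q[, (k_true + 1L):(2L * k_true), drop = FALSE]
    noise_sd <- noise_level * sqrt(k_true / n)       # per-entry complex sd
    make_cohort <- function(B, p, prefix) {
      lapply(seq_len(p), function(i) {
        zc <- B %*% rcnorm(k_true) + noise_sd * rcnorm(n)
        spectrum_from_coeffs(as.complex(zc), dt = dt,
                             participant_id = sprintf("%s%03d", prefix, i))
      })
    }
    list(in_cohort = make_cohort(B_in, p_in, "in"),
         out_cohort = make_cohort(B_out, p_out, "out"),
         basis = B_in, basis_out = B_out)
  })
}

# Wrap a bare coefficient vector (already in negative-frequencies-first
# order) as a mouse_spectrum.
spectrum_from_coeffs <- function(Z, dt = 20, participant_id = "p",
                                 accuracy = NULL) {
  n <- length(Z)
  n_idx <- seq.int(-n / 2, n / 2 - 1)
  structure(list(Z = Z, n_idx = n_idx, f_hz = n_idx / (n * dt) * 1000,
                 n = n, dt = dt, t0 = 0, participant_id = participant_id,
                 accuracy = accuracy),
            class = "mouse_spectrum")
}

#' Whac-A-Mole game configuration
#'
#' Defaults follow the original task: each mole is visible for 650 ms; a
#' hit mole stays on screen stunned for 350 ms before the next appears; the
#' game ends after 120 moles; the browser polls the cursor every 8-12 ms.
#' Hills are laid out on a 3-column grid inside the play area.
#'
#' @param n_moles Number of moles shown (default 120).
#' @param visible_ms Mole visibility window in ms (default 650).
#' @param stunned_ms Post-hit display time in ms (default 350).
#' @param n_hills Number of mole hills (>= 2, default 9).
#' @param poll_ms Polling-interval range in ms (default `c(8, 12)`).
#' @param screen_px Play-area width and height in px.
#' @param hill_radius_px Click-target radius of a hill in px.
#' @param seed Seed fixing the mole schedule (same seed, same schedule,
#'   for every agent).
#' @return A list of class `game_spec`.
#' @export
game_spec <- function(n_moles = 120, visible_ms = 650, stunned_ms = 350,
                      n_hills = 9, poll_ms = c(8, 12),
                      screen_px = c(800, 600), hill_radius_px = 40,
                      seed = 1) {
  stopifnot(n_moles >= 1, visible_ms > 0, stunned_ms > 0, n_hills >= 2,
            length(poll_ms) == 2, poll_ms[1] > 0, poll_ms[2] >= poll_ms[1],
            hill_radius_px > 0)
  structure(list(n_moles = as.integer(n_moles), visible_ms = visible_ms,
                 stunned_ms = stunned_ms, n_hills = as.integer(n_hills),
                 poll_ms = poll_ms, screen_px = screen_px,
                 hill_radius_px = hill_radius_px, seed = seed),
            class = "game_spec")
}

#' Simulated player configuration
#'
#' The agent is a noisy proportional controller with a speed cap: after a
#' reaction latency it steers toward the active mole and clicks once it is
#' inside the hill radius. It is a device for generating traces whose task
#' accuracy is known by construction, not a model of human players. A
#' `"camper"` parks on one hill and clicks only the moles that appear
#' there.
#'
#' @param reaction_ms Latency before the agent knows a mole's position.
#' @param speed_px_s Maximum cursor speed (px/s); may be `Inf`.
#' @param click_jitter_px Spatial s.d. of click placement noise (px).
#' @param motor_noise_px Per-poll positional noise s.d. (px).
#' @param strategy `"reactive"` (chase every mole) or `"camper"`.
#' @param seed Optional integer seed for the agent's randomness.
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(reaction_ms = 250, speed_px_s = 1500,
                       click_jitter_px = 5, motor_noise_px = 2,
                       strategy = c("reactive", "camper"), seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(reaction_ms >= 0, speed_px_s > 0, click_jitter_px >= 0,
            motor_noise_px >= 0)
  structure(list(reaction_ms = reaction_ms, speed_px_s = speed_px_s,
                 click_jitter_px = click_jitter_px,
                 motor_noise_px = motor_noise_px, strategy = strategy,
                 seed = seed),
            class = "agent_spec")
}

#' Mole schedule for a game
#'
#' The hill sequence is pre-generated from the game seed alone (uniform
#' over hills, excluding the hill the previous mole used), so every agent
#' playing the same game spec sees the identical pseudo-random sequence.
#' Appearance *times* depend on hits and are resolved during play.
#'
#' @param game A [game_spec()].
#' @return List with `hills` (integer sequence of length `n_moles`) and
#'   `positions` (`n_hills` x 2 matrix of hill centers in px).
#' @export
mole_schedule <- function(game) {
  stopifnot(inherits(game, "game_spec"))
  with_seed(game$seed, {
    ncol_grid <- ceiling(sqrt(game$n_hills))
    nrow_grid <- ceiling(game$n_hills / ncol_grid)
    gx <- game$screen_px[1] * (seq_len(ncol_grid) - 0.5) / ncol_grid
    gy <- game$screen_px[2] * (seq_len(nrow_grid) - 0.5) / nrow_grid
    pos <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(game$n_hills), ,
                                                  drop = FALSE]
    hills <- integer(game$n_moles)
    hills[1L] <- sample.int(game$n_hills, 1L)
    for (i in seq_len(game$n_moles)[-1L]) {
      hills[i] <- sample(setdiff(seq_len(game$n_hills), hills[i - 1L]), 1L)
    }
    list(hills = hills, positions = pos)
  })
}

#' Simulate one play-through of the Whac-A-Mole game
#'
#' Runs the event loop: the agent's cursor is polled every 8-12 ms
#' (uniformly jittered, like browser polling); after its reaction latency
#' it moves toward the active mole at up to its speed cap, with motor
#' noise; when it reaches the hill it clicks (with click jitter) and the
#' mole is hit if the click lands within the hill radius while the mole is
#' visible. A hit mole is displayed stunned for `stunned_ms` before the
#' next mole appears; a missed mole is replaced immediately when its
#' visibility window ends. Accuracy is hits / n_moles.
#'
#' @param game A [game_spec()].
#' @param agent An [agent_spec()].
#' @return List with `trace` (a [raw_trace()] with clicks and the achieved
#'   accuracy attached), `accuracy`, `hits` and `schedule`.
#' @export
gen_game_trace <- function(game, agent) {
  stopifnot(inherits(game, "game_spec"), inherits(agent, "agent_spec"))
  sched <- mole_schedule(game)
  with_seed(agent$seed, {
    n_max <- ceiling(game$n_moles * (game$visible_ms + game$stunned_ms) /
                       game$poll_ms[1]) + 16L
    t_log <- numeric(n_max); x_log <- numeric(n_max); y_log <- numeric(n_max)
    clicks <- list()
    pos <- game$screen_px / 2
    camp_hill <- sched$hills[1L]
    t_now <- 0
    mole_i <- 1L
    mole_on <- 0                     # appearance time of current mole
    hits <- 0L
    k <- 0L
    while (mole_i <= game$n_moles) {
      t_prev <- t_now
      t_now <- t_now + stats::runif(1, game$poll_ms[1], game$poll_ms[2])
      # retire moles that timed out unhit (possibly several polls ago)
      while (mole_i <= game$n_moles && t_now > mole_on + game$visible_ms) {
        mole_on <- mole_on + game$visible_ms
        mole_i <- mole_i + 1L
      }
      if (mole_i > game$n_moles) break
      mole_pos <- sched$positions[sched$hills[mole_i], ]
      target <- switch(agent$strategy,
                       reactive = mole_pos,
                       camper = sched$positions[camp_hill, ])
      knows <- t_now >= mole_on + agent$reaction_ms
      if (knows || agent$strategy == "camper") {
        step_max <- agent$speed_px_s / 1000 * (t_now - t_prev)
        delta <- target - pos
        dist <- sqrt(sum(delta^2))
        if (is.finite(agent$speed_px_s)) {
          if (dist > 0) pos <- pos + delta * min(1, step_max / dist)
        } else {
          pos <- target
        }
      }
      if (agent$motor_noise_px > 0) {
        pos <- pos + stats::rnorm(2, sd = agent$motor_noise_px)
      }
      pos <- pmin(pmax(pos, c(0, 0)), game$screen_px)
      k <- k + 1L
      if (k > length(t_log)) {       # grow log if the game runs long
        t_log <- c(t_log, numeric(n_max))
        x_log <- c(x_log, numeric(n_max))
        y_log <- c(y_log, numeric(n_max))
      }
      t_log[k] <- t_now; x_log[k] <- pos[1]; y_log[k] <- pos[2]
      # click when in range of the (visible, known) mole
      can_click <- knows && t_now <= mole_on + game$visible_ms &&
        (agent$strategy == "reactive" ||
           sched$hills[mole_i] == camp_hill)
      if (can_click &&
          sqrt(sum((pos - mole_pos)^2)) <= game$hill_radius_px) {
        click_at <- pos
        if (agent$click_jitter_px > 0) {
          click_at <- click_at + stats::rnorm(2, sd = agent$click_jitter_px)
        }
        clicks[[length(clicks) + 1L]] <- c(t_now, click_at)
        if (sqrt(sum((click_at - mole_pos)^2)) <= game$hill_radius_px) {
          hits <- hits + 1L
          mole_on <- t_now + game$stunned_ms   # next mole after stun display
          mole_i <- mole_i + 1L
        }
      }
    }
    acc <- hits / game$n_moles
    click_df <- if (length(clicks) > 0L) {
      cd <- do.call(rbind, clicks)
      data.frame(t = cd[, 1], x = cd[, 2], y = cd[, 3])
    } else {
      NULL
    }
    trace <- raw_trace(t_log[1:k], x_log[1:k], y_log[1:k],
                       participant_id = sprintf("agent_%s_r%g",
                                                agent$strategy,
                                                agent$reaction_ms),
                       clicks = click_df, accuracy = acc)
    list(trace = trace, accuracy = acc, hits = hits, schedule = sched)
  })
}
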