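#' Column dialect for raw cursor logs
#'
#' Describes how to find the timestamp, x and y columns (and optionally a
#' participant id and click flag) in a delimited cursor log.
#'
#' @param t,x,y Column names for the timestamp (ms), horizontal and vertical
#'   cursor position (px).
#' @param id Optional column name holding the participant id (required for
#'   long-format cohort logs read with [read_cohort_log()]).
#' @param click Optional column name holding a 0/1 click flag.
#' @param sep Field separator.
#' @return A list of class `trace_dialect`.
#' @export
trace_dialect <- function(t = "t", x = "x", y = "y", id = NULL,
                          click = NULL, sep = ",") {
  structure(list(t = t, x = x, y = y, id = id, click = click, sep = sep),
            class = "trace_dialect")
}

#' Construct a raw cursor trace
#'
#' A raw trace holds irregularly sampled, time-stamped cursor positions for
#' one participant, prior to resampling. Rows are sorted by timestamp
#' (stable sort) and duplicate timestamps are collapsed keeping the last
#' record, matching browser event order where the last write wins. Click
#' events are carried as metadata only; they never enter the spectral or
#' fluctuation analyses.
#'
#' @param t Timestamps in ms (length >= 2 after deduplication).
#' @param x,y Cursor coordinates in px, same length as `t`.
#' @param participant_id Identifier string.
#' @param clicks Optional data frame of click events with columns `t`, `x`,
#'   `y`.
#' @param accuracy Optional task accuracy in \[0, 1\] (fraction of targets
#'   hit).
#' @return An object of class `raw_trace` with fields `t`, `x`, `y`,
#'   `participant_id`, `clicks`, `accuracy`.
#' @export
raw_trace <- function(t, x, y, participant_id = "p1", clicks = NULL,
                      accuracy = NULL) {
  if (length(t) != length(x) || length(t) != length(y)) {
    stop("t, x and y must have equal length", call. = FALSE)
  }
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  stopifnot_finite(t, "t"); stopifnot_finite(x, "x"); stopifnot_finite(y, "y")
  ord <- order(t)                      # stable: preserves input order on ties
  t <- t[ord]; x <- x[ord]; y <- y[ord]
  keep <- !duplicated(t, fromLast = TRUE)   # last record wins
  t <- t[keep]; x <- x[keep]; y <- y[keep]
  if (length(t) < 2L) {
    stop("insufficient data: a raw trace needs at least 2 distinct timestamps",
         call. = FALSE)
  }
  if (!is.null(accuracy)) {
    if (!is_number(accuracy) || accuracy < 0 || accuracy > 1) {
      stop("accuracy must be a single value in [0, 1]", call. = FALSE)
    }
  }
  structure(list(t = t, x = x, y = y,
                 participant_id = as.character(participant_id),
                 clicks = clicks, accuracy = accuracy),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %s: %d samples over %.0f ms%s\n",
              x$participant_id, length(x$t), x$t[length(x$t)] - x$t[1],
              if (is.null(x$accuracy)) "" else
                sprintf(", accuracy %.3f", x$accuracy)))
  invisible(x)
}

#' Construct a uniformly sampled complex trace
#'
#' A uniform trace stores a cursor trajectory as a single complex series
#' `z = x + iy` on a fixed time grid `t0 + (0:(N-1)) * dt`. The length is
#' required to be even so that the two-sided spectrum index range
#' `-N/2 .. N/2 - 1` is well defined.
#'
#' @param z Complex vector (real part x px, imaginary part y px), even
#'   length >= 2.
#' @param dt Sampling interval in ms.
#' @param t0 Grid origin in ms.
#' @param participant_id Identifier string.
#' @param accuracy Optional accuracy in \[0, 1\].
#' @return An object of class `uniform_trace`.
#' @export
uniform_trace <- function(z, dt = 20, t0 = 0, participant_id = "p1",
                          accuracy = NULL) {
  z <- as.complex(z)
  stopifnot_finite(z, "z")
  if (length(z) < 2L) stop("insufficient data: need at least 2 samples",
                           call. = FALSE)
  if (length(z) %% 2L != 0L) {
    stop("uniform traces must have even length (drop one trailing sample)",
         call. = FALSE)
  }
  if (!is_number(dt) || dt <= 0) stop("dt must be a positive number",
                                      call. = FALSE)
  structure(list(z = z, dt = dt, t0 = t0,
                 participant_id = as.character(participant_id),
                 accuracy = accuracy),
            class = "uniform_trace")
}

#' @export
print.uniform_trace <- function(x, ...) {
  cat(sprintf("<uniform_trace> %s: N = %d, dt = %g ms%s\n",
              x$participant_id, length(x$z), x$dt,
              if (is.null(x$accuracy)) "" else
                sprintf(", accuracy %.3f", x$accuracy)))
  invisible(x)
}

#' @export
length.uniform_trace <- function(x) length(x$z)

#' Embed 2-D coordinates in the complex plane
#'
#' Represents a 2-D trajectory as one complex series `z_n = x_n + i y_n`,
#' so one-dimensional time-series methods apply without discarding a spatial
#' dimension. `Re(z)` recovers x and `Im(z)` recovers y exactly.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A complex vector.
#' @export
#' @examples
#' complex_embed(c(1, 2), c(3, 4))
complex_embed <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  complex(real = as.numeric(x), imaginary = as.numeric(y))
}

#' Read a single-participant cursor log
#'
#' Parses a delimited text log of time-stamped cursor positions. Rows are
#' sorted by timestamp; duplicate timestamps keep the last row. Rows with
#' missing values in the t/x/y columns are dropped.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect A [trace_dialect()] mapping column names.
#' @param participant_id Id to assign; defaults to the file name (or the id
#'   column when the dialect names one).
#' @param accuracy Optional accuracy in \[0, 1\] to attach.
#' @return A [raw_trace()].
#' @export
read_trace_log <- function(path, dialect = trace_dialect(),
                           participant_id = NULL, accuracy = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(dialect$t, dialect$x, dialect$y)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  t <- as.numeric(df[[dialect$t]])
  x <- as.numeric(df[[dialect$x]])
  y <- as.numeric(df[[dialect$y]])
  ok <- is.finite(t) & is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) {
    stop("insufficient data: fewer than 2 usable rows in ", path,
         call. = FALSE)
  }
  clicks <- NULL
  if (!is.null(dialect$click) && dialect$click %in% names(df)) {
    ci <- ok & !is.na(df[[dialect$click]]) & df[[dialect$click]] != 0
    if (any(ci)) clicks <- data.frame(t = t[ci], x = x[ci], y = y[ci])
  }
  if (is.null(participant_id)) {
    participant_id <- if (!is.null(dialect$id) && dialect$id %in% names(df)) {
      as.character(df[[dialect$id]][ok][1L])
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  raw_trace(t[ok], x[ok], y[ok], participant_id = participant_id,
            clicks = clicks, accuracy = accuracy)
}

#' Read a long-format cohort log
#'
#' Reads a delimited file holding many participants' cursor samples in long
#' format and splits it into one [raw_trace()] per participant. The dialect
#' must name an id column.
#'
#' @inheritParams read_trace_log
#' @param accuracy Optional named vector mapping participant id to accuracy.
#' @return A named list of [raw_trace()] objects.
#' @export
read_cohort_log <- function(path, dialect = trace_dialect(id = "participant_id"),
                            accuracy = NULL) {
  if (is.null(dialect$id)) {
    stop("cohort logs need an id column in the dialect", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(dialect$id, dialect$t, dialect$x, dialect$y)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(df[[dialect$id]])
  out <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    sub <- df[idx, , drop = FALSE]
    id <- as.character(sub[[dialect$id]][1L])
    raw_trace(sub[[dialect$t]], sub[[dialect$x]], sub[[dialect$y]],
              participant_id = id,
              accuracy = if (!is.null(accuracy) && id %in% names(accuracy))
                unname(accuracy[id]) else NULL)
  })
  out[order(names(out))]
}

#' Resample a raw trace onto a uniform grid
#'
#' Linearly interpolates x and y independently onto the grid
#' `t0 + j * dt` with `t0` the first raw timestamp and the last grid point
#' not exceeding the last raw timestamp (no extrapolation: the browser polls
#' only on movement, so positions outside the observed span would be
#' fabricated). The interpolated coordinates are embedded as a complex
#' series; an odd-length result drops its final sample so the length is
#' even.
#'
#' @param raw A [raw_trace()].
#' @param dt Grid spacing in ms (default 20).
#' @return A [uniform_trace()] carrying the participant id and accuracy.
#' @export
resample_uniform <- function(raw, dt = 20) {
  stopifnot(inherits(raw, "raw_trace"))
  if (!is_number(dt) || dt <= 0) stop("dt must be a positive number",
                                      call. = FALSE)
  t0 <- raw$t[1L]
  span <- raw$t[length(raw$t)] - t0
  if (span < 2 * dt) {
    stop("insufficient data: trace spans ", span,
         " ms, need at least 2*dt = ", 2 * dt, " ms", call. = FALSE)
  }
  n_steps <- floor(span / dt + 1e-9)
  grid <- t0 + dt * (0:n_steps)
  xg <- stats::approx(raw$t, raw$x, xout = grid, method = "linear",
                      ties = "ordered")$y
  yg <- stats::approx(raw$t, raw$y, xout = grid, method = "linear",
                      ties = "ordered")$y
  z <- complex_embed(xg, yg)
  if (length(z) %% 2L != 0L) z <- z[-length(z)]
  uniform_trace(z, dt = dt, t0 = t0, participant_id = raw$participant_id,
                accuracy = raw$accuracy)
}

#' Trim a cohort of uniform traces to a common length
#'
#' Truncates every trace to the length of the shortest one, keeping the
#' first samples, and forces the common length even. Cohorts that will be
#' compared against one another should be trimmed jointly (pass the
#' concatenated list) so all spectra share one frequency grid.
#'
#' @param traces A non-empty list of [uniform_trace()] objects sharing `dt`.
#' @return A list of [uniform_trace()] objects, all of one even length.
#' @export
trim_cohort <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L) {
    stop("traces must be a non-empty list", call. = FALSE)
  }
  stopifnot(all(vapply(traces, inherits, logical(1), "uniform_trace")))
  dts <- vapply(traces, function(tr) tr$dt, numeric(1))
  if (length(unique(dts)) != 1L) {
    stop("all traces must share the same dt (got: ",
         paste(unique(dts), collapse = ", "), ")", call. = FALSE)
  }
  n_star <- min(vapply(traces, function(tr) length(tr$z), integer(1)))
  n_star <- n_star - n_star %% 2L
  lapply(traces, function(tr) {
    uniform_trace(tr$z[seq_len(n_star)], dt = tr$dt, t0 = tr$t0,
                  participant_id = tr$participant_id, accuracy = tr$accuracy)
  })
}

#' Write / read a cohort of uniform traces as CSV
#'
#' Long-format CSV with columns `participant_id`, `t_ms`, `x`, `y` and
#' (when known) `accuracy`. Coordinates are printed with 17 significant
#' digits so the writer/reader pair round-trips doubles exactly.
#'
#' @param traces List of [uniform_trace()] objects.
#' @param path Output file path.
#' @return `write_uniform_csv` returns `path` invisibly; `read_uniform_csv`
#'   returns a named list of [uniform_trace()] objects.
#' @export
write_uniform_csv <- function(traces, path) {
  stopifnot(all(vapply(traces, inherits, logical(1), "uniform_trace")))
  rows <- lapply(traces, function(tr) {
    n <- length(tr$z)
    data.frame(
      participant_id = tr$participant_id,
      t_ms = sprintf("%.17g", tr$t0 + tr$dt * (0:(n - 1L))),
      x = sprintf("%.17g", Re(tr$z)),
      y = sprintf("%.17g", Im(tr$z)),
      accuracy = if (is.null(tr$accuracy)) NA_character_ else
        sprintf("%.17g", tr$accuracy),
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_uniform_csv
#' @export
read_uniform_csv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  out <- lapply(split(seq_len(nrow(df)), df$participant_id), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$t_ms), , drop = FALSE]
    steps <- diff(sub$t_ms)
    dt <- steps[1L]
    if (any(abs(steps - dt) > 1e-6 * dt)) {
      stop("non-uniform grid for participant ", sub$participant_id[1L],
           call. = FALSE)
    }
    acc <- if ("accuracy" %in% names(sub) && is.finite(sub$accuracy[1L]))
      sub$accuracy[1L] else NULL
    uniform_trace(complex_embed(sub$x, sub$y), dt = dt, t0 = sub$t_ms[1L],
                  participant_id = sub$participant_id[1L], accuracy = acc)
  })
  out[order(names(out))]
}
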