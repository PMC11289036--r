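# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Standard complex Gaussian draws: real and imaginary parts N(0, 1/2) so the
# complex variance is 1.
rcnorm <- function(n) {
  complex(real = stats::rnorm(n, sd = sqrt(0.5)),
          imaginary = stats::rnorm(n, sd = sqrt(0.5)))
}

cnorm <- function(z) sqrt(sum(Mod(z)^2))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x))))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

# 32-bit polynomial rolling hash of character input, as 8 hex digits. Used
# only for provenance tags on fitted objects (config/cohort fingerprints),
# not for anything cryptographic.
provenance_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
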