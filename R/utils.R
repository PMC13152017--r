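# Internal helpers: seeded RNG scoping, validation, canonical JSON hashing.

# Run code with a local RNG state; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of a master seed into per-item child seeds, kept
# below 2^31 so they remain valid R integers.
child_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Canonical JSON: sorted keys, no whitespace dependence, stable digits.
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) {
      lapply(v, sort_rec)
    } else v
  }
  jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA, null = "null")
}

sha256_of <- function(txt) digest::digest(txt, algo = "sha256", serialize = FALSE)

# Linear interpolation of NA runs in a numeric vector; leading/trailing NA
# runs are extended from the nearest observed value.
fill_gaps_linear <- function(x) {
  n <- length(x)
  obs <- which(!is.na(x))
  if (length(obs) == 0L) return(x)
  if (length(obs) == n) return(x)
  out <- stats::approx(obs, x[obs], xout = seq_len(n), method = "linear",
                       rule = 2)$y
  out
}
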