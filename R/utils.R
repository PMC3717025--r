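# Internal helpers shared across modules. Nothing here is exported.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. `seed = NULL` leaves the global stream untouched,
# matching the behaviour of simulate() methods in base R.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a master seed so that pipeline
# stages draw from decoupled streams regardless of execution order.
derive_seed <- function(seed, offset) {
  (abs(seed) * 48271 + offset * 1000003) %% 2147483647L
}

# Cheap rolling hash over a canonical character representation; used only to
# fingerprint parameter tables for provenance in manifests, not for security.
fingerprint <- function(x) {
  s <- paste(x, collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) stop_field(field, sprintf("must lie in %s", if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

check_count <- function(x, field, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_field(field, "must be a single whole number")
  if (positive && x < 1) stop_field(field, "must be >= 1")
  if (!positive && x < 0) stop_field(field, "must be >= 0")
  invisible(as.integer(x))
}
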