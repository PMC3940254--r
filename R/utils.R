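`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a given seed without disturbing the caller's RNG stream.
# seed = NULL means: use (and advance) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# md5 fingerprint of an arbitrary R object (used to verify two models were
# evaluated on byte-identical cross-validation splits)
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, name) {
  stop_if_not_scalar_number(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  invisible(x)
}
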