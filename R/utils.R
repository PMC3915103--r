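# Internal helpers shared across modules.

af_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "atlasfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(fmt, ...) af_stop("atlasfuse_validation_error", fmt, ...)
io_error         <- function(fmt, ...) af_stop("atlasfuse_io_error", fmt, ...)

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_vec3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    validation_error("%s must be a finite numeric 3-vector", what)
  as.numeric(x)
}
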