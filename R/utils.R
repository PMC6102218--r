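# Internal helpers shared across modules.

# Condition constructors: every user-facing failure is one of these three
# classes so callers can distinguish bad arguments from bad files.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("ascansig_validation_error", "ascansig_error")))
}

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("ascansig_format_error", "ascansig_error")))
}

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("ascansig_io_error", "ascansig_error")))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream of child seeds from one master seed, kept inside the
# 32-bit signed integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + as.numeric(index) * 7919 + 17) %% 2147483587)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

check_probability_image <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    abort_validation("%s must be a numeric matrix", what)
  if (any(!is.finite(x)))
    abort_validation("%s contains non-finite values", what)
  invisible(x)
}
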