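# internal helpers shared across modules

# fail with a classed condition so callers/tests can be precise
stop_mixtox <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "mixtoxsys_error"), ...)
}

# all generators draw from a private RNG stream: the caller's .Random.seed is
# restored on exit and an explicit integer seed fully determines the output
with_gen_seed <- function(seed, code) {
  if (!rlang::is_scalar_integerish(seed) || is.na(seed)) {
    stop_mixtox("`seed` must be a single integer.", "mixtoxsys_validation_error")
  }
  withr::with_seed(as.integer(seed), code)
}

geometric_mean <- function(x) exp(mean(log(x)))

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_mixtox(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "mixtoxsys_validation_error"
    )
  }
  invisible(data)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0 && x < 1
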