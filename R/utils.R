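# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("oddpred_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop_config(name, " must be a single integer >= ", min, " (got ", x, ")")
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_config(name, " must be a probability in [0, 1] (got ", x, ")")
  as.numeric(x)
}

# deterministic child seeds below 2^31, derived from a user seed
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + 7919 * as.numeric(index)
  as.integer(s %% 2147480000)
}
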