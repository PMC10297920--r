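# internal assertion / misc helpers

abort_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive_scalar <- function(x, name) {
  abort_if(!is_scalar_number(x) || x <= 0, "`%s` must be a single positive number", name)
}

check_count <- function(x, name) {
  abort_if(!is_scalar_number(x) || x < 1 || x != round(x),
           "`%s` must be a single positive integer", name)
}

geo_mean <- function(x) exp(mean(log(x)))

# adjusted Rand index between two label vectors (mclust's implementation)
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
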