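`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stop_config <- function(field, msg) {
  stop(sprintf("configuration error in field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_config(field, sprintf("must be a single number in [%s, %s]", min, max))
  as.numeric(x)
}

rmse <- function(truth, pred) sqrt(mean((pred - truth)^2))

# Split an integer total into parts by proportions, preserving the exact sum
# (floor allocation, remainder to the largest fractional parts).
split_integer <- function(total, props) {
  raw <- total * props / sum(props)
  parts <- floor(raw)
  rem <- total - sum(parts)
  if (rem > 0) {
    idx <- order(raw - parts, decreasing = TRUE)[seq_len(rem)]
    parts[idx] <- parts[idx] + 1
  }
  as.integer(parts)
}

# Derive a per-epoch / per-fold RNG seed from a base seed, kept inside the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 7919) %% 2147483647)
}
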