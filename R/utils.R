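# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-unit child seed that stays below 2^31.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(i)) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# The eight flash stages of the default quenching protocol, in time order.
STAGES <- c("L1", "L2", "L3", "L4", "Lss", "D1", "D2", "D3")
LIGHT_STAGES <- c("L1", "L2", "L3", "L4", "Lss")
DARK_STAGES <- c("D1", "D2", "D3")
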