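# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

# ITU-R BT.601 luma weights; used wherever a scalar intensity is needed.
luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

# Population (1/N) standard deviation; the chrominance ratio mu is defined
# with it (the 1/N vs 1/(N-1) choice cancels in the ratio, but tests are
# bit-exact against this definition).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
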