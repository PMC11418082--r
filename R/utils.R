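# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression with a local RNG state so library calls never disturb the
# caller's random stream; everything in the package draws through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# leaky ReLU and its derivative w.r.t. the pre-activation
lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# One Adam update; state carries first/second moments and the step counter.
adam_init <- function(shape_like) {
  list(m = shape_like * 0, v = shape_like * 0, t = 0L)
}

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}
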