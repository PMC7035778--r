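# Elementwise nonlinearities with analytic derivatives (as functions of the
# pre-activation). The set matches the hyperparameter grid; PReLU uses a
# fixed slope of 0.25 (not learned), SELU the standard constants.

.SELU_ALPHA <- 1.6732632423543772
.SELU_SCALE <- 1.0507009873554805

.activation <- function(name) {
  switch(tolower(name),
    relu = list(
      f = function(z) pmax(z, 0),
      df = function(z) (z > 0) * 1),
    tanh = list(
      f = function(z) tanh(z),
      df = function(z) 1 - tanh(z)^2),
    elu = list(
      f = function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
      df = function(z) ifelse(z > 0, 1, exp(pmin(z, 0)))),
    leakyrelu = list(
      f = function(z) ifelse(z > 0, z, 0.01 * z),
      df = function(z) ifelse(z > 0, 1, 0.01)),
    prelu = list(
      f = function(z) ifelse(z > 0, z, 0.25 * z),
      df = function(z) ifelse(z > 0, 1, 0.25)),
    selu = list(
      f = function(z) .SELU_SCALE * ifelse(z > 0, z, .SELU_ALPHA * (exp(pmin(z, 0)) - 1)),
      df = function(z) .SELU_SCALE * ifelse(z > 0, 1, .SELU_ALPHA * exp(pmin(z, 0)))),
    stop("unknown activation: ", name)
  )
}

.ACTIVATIONS <- c("Tanh", "ELU", "LeakyReLU", "ReLU", "PReLU", "SELU")

# Glorot/Xavier uniform init. `byrow = TRUE` fills row-by-row so that, for a
# K x h output layer, the first h draws always form row 1: a K = 1 head and
# the first output of a K = 2 head then start from identical weights.
.xavier <- function(nout, nin, byrow = FALSE) {
  b <- sqrt(6 / (nin + nout))
  matrix(runif(nout * nin, -b, b), nout, nin, byrow = byrow)
}

# Inverted dropout: scales kept units by 1/(1-rate) so expectations match at
# inference. Returns the multiplicative mask.
.dropoutMask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

# --- Adam ---------------------------------------------------------------

.adamInit <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# One Adam update; `grads` mirrors the structure of `params`.
.adamStep <- function(params, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^step)
    vhat <- st$v / (1 - beta2^step)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    state[[k]] <- st
  }
  list(params = params, state = state)
}
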