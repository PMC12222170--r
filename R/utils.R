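# Internal helpers: logging, numerics, parameter-list arithmetic.

gt_log <- function(...) message("[gtmaloc] ", sprintf(...))

gt_verbose <- function(...) {
  if (isTRUE(getOption("gtmaloc.verbose", FALSE))) gt_log(...)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
elu_grad <- function(x) {
  g <- x
  neg <- x < 0
  g[neg] <- exp(x[neg])
  g[!neg] <- 1
  g
}

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
leaky_relu_grad <- function(x, slope) {
  g <- x
  neg <- x < 0
  g[neg] <- slope
  g[!neg] <- 1
  g
}

relu <- function(x) pmax(x, 0)

# Row-wise layer normalization with learnable scale g and shift b.
ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  z <- xc * inv
  out <- sweep(sweep(z, 2L, g, "*"), 2L, b, "+")
  list(out = out, z = z, inv = inv)
}

ln_backward <- function(dout, cache, g) {
  z <- cache$z
  dz <- sweep(dout, 2L, g, "*")
  dg <- colSums(dout * z)
  db <- colSums(dout)
  dx <- cache$inv * (dz - rowMeans(dz) - z * rowMeans(dz * z))
  list(dx = dx, dg = dg, db = db)
}

# Glorot-uniform init
xavier <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -l, l), n_in, n_out)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

# Adam optimizer over a flat named list of numeric arrays.
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(state = state, params = params)
}

is_binary_matrix <- function(m) is.matrix(m) && all(m %in% c(0, 1))

check_symmetric <- function(m, tol = 1e-9) {
  max(abs(m - t(m))) <= tol
}
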