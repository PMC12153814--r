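# Batch normalization for the dense-network engine: per-layer learnable
# scale/shift with running statistics for inference. Applied between the
# affine transform and the ReLU on hidden layers when enabled.

bn_init <- function(width) {
  list(gamma = rep(1, width), beta = rep(0, width),
       run_mean = rep(0, width), run_var = rep(1, width))
}

# Forward through one BN layer. In training mode uses batch moments and
# updates running statistics (momentum 0.9); in inference mode uses the
# running statistics.
bn_forward <- function(bn, z, training, eps = 1e-5) {
  if (training) {
    mu <- colMeans(z)
    v <- colMeans(sweep(z, 2, mu)^2)
    bn$run_mean <- 0.9 * bn$run_mean + 0.1 * mu
    bn$run_var <- 0.9 * bn$run_var + 0.1 * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  zc <- sweep(z, 2, mu)
  zhat <- sweep(zc, 2, sqrt(v + eps), "/")
  y <- sweep(sweep(zhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(y = y, zhat = zhat, zc = zc, var = v, bn = bn)
}

# Backward through one BN layer (training-mode batch statistics).
# delta is the gradient w.r.t. the BN output y.
bn_backward <- function(cache, bn, delta, eps = 1e-5) {
  m <- nrow(delta)
  dgamma <- colSums(delta * cache$zhat)
  dbeta <- colSums(delta)
  dzhat <- sweep(delta, 2, bn$gamma, "*")
  inv_sd <- 1 / sqrt(cache$var + eps)
  dvar <- colSums(dzhat * cache$zc) * (-0.5) * inv_sd^3
  dmu <- colSums(sweep(dzhat, 2, -inv_sd, "*")) +
    dvar * colMeans(-2 * cache$zc)
  dz <- sweep(dzhat, 2, inv_sd, "*") +
    sweep(2 * cache$zc, 2, dvar / m, "*") +
    matrix(dmu / m, m, length(dmu), byrow = TRUE)
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}
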