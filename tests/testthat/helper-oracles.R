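# Independent naive-loop oracles and random fixtures used across tests.
# Every oracle is written as an explicit scalar loop so it shares no code
# path with the vectorized implementation it checks.

oracle_column_means <- function(frames) {
  out <- numeric(ncol(frames))
  for (j in seq_len(ncol(frames))) {
    s <- 0
    for (i in seq_len(nrow(frames))) s <- s + frames[i, j]
    out[j] <- s / nrow(frames)
  }
  out
}

oracle_mbe <- function(y, yhat) {
  s <- 0
  for (m in seq_along(y)) s <- s + (y[m] - yhat[m])
  s / length(y)
}

oracle_rmse <- function(y, yhat) {
  s <- 0
  for (m in seq_along(y)) s <- s + (y[m] - yhat[m])^2
  sqrt(s / length(y))
}

oracle_rep <- function(y, yhat) {
  r <- numeric(length(y))
  for (m in seq_along(y)) r[m] <- abs(y[m] - yhat[m]) / y[m] * 100
  list(per_sample = r, max = max(r), mean = sum(r) / length(r))
}

oracle_contributions <- function(mivs) {
  tot <- 0
  for (v in mivs) tot <- tot + abs(v)
  out <- numeric(length(mivs))
  for (i in seq_along(mivs)) out[i] <- abs(mivs[i]) / tot * 100
  out
}

# Scalar per-neuron forward pass: one sample at a time, one neuron at a time.
oracle_forward <- function(genome, arch, X) {
  ni <- arch$n_input; nh <- arch$n_hidden; no <- arch$n_output
  act <- function(name, x) switch(name,
    tanh = tanh(x), sigmoid = 1 / (1 + exp(-x)), linear = x)
  preds <- matrix(NA_real_, nrow(X), no)
  for (s in seq_len(nrow(X))) {
    h <- numeric(nh)
    for (j in seq_len(nh)) {
      z <- 0
      for (i in seq_len(ni)) z <- z + genome[(j - 1) * ni + i] * X[s, i]
      z <- z + genome[nh * ni + j]
      h[j] <- act(arch$hidden_activation, z)
    }
    off <- nh * ni + nh
    for (k in seq_len(no)) {
      z <- 0
      for (j in seq_len(nh)) z <- z + genome[off + (k - 1) * nh + j] * h[j]
      z <- z + genome[off + no * nh + k]
      preds[s, k] <- act(arch$output_activation, z)
    }
  }
  if (no == 1) drop(preds) else preds
}

oracle_fd_gradient <- function(genome, arch, X, y, h = 1e-6) {
  f <- function(g) mean((nn_forward(g, arch, X) - y)^2)
  grad <- numeric(length(genome))
  for (i in seq_along(genome)) {
    up <- genome; up[i] <- up[i] + h
    dn <- genome; dn[i] <- dn[i] - h
    grad[i] <- (f(up) - f(dn)) / (2 * h)
  }
  grad
}

random_architecture <- function(ni, nh, no = 1,
                                hidden = c("tanh", "sigmoid")) {
  network_architecture(ni, nh, no,
                       hidden_activation = sample(hidden, 1),
                       output_activation = "linear")
}

random_genome <- function(arch, scale = 1) {
  stats::runif(genome_length(arch), -scale, scale)
}

small_dataset <- function(n = 20, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    X <- matrix(runif(n * 10, 10, 200), n, 10)
    colnames(X) <- plantar_regions()
    y <- 400 + rowSums(X %*% diag(runif(10, -0.3, 0.3))) + rnorm(n, 0, 2)
    structure(list(X = X, y = y,
                   meta = data.frame(subject_id = rep(sprintf("S%02d", 1:5),
                                                      length.out = n),
                                     foot = "left", trial = seq_len(n))),
              class = "pressure_dataset")
  })
}

# A trained linear-stub model: predictions are an exact affine map of the
# raw features, built by choosing a linear-activation genome whose composite
# weights realize the requested raw-scale coefficients.
linear_stub_model <- function(coefs, intercept, X) {
  arch <- network_architecture(length(coefs), 1, 1,
                               hidden_activation = "linear",
                               output_activation = "linear")
  ds <- structure(list(X = X, y = seq_len(nrow(X)) + 0.0,
                       meta = data.frame(row = seq_len(nrow(X)))),
                  class = "pressure_dataset")
  params <- fit_normalizer(structure(list(X = X,
                                          y = as.numeric(X %*% coefs) + intercept,
                                          meta = ds$meta),
                                     class = "pressure_dataset"))
  # normalized prediction must map back to coefs . x + intercept:
  # yhat_norm = sum_i wi * xnorm_i + b with
  # wi = coefs_i * (xmax - xmin)_i / (ymax - ymin)
  rx <- params$x_max - params$x_min
  ry <- params$y_max - params$y_min
  w1 <- coefs * rx / ry
  b <- (intercept + sum(coefs * params$x_min) - params$y_min) / ry
  genome <- c(w1, b, 1, 0)  # hidden unit = affine map, output = identity
  bp_model(genome, arch, params)
}
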