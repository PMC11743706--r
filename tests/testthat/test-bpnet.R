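# Network sizing, forward pass, backprop gradient and training.

test_that("hidden-layer sizing rule reproduces both printed forms", {
  expect_equal(hidden_node_count(10, 1), 13L)
  expect_equal(hidden_node_count(10, 1, a = 9, form = "sqrt"), 12L)
  expect_equal(hidden_node_count(1, 1, a = 1), 3L)
  expect_error(hidden_node_count(10, 1, a = 0), "\\[1, 9\\]")
  expect_error(hidden_node_count(10, 1, a = 10), "\\[1, 9\\]")
})

test_that("genome length matches the architecture layout (157 for 10-13-1)", {
  expect_equal(genome_length(network_architecture()), 157L)
  expect_equal(genome_length(network_architecture(2, 3, 1)), 2 * 3 + 3 + 3 + 1)
})

test_that("forward pass matches the per-neuron scalar oracle on random nets", {
  expect_equal(nn_forward(rep(0, genome_length(network_architecture())),
                          network_architecture(), runif(10)), 0)
  set.seed(101)
  for (rep in 1:20) {
    arch <- random_architecture(sample(2:6, 1), sample(2:8, 1))
    genome <- random_genome(arch)
    X <- matrix(runif(5 * arch$n_input, -2, 2), 5)
    expect_equal(nn_forward(genome, arch, X), oracle_forward(genome, arch, X),
                 tolerance = 1e-12)
  }
})

test_that("a 1-1-1 identity network passes inputs through", {
  arch <- network_architecture(1, 1, 1, hidden_activation = "linear",
                               output_activation = "linear")
  genome <- c(1, 0, 1, 0)
  x <- matrix(seq(-2, 2, by = 0.5), ncol = 1)
  expect_equal(nn_forward(genome, arch, x), drop(x))
})

test_that("backprop gradient agrees with central finite differences", {
  set.seed(202)
  for (rep in 1:20) {
    arch <- random_architecture(3, 4)
    genome <- random_genome(arch, scale = 0.8)
    X <- matrix(runif(8 * 3, -1, 1), 8)
    y <- runif(8, -1, 1)
    g <- nn_gradient(genome, arch, X, y)
    fd <- oracle_fd_gradient(genome, arch, X, y)
    expect_lt(max(abs(g - fd)) / max(abs(fd), 1e-8), 1e-6)
  }
})

test_that("gradient is zero at a perfect fit and invariant to duplication", {
  set.seed(33)
  arch <- network_architecture(3, 4, 1)
  genome <- random_genome(arch)
  X <- matrix(runif(12, -1, 1), 4)
  y <- nn_forward(genome, arch, X)
  expect_lt(max(abs(nn_gradient(genome, arch, X, y))), 1e-14)
  other <- random_genome(arch)
  g1 <- nn_gradient(other, arch, X, y)
  g2 <- nn_gradient(other, arch, rbind(X, X), c(y, y))
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("training stops immediately at an already-optimal start", {
  set.seed(44)
  arch <- network_architecture(4, 3, 1)
  genome <- random_genome(arch)
  X <- matrix(runif(40, 0, 1), 10)
  y <- nn_forward(genome, arch, X)
  fit <- train_bp(genome, arch, X, y)
  expect_lte(fit$loss_history[1], 1e-20)
  expect_equal(fit$epochs, 0L)
  expect_true(fit$converged)
  expect_identical(fit$genome, genome)
})

test_that("linear toy problem converges to the least-squares slope", {
  arch <- network_architecture(1, 1, 1, hidden_activation = "linear",
                               output_activation = "linear")
  set.seed(55)
  x <- matrix(runif(50, -1, 1), ncol = 1)
  y <- 0.5 * drop(x)
  fit <- train_bp(c(0.2, 0, 0.2, 0), arch, x, y,
                  train_config(max_epochs = 8000, learning_rate = 0.05,
                               goal_mse = 1e-12))
  p <- fit$genome
  composite <- p[1] * p[3]           # w1 * w2: end-to-end slope
  expect_equal(composite, 0.5, tolerance = 1e-3)
})

test_that("loss history is non-increasing on a convex instance", {
  arch <- network_architecture(2, 2, 1, hidden_activation = "linear",
                               output_activation = "linear")
  set.seed(66)
  X <- matrix(runif(60, -1, 1), 30)
  y <- drop(X %*% c(0.3, -0.7)) + 0.1
  fit <- train_bp(random_genome(arch, 0.3), arch, X, y,
                  train_config(max_epochs = 500, learning_rate = 0.01))
  expect_true(all(diff(fit$loss_history) <= 1e-12))
  expect_error(train_bp(random_genome(arch), arch,
                        matrix(numeric(0), 0, 2), numeric(0)), "empty")
})

test_that("models predict on the raw scale through their normalizer", {
  ds <- small_dataset(30)
  params <- fit_normalizer(ds)
  arch <- network_architecture()
  genome <- with_seed <- local({ set.seed(7); runif(157, -1, 1) })
  model <- bp_model(genome, arch, params)
  pred <- predict(model, ds)
  manual <- denormalize_target(
    nn_forward(genome, arch, normalize_features(ds$X, params)), params)
  expect_equal(pred, manual)
})

test_that("model JSON serialization is prediction-exact", {
  dir <- withr::local_tempdir()
  ds <- small_dataset(20)
  model <- bp_model(local({ set.seed(8); runif(157, -1, 1) }),
                    network_architecture(), fit_normalizer(ds))
  path <- file.path(dir, "model.json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(predict(back, ds), predict(model, ds))
})
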