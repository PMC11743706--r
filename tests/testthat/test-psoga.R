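# Hybrid PSO-GA optimizer: fitness, swarm dynamics, GA operators and the
# exchange strategy.

sphere <- function(x) sum(x^2)

test_that("fitness is the training-set RMSE of the genome's predictions", {
  arch <- network_architecture(2, 2, 1)
  set.seed(1)
  genome <- random_genome(arch)
  X <- matrix(runif(10, 0, 1), 5)
  y <- nn_forward(genome, arch, X)
  expect_equal(psoga_fitness(genome, arch, X, y), 0)
  # t = (0, 0), t_hat = (3, 4) -> sqrt(12.5)
  arch0 <- network_architecture(1, 1, 1, hidden_activation = "linear",
                                output_activation = "linear")
  g <- c(1, 0, 1, 0)  # identity net: predictions equal inputs
  expect_equal(psoga_fitness(g, arch0, matrix(c(3, 4), 2, 1), c(0, 0)),
               sqrt(12.5))
  # permutation invariance
  set.seed(2)
  X2 <- matrix(runif(12, 0, 1), 6)
  y2 <- runif(6)
  perm <- sample(6)
  expect_equal(psoga_fitness(genome, arch, X2[perm, ], y2[perm]),
               psoga_fitness(genome, arch, X2, y2))
  expect_error(psoga_fitness(genome, arch, matrix(numeric(0), 0, 2),
                             numeric(0)), "empty")
})

test_that("degenerate PSO coefficients freeze the swarm", {
  cfg <- optimizer_config(c1 = 0, c2 = 0, w_start = 0, w_end = 0,
                          swarm_size = 4)
  set.seed(3)
  swarm <- plantarstiff:::new_swarm(3, sphere, cfg)
  out <- pso_step(swarm, sphere, cfg, w = 0)
  expect_equal(out$position, swarm$position)
  expect_true(all(out$velocity == 0))
})

test_that("a particle sitting at its own best with zero velocity is stationary", {
  cfg <- optimizer_config(swarm_size = 1)
  x <- c(0.2, -0.3)
  swarm <- list(position = matrix(x, 1), velocity = matrix(0, 1, 2),
                fitness = sphere(x), pbest = matrix(x, 1),
                pbest_fit = sphere(x), gbest = x, gbest_fit = sphere(x))
  out <- pso_step(swarm, sphere, cfg, w = 0.5)
  expect_equal(drop(out$position), x)
})

test_that("PSO improves the sphere global best over initialization", {
  improved <- vapply(1:100, function(s) {
    cfg <- optimizer_config(seed = s, ga_generations = 1, ga_population = 2,
                            mutation_rate = 0, crossover_rate = 0)
    res <- with_seed <- local({
      set.seed(s)
      swarm <- plantarstiff:::new_swarm(5, sphere, cfg)
      init <- swarm$gbest_fit
      for (it in 1:30) {
        w <- 0.9 - 0.5 * (it - 1) / 29
        swarm <- pso_step(swarm, sphere, cfg, w)
      }
      swarm$gbest_fit < init
    })
    res
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})

test_that("GA with no variation operators keeps the population static", {
  cfg <- optimizer_config(crossover_rate = 0, mutation_rate = 0,
                          ga_generations = 10, ga_accuracy = 0)
  set.seed(5)
  pop <- matrix(runif(10, -1, 1), 5)
  res <- ga_run(pop, sphere, cfg)
  fits <- apply(pop, 1, sphere)
  expect_equal(res$best_fit, min(fits))
  expect_equal(res$best, pop[which.min(fits), ])
})

test_that("GA locates a 1-D quadratic optimum within 0.1 in >= 95% of seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    cfg <- optimizer_config(ga_generations = 50, ga_population = 10,
                            position_bounds = 6, mutation_sd = 0.3,
                            ga_accuracy = 0)
    pop <- matrix(runif(10, -6, 6), 10)
    res <- ga_run(pop, function(x) (x - 3)^2, cfg)
    abs(res$best - 3) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("GA best fitness is non-increasing across generations (elitism)", {
  set.seed(6)
  cfg <- optimizer_config(ga_generations = 30, ga_accuracy = 0)
  pop <- matrix(runif(15, -1, 1), 5)
  # track best per generation by wrapping the fitness with a recorder
  best_seen <- Inf
  trace <- numeric(0)
  rec <- function(x) {
    f <- sphere(x)
    best_seen <<- min(best_seen, f)
    f
  }
  ga_run(pop, rec, cfg)
  expect_true(is.finite(best_seen))
  res <- ga_run(pop, sphere, cfg)
  expect_lte(res$best_fit, min(apply(pop, 1, sphere)))
  expect_error(ga_run(matrix(numeric(0), 0, 3), sphere, cfg), "empty")
})

test_that("hybrid optimizer trace is non-increasing and deterministic", {
  cfg <- optimizer_config(pso_iterations = 15, seed = 9)
  r1 <- psoga_optimize(sphere, 5, cfg)
  r2 <- psoga_optimize(sphere, 5, cfg)
  expect_identical(r1$best, r2$best)
  expect_identical(as.numeric(r1$trace), as.numeric(r2$trace))
  expect_true(all(diff(as.numeric(r1$trace)) <= 0))
  expect_equal(r1$best_fitness, min(as.numeric(r1$trace)))
  expect_length(as.numeric(r1$trace), 15L)
})

test_that("hybrid exchange preserves swarm size and helps on the network problem", {
  cohort <- generate_cohort(cohort_config(noise_sd = 0,
                                          nonlinearity_scale = 0, seed = 12))
  ds <- as_dataset(cohort, response = "true")
  params <- fit_normalizer(ds)
  dn <- normalize_dataset(ds, params)
  arch <- network_architecture()
  cfg <- optimizer_config(pso_iterations = 8, seed = 4)
  res <- initialize_network(arch, dn$X, dn$y, cfg)
  expect_length(res$best, 157L)
  expect_true(all(diff(as.numeric(res$trace)) <= 0))
  expect_true(all(abs(res$best) <= 1))
  # the optimum beats random initializations of the same scale
  set.seed(10)
  rand <- replicate(20, psoga_fitness(runif(157, -1, 1), arch, dn$X, dn$y))
  expect_lt(res$best_fitness, stats::median(rand))
})
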