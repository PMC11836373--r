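test_that("pheromone initialization fills every trail with tau0", {
  sp <- aco_space(list(a = 1:3, b = 1:3))
  ph <- aco_init_pheromone(sp, aco_config(tau0 = 1.0))
  expect_equal(unname(lengths(ph$tau)), c(3L, 3L))
  expect_true(all(unlist(ph$tau) == 1.0))
  expect_identical(ph$iteration, 0L)

  single <- aco_init_pheromone(aco_space(list(only = 1)), aco_config(tau0 = 2))
  expect_equal(unlist(single$tau), c(only = 2))

  expect_error(aco_config(tau0 = 0), "tau0")
})

test_that("selection follows tau^alpha / sum(tau^alpha)", {
  sp <- aco_space(list(a = 1:4))
  cfg <- aco_config(alpha = 1)
  ph <- aco_init_pheromone(sp, cfg)
  expect_equal(aco_selection_probs(ph, cfg)[[1]], rep(0.25, 4))

  sp2 <- aco_space(list(a = 1:2))
  ph2 <- aco_init_pheromone(sp2, cfg)
  ph2$tau[[1]] <- c(3, 1)
  expect_equal(aco_selection_probs(ph2, cfg)[[1]], c(0.75, 0.25))
  # empirical frequencies over 1e5 seeded draws within +-0.01
  set.seed(42)
  hits <- 0L
  for (i in seq_len(1e5))
    hits <- hits + (aco_sample_solution(sp2, ph2, cfg)$choices[1] == 1L)
  expect_lt(abs(hits / 1e5 - 0.75), 0.01)

  # alpha = 2 reweights quadratically
  cfg2 <- aco_config(alpha = 2)
  expect_equal(aco_selection_probs(ph2, cfg2)[[1]], c(9, 1) / 10)

  # single-candidate layers are forced regardless of seed
  sp3 <- aco_space(list(a = list("x"), b = list("y")))
  ph3 <- aco_init_pheromone(sp3, cfg)
  expect_equal(aco_sample_solution(sp3, ph3, cfg)$choices, c(1L, 1L))
})

test_that("deposit is Q/(1+fitness), decreasing in the loss", {
  expect_equal(aco_deposit_amount(0, 1), 1.0)
  expect_equal(aco_deposit_amount(1, 1), 0.5)
  expect_equal(aco_deposit_amount(3, 2), 0.5)
  expect_equal(aco_deposit_amount(5, 0), 0)
  expect_equal(aco_deposit_amount(Inf, 1), 0)
  expect_error(aco_deposit_amount(-0.1, 1), "non-negative")
})

test_that("pheromone update evaporates, deposits on-path, floors at tau_min", {
  sp <- aco_space(list(a = 1:2, b = 1:2))
  cfg <- aco_config(rho = 0.5, tau_min = 1e-6)
  ph <- aco_init_pheromone(sp, cfg)
  best <- aco_solution(sp, c(1L, 2L), fitness = 0)
  ph2 <- aco_update_pheromone(ph, best, delta = 0.2, cfg)
  expect_equal(ph2$tau$a, c(0.7, 0.5))
  expect_equal(ph2$tau$b, c(0.5, 0.7))
  expect_identical(ph2$iteration, 1L)

  # pure evaporation with delta 0
  ph3 <- aco_update_pheromone(ph, best, delta = 0, cfg)
  expect_equal(unlist(ph3$tau), rep(0.5, 4), ignore_attr = TRUE)

  # rho = 1 evaporates fully; floor engages
  cfg1 <- aco_config(rho = 1, tau_min = 1e-6)
  ph4 <- aco_update_pheromone(ph, best, delta = 0, cfg1)
  expect_true(all(unlist(ph4$tau) == 1e-6))
})

test_that("trails stay within [tau_min, max(tau0, delta_max/rho)] over long runs", {
  sp <- aco_space(list(a = 1:3, b = 1:3))
  cfg <- aco_config(rho = 0.3, tau_min = 0.05, tau0 = 1, q_scale = 1)
  ph <- aco_init_pheromone(sp, cfg)
  set.seed(7)
  dmax <- 0
  for (i in 1:200) {
    best <- aco_solution(sp, sample.int(3, 2, replace = TRUE), fitness = runif(1, 0, 2))
    delta <- aco_deposit_amount(best$fitness, cfg$q_scale)
    dmax <- max(dmax, delta)
    ph <- aco_update_pheromone(ph, best, delta, cfg)
    expect_gte(min(unlist(ph$tau)), cfg$tau_min)
    expect_lte(max(unlist(ph$tau)), max(cfg$tau0, dmax / cfg$rho) + 1e-12)
  }
})

test_that("optimizer finds the enumerable optimum and keeps a monotone trace", {
  # 2x2 landscape with a unique minimum, checked against brute force
  tl <- toy_landscape("deceptive_2x2")
  bf <- brute_force_min(tl$space, tl$fitness_fn)
  expect_equal(bf, tl$min_fitness)
  hits <- 0L
  for (s in 0:19) {
    res <- aco_optimize(tl$space, tl$fitness_fn, aco_config(seed = s))
    expect_gte(res$best$fitness, bf)
    expect_true(all(diff(res$trace$best_so_far) <= 0))
    hits <- hits + (abs(res$best$fitness - bf) < 1e-12)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("constant fitness gives a flat trace and a valid solution", {
  tl <- toy_landscape("flat")
  res <- aco_optimize(tl$space, tl$fitness_fn, aco_config(seed = 1))
  expect_true(all(res$trace$best_fitness == 0.5))
  expect_true(all(res$trace$best_so_far == 0.5))
  expect_true(all(res$best$choices %in% 1:2))
  # patience stops the run well before max_iterations
  expect_lte(nrow(res$trace), aco_config()$patience + 1L)
})

test_that("identical seed and config reproduce the identical run", {
  tl <- toy_landscape("additive_4x5")
  r1 <- aco_optimize(tl$space, tl$fitness_fn, aco_config(seed = 123))
  r2 <- aco_optimize(tl$space, tl$fitness_fn, aco_config(seed = 123))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best, r2$best)
})

test_that("fitness function failures abort with the choices in context", {
  sp <- aco_space(list(a = 1:2))
  expect_error(
    aco_optimize(sp, function(sol) stop("boom"), aco_config(seed = 1)),
    "choices")
  expect_error(
    aco_optimize(sp, function(sol) -1, aco_config(seed = 1)),
    "non-negative")
})

test_that("trace exports as CSV with the documented columns", {
  tl <- toy_landscape("additive_4x5")
  res <- aco_optimize(tl$space, tl$fitness_fn, aco_config(seed = 5))
  path <- tempfile(fileext = ".csv")
  write_trace_csv(res$trace, path)
  got <- read.csv(path)
  expect_identical(names(got), c("iteration", "best_fitness", "best_so_far"))
  expect_equal(got$best_so_far, res$trace$best_so_far)
})
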