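test_that("the empty policy is the identity and flips are involutions", {
  img <- fixture_image(16)
  expect_identical(apply_policy(img, aug_policy(), seed = 1), img)

  pol <- aug_policy(list(flip_horizontal = TRUE))
  once <- apply_policy(img, pol, seed = 1)
  expect_false(identical(once, img))
  expect_equal(apply_policy(once, pol, seed = 1), img)
})

test_that("90-degree rotation permutes pixels exactly as the index map prescribes", {
  img <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)  # asymmetric 2x2
  rot <- rotate_image(img, 90)
  # counter-clockwise: (r, c) -> (W - c + 1, r)
  expected <- matrix(0, 2, 2)
  for (r in 1:2) for (c in 1:2) expected[2 - c + 1, r] <- img[r, c]
  expect_equal(rot, expected)
  # four quarter-turns restore the image
  out <- img
  for (i in 1:4) out <- rotate_image(out, 90)
  expect_equal(out, img)
})

test_that("off-grid rotation preserves shape, range, and is seed-deterministic", {
  img <- fixture_image(32)
  for (deg in c(-10, 5, 37)) {
    rot <- rotate_image(img, deg)
    expect_identical(dim(rot), dim(img))
    expect_gte(min(rot), 0)
    expect_lte(max(rot), 1)
  }
  pol <- aug_policy(list(rotate = 5, gauss_noise = 0.05))
  expect_identical(apply_policy(img, pol, seed = 9), apply_policy(img, pol, seed = 9))
  expect_false(identical(apply_policy(img, pol, seed = 9),
                         apply_policy(img, pol, seed = 10)))
})

test_that("every menu operator preserves shape and the [0,1] range", {
  img <- fixture_image(20)
  set.seed(4)
  for (op in default_augmentation_ops()) {
    for (v in op$values) {
      out <- op$fn(img, v)
      expect_identical(dim(out), dim(img))
      expect_gte(min(out), 0)
      expect_lte(max(out), 1)
    }
  }
})

test_that("policy complexity follows the additive cost model", {
  expect_equal(policy_complexity(aug_policy()), 0)
  # one op, cost weight 1, parameter at the grid's magnitude minimum -> 1.0
  expect_equal(policy_complexity(aug_policy(list(rotate = 5))), 1.0)
  # magnitude maximum -> 2.0
  expect_equal(policy_complexity(aug_policy(list(rotate = 90))), 2.0)
  # appending an op strictly increases complexity
  p1 <- aug_policy(list(rotate = 5))
  p2 <- aug_policy(list(rotate = 5, brightness = 0.1))
  expect_gt(policy_complexity(p2), policy_complexity(p1))
})

test_that("policy fitness is mean loss plus lambda times complexity", {
  ds <- oct_dataset(list(matrix(0.2, 8, 8), matrix(0.8, 8, 8)), c(1L, 2L),
                    c("a", "b"))
  # stub loss keyed on the sample's mean intensity
  loss_fn <- function(img, y) if (mean(img) < 0.5) 0.2 else 0.4
  f0 <- policy_fitness(aug_policy(), loss_fn, ds, lambda = 0, n_eval = 2, seed = 1)
  expect_equal(f0, 0.3)
  expect_equal(policy_fitness(aug_policy(), function(img, y) 0, ds,
                              lambda = 1, n_eval = 2, seed = 1), 0)
  # lambda = 1, complexity 2.0, mean loss 0.5 -> 2.5
  pol <- aug_policy(list(rotate = 90))
  f <- policy_fitness(pol, function(img, y) 0.5, ds, lambda = 1, n_eval = 2, seed = 1)
  expect_equal(f, 0.5 + 1 * policy_complexity(pol))
  # exact fitness decomposition F(W, lambda) = F(W, 0) + lambda * C(W)
  lf <- function(img, y) mean(img)
  fa <- policy_fitness(pol, lf, ds, lambda = 0.7, n_eval = 2, seed = 3)
  fb <- policy_fitness(pol, lf, ds, lambda = 0, n_eval = 2, seed = 3)
  expect_equal(fa, fb + 0.7 * policy_complexity(pol))
  expect_error(policy_fitness(aug_policy(), lf, ds, n_eval = 5), "n_eval")
})

test_that("policy search prefers augmentations that pay for their cost", {
  ds <- oct_dataset(replicate(4, fixture_image(16), simplify = FALSE),
                    rep(1:2, 2), c("a", "b"))
  menu <- default_augmentation_ops()["brightness"]
  # loss indifferent to augmentation, lambda > 0 -> everything off
  res <- search_augmentation_policy(menu, function(img, y) 0.5, ds,
                                    lambda = 0.1, n_eval = 4, seed = 1,
                                    aco_cfg = aco_config(seed = 1))
  expect_length(res$policy$steps, 0)
  # a parameter that strictly lowers the loss beyond its cost gets selected
  hits <- 0L
  for (s in 0:19) {
    res2 <- search_augmentation_policy(
      menu, function(img, y) if (mean(img) > 0.4) 0.1 else 1, ds,
      lambda = 0.01, n_eval = 4, seed = 1,
      aco_cfg = aco_config(seed = s))
    sel <- vapply(res2$policy$steps, function(st) st$param, numeric(1))
    hits <- hits + (length(sel) == 1 && sel == 0.2)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("policies round-trip through YAML", {
  pol <- aug_policy(list(rotate = -5, contrast = 1.2))
  path <- tempfile(fileext = ".yaml")
  write_policy_yaml(pol, path)
  back <- read_policy_yaml(path)
  expect_equal(policy_complexity(back), policy_complexity(pol))
  expect_setequal(vapply(back$steps, function(s) s$op$name, character(1)),
                  c("rotate", "contrast"))
})
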