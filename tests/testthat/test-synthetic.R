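test_that("generated scans are in range, seeded, and class-deterministic", {
  spec <- oct_spec(speckle_sigma = 0.05, seed = 1)
  for (cl in oct_classes()) {
    img <- generate_oct_like(cl, spec, seed = 42)
    expect_identical(dim(img), c(64L, 64L))
    expect_gte(min(img), 0); expect_lte(max(img), 1)
    expect_identical(img, generate_oct_like(cl, spec, seed = 42))
  }
  # noiseless Normal scans are pure deterministic band templates
  s0 <- oct_spec(speckle_sigma = 0)
  n1 <- generate_oct_like("Normal", s0, seed = 7)
  expect_identical(n1, generate_oct_like("Normal", s0, seed = 7))
  expect_false(identical(n1, generate_oct_like("Normal", s0, seed = 8)))
})

test_that("lesion overlays have the constructed sign inside their masks", {
  s0 <- oct_spec(speckle_sigma = 0)
  for (sd in c(3, 7, 21)) {
    nrm <- generate_oct_like("Normal", s0, seed = sd)
    dme <- generate_oct_like("DME", s0, seed = sd)
    cnv <- generate_oct_like("CNV", s0, seed = sd)
    # DME only darkens: difference <= 0 everywhere, strictly inside pockets
    expect_lte(max(dme - nrm), 0)
    expect_true(all((dme - nrm)[attr(dme, "mask")] < 0))
    expect_gt(sum(attr(dme, "mask")), 0)
    # CNV only brightens: difference >= 0, strictly inside the ellipse
    expect_gte(min(cnv - nrm), 0)
    expect_true(all((cnv - nrm)[attr(cnv, "mask")] > 0))
    # Drusen deforms the bottom boundary somewhere
    dru <- generate_oct_like("Drusen", s0, seed = sd)
    expect_gt(sum(attr(dru, "mask")), 0)
    expect_false(identical(dru, nrm))
  }
})

test_that("datasets honour requested counts, shuffling, and bitwise determinism", {
  spec <- oct_spec(counts = c(120, 40, 30, 90), seed = 5)
  ds <- generate_dataset(spec)
  expect_equal(unname(class_counts(ds)), c(120L, 40L, 30L, 90L))
  expect_identical(ds, generate_dataset(spec))
  # shuffled: not grouped by class
  expect_gt(length(rle(ds$labels)$lengths), 10)
})

test_that("the class ratio scales down within rounding", {
  ref <- c(37206, 11349, 8617, 26323)
  for (total in c(40, 83, 280, 1000)) {
    counts <- scaled_class_counts(total)
    expect_equal(sum(counts), total)
    expect_true(all(abs(counts - total * ref / sum(ref)) <= 1))
  }
})

test_that("a linear classifier separates the four classes on downsampled pixels", {
  ds <- generate_dataset(oct_spec(counts = c(120, 40, 30, 90),
                                  speckle_sigma = 0.05, seed = 3))
  sp <- stratified_split(ds$labels, 0.2, seed = 9)
  X <- t(vapply(ds$images, function(im)
    as.vector(octaco:::.downsample_for_nn(im, 32L)), numeric(32 * 32)))
  fit <- glmnet::glmnet(X[sp$train, ], factor(ds$labels[sp$train]),
                        family = "multinomial", lambda = 0.01)
  pred <- as.integer(predict(fit, X[sp$val, ], type = "class"))
  expect_gte(mean(pred == ds$labels[sp$val]), 0.9)
})

test_that("toy landscapes carry their certified optima", {
  # flat: all equal, argmin flagged non-unique
  fl <- toy_landscape("flat")
  expect_false(fl$argmin_unique)
  expect_equal(brute_force_min(fl$space, fl$fitness_fn), fl$min_fitness)

  # additive_4x5: exhaustive 625-config enumeration matches the stored argmin
  tl <- toy_landscape("additive_4x5")
  expect_equal(brute_force_min(tl$space, tl$fitness_fn), tl$min_fitness)
  expect_equal(tl$fitness_fn(aco_solution(tl$space, tl$argmin)), tl$min_fitness)
  # uniqueness: only one configuration attains the minimum
  sizes <- vapply(tl$space$layers, length, integer(1))
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  n_min <- sum(apply(grid, 1, function(ch)
    abs(tl$fitness_fn(aco_solution(tl$space, as.integer(ch))) - tl$min_fitness) < 1e-12))
  expect_equal(n_min, 1L)

  # deceptive_2x2: optimum off the greedy per-layer-marginal path
  dc <- toy_landscape("deceptive_2x2")
  expect_equal(brute_force_min(dc$space, dc$fitness_fn), dc$min_fitness)
  tab <- dc$table
  greedy <- c(which.min(rowMeans(tab)), which.min(colMeans(tab)))
  expect_false(identical(as.integer(greedy), dc$argmin))

  expect_error(toy_landscape("nope"))
})

test_that("informative feature fixtures separate classes only through the signal columns", {
  gen <- informative_features(n = 200, p = 50, k_informative = 5, seed = 2)
  expect_identical(gen$informative, 1:5)
  expect_identical(gen$x, informative_features(200, 50, 5, seed = 2)$x)
  split <- stratified_split(gen$y, 0.3, seed = 1)
  acc_of <- function(cols) {
    f <- glmnet::glmnet(gen$x[split$train, cols, drop = FALSE],
                        factor(gen$y[split$train]), family = "multinomial",
                        lambda = 0.01)
    mean(as.integer(predict(f, gen$x[split$val, cols, drop = FALSE],
                            type = "class")) == gen$y[split$val])
  }
  expect_gte(acc_of(1:5) - acc_of(6:50), 0.3)
  # k = p marks every feature informative
  expect_identical(informative_features(20, 3, 3, seed = 1)$informative, 1:3)
  expect_error(informative_features(20, 3, 4, seed = 1), "k_informative")
})
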