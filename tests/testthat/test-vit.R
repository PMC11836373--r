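tiny_cfg <- function(...) {
  vit_config(scales = c(4L, 8L), d = 8L, heads = 2L, blocks = 1L,
             window_radius = 1L, dense_neurons = 12L, n_classes = 4L,
             seed = 3, ...)
}

test_that("patch extraction tiles, pads by reflection, and reassembles", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  ep <- extract_patches(img, 4L)
  expect_equal(c(ep$rows, ep$cols), c(2L, 2L))
  expect_equal(nrow(ep$patches), 4L)
  # lossless: patches reassemble the padded image
  re <- matrix(0, 8, 8)
  for (gr in 1:2) for (gc in 1:2)
    re[(gr - 1) * 4 + 1:4, (gc - 1) * 4 + 1:4] <-
      matrix(ep$patches[(gr - 1) * 2 + gc, ], 4, 4)
  expect_equal(re, img)

  # 6x6 with patch 4 -> padded 8x8 matching an explicit reflect oracle
  img6 <- matrix(runif(36), 6, 6)
  ep6 <- extract_patches(img6, 4L)
  mirror <- function(n, m) {
    # reflect indices 1..m onto 1..n without repeating the edge sample
    i <- seq_len(m); p <- 2L * (n - 1L)
    j <- (i - 1L) %% p; ifelse(j >= n, p - j, j) + 1L
  }
  expect_equal(ep6$padded, img6[mirror(6, 8), mirror(6, 8)])

  # patch size equal to the image -> a single patch equal to the image
  ep1 <- extract_patches(img, 8L)
  expect_equal(nrow(ep1$patches), 1L)
  expect_equal(matrix(ep1$patches[1, ], 8, 8), img)
})

test_that("multi-scale embedding yields sum of per-scale token counts", {
  cfg <- vit_config(scales = c(4L, 8L), d = 16L, heads = 2L, blocks = 1L,
                    dense_neurons = 8L, seed = 1)
  m <- vit_init(cfg)
  emb <- embed_multiscale(m, matrix(0.5, 16, 16))
  expect_equal(nrow(emb[["4"]]$tokens), 16L)
  expect_equal(nrow(emb[["8"]]$tokens), 4L)
  expect_true(all(vapply(emb, function(e) ncol(e$tokens), integer(1)) == 16L))
  # a single scale the size of the image -> one token
  m1 <- vit_init(vit_config(scales = 16L, d = 8L, heads = 2L, blocks = 1L,
                            dense_neurons = 8L, seed = 1))
  expect_equal(nrow(embed_multiscale(m1, matrix(0.2, 16, 16))[["16"]]$tokens), 1L)
})

test_that("token neighbourhoods match exhaustive Chebyshev enumeration", {
  # interior token of a 4x4 grid with r = 1 -> full 3x3 window
  expect_length(token_neighborhood(6L, 4L, 4L, 1L), 9L)
  # brute-force oracle over all tokens and radii
  for (r in 0:2) {
    for (i in 1:16) {
      pos <- c((i - 1) %/% 4 + 1, (i - 1) %% 4 + 1)
      oracle <- which(vapply(1:16, function(j) {
        pj <- c((j - 1) %/% 4 + 1, (j - 1) %% 4 + 1)
        max(abs(pj - pos)) <= r
      }, logical(1)))
      expect_equal(token_neighborhood(i, 4L, 4L, r), oracle)
      expect_true(i %in% token_neighborhood(i, 4L, 4L, r))
    }
  }
  # radius covering the grid -> everything
  expect_length(token_neighborhood(1L, 4L, 4L, 4L), 16L)
})

test_that("attention pair counts match enumeration and the O(N k) bound", {
  oracle_pairs <- function(rows, cols, r)
    sum(vapply(seq_len(rows * cols), function(i)
      length(token_neighborhood(i, rows, cols, r)), integer(1)))
  expect_equal(count_attention_pairs(4L, 4L, 1L), 100L)
  expect_equal(count_attention_pairs(4L, 4L, 1L), oracle_pairs(4, 4, 1))
  expect_equal(count_attention_pairs(5L, 3L, 2L), oracle_pairs(5, 3, 2))
  expect_equal(count_attention_pairs(4L, 4L, 0L), 16L)   # self only
  expect_equal(count_attention_pairs(4L, 4L, 5L), 256L)  # dense
  # linear growth in token count at fixed r
  for (n in c(4, 8, 12))
    expect_lte(count_attention_pairs(n, n, 1L), n * n * 9L)
})

test_that("content weights normalize patch variance to [0,1]", {
  expect_equal(content_weights(matrix(0.3, 4, 16)), rep(0, 4))
  p <- rbind(rep(0.5, 4),                    # variance 0
             c(0.4, 0.6, 0.4, 0.6),         # variance 0.01
             c(0.3, 0.7, 0.3, 0.7))         # variance 0.04
  w <- content_weights(p)
  expect_equal(w, c(0, 0.25, 1))
  expect_equal(content_weights(p[2:3, , drop = FALSE]), c(0, 1))
})

test_that("windowed attention equals the dense oracle when the window covers the grid", {
  set.seed(11)
  tok <- matrix(rnorm(16 * 8), 16, 8)
  for (heads in c(1L, 2L, 4L)) {
    got <- windowed_attention(tok, 4L, 4L, r = 4L, heads = heads)
    expect_lt(max(abs(got - dense_attention_oracle(tok, heads))), 1e-5)
  }
  # identical keys -> uniform attention over the neighbourhood
  tok_const <- matrix(1, 9, 4)
  tok_const[5, ] <- 1  # keep keys identical
  out <- windowed_attention(tok_const, 3L, 3L, r = 1L, heads = 1L)
  expect_equal(out[1, ], tok_const[1, ])  # average of identical values
})

test_that("relative position bias depends only on the grid offset", {
  geom <- octaco:::vit_geometry(5L, 5L, 1L)
  # interior tokens translated by one grid cell see identical offset ids
  id_of <- function(i, j) geom$offid[i, j]
  # token 7 (row 2, col 2) vs token 13 (row 3, col 3): same relative pattern
  n7 <- token_neighborhood(7L, 5L, 5L, 1L)
  n13 <- token_neighborhood(13L, 5L, 5L, 1L)
  expect_equal(vapply(n7, function(j) id_of(7L, j), integer(1)),
               vapply(n13, function(j) id_of(13L, j), integer(1)))
})

test_that("forward pass returns valid, finite, deterministic probabilities", {
  m <- vit_init(tiny_cfg())
  img <- fixture_image(16)
  p <- vit_forward(m, img)
  expect_length(p, 4L)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(p, vit_forward(m, img))          # bitwise repeatable
  expect_true(all(is.finite(vit_forward(m, matrix(0, 16, 16)))))
  expect_true(all(is.finite(vit_forward(m, matrix(1, 16, 16)))))

  # zeroed final layer -> exactly uniform probabilities
  m0 <- m
  m0$params$head_Wout[] <- 0
  m0$params$head_bout[] <- 0
  expect_identical(vit_forward(m0, img), rep(0.25, 4))
})

test_that("analytic gradients match central finite differences", {
  cfg <- vit_config(scales = c(4L, 8L), d = 8L, heads = 2L, blocks = 2L,
                    window_radius = 1L, dense_neurons = 10L, n_classes = 3L,
                    seed = 2)
  m <- vit_init(cfg)
  set.seed(5)
  img <- matrix(runif(64), 8, 8)
  y <- 2L
  w <- c(0.5, 2, 1)
  fw <- octaco:::vit_forward_full(m, img, keep = TRUE)
  g <- octaco:::vit_backward(m, fw, y, w)
  lossfn <- function(model) octaco:::.sample_loss(vit_forward(model, img), y, w)
  eps <- 1e-6
  for (nm in names(m$params)) {
    P <- m$params[[nm]]
    idxs <- if (length(P) > 4) sample(length(P), 4) else seq_along(P)
    for (i in idxs) {
      mp <- m; mp$params[[nm]][i] <- P[i] + eps
      mm <- m; mm$params[[nm]][i] <- P[i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]),
                1e-4 * max(1, abs(num)))
    }
  }
})

test_that("a few Adam steps reduce the training loss on a toy task", {
  set.seed(9)
  imgs <- c(replicate(6, matrix(runif(64, 0, 0.3), 8, 8), simplify = FALSE),
            replicate(6, matrix(runif(64, 0.7, 1), 8, 8), simplify = FALSE))
  ds <- oct_dataset(imgs, rep(1:2, each = 6), c("dark", "bright"))
  m <- vit_init(vit_config(scales = c(4L, 8L), d = 8L, heads = 2L, blocks = 1L,
                           dense_neurons = 8L, n_classes = 2L, seed = 1))
  fit <- vit_train(m, ds, epochs = 8L, batch_size = 6L, lr = 3e-3, seed = 2)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  probs <- vit_predict(fit$model, ds$images)
  expect_equal(dim(probs), c(12L, 2L))
  expect_gte(mean(max.col(probs) == ds$labels), 0.8)
  # epochs = 0 leaves the model untouched
  fit0 <- vit_train(m, ds, epochs = 0L)
  expect_identical(fit0$model$params, m$params)
})
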