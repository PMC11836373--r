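# Independent oracles used across the suite; deliberately naive
# implementations, kept separate from the package's own code paths.

# dense multi-head self-attention with Q = K = V = tokens, no projections
dense_attention_oracle <- function(X, heads = 1L) {
  d <- ncol(X)
  dh <- d %/% heads
  out <- matrix(0, nrow(X), d)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    S <- X[, idx, drop = FALSE] %*% t(X[, idx, drop = FALSE]) / sqrt(dh)
    A <- exp(S - apply(S, 1L, max))
    A <- A / rowSums(A)
    out[, idx] <- A %*% X[, idx, drop = FALSE]
  }
  out
}

# per-class metrics computed scalar-by-scalar from first principles
brute_force_metrics <- function(cm) {
  C <- nrow(cm)
  prec <- rec <- f1 <- numeric(C)
  for (c in seq_len(C)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) 2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  list(accuracy = sum(diag(cm)) / sum(cm),
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

# enumerate every configuration of a small aco_space and return the
# minimum fitness (brute force)
brute_force_min <- function(space, fitness_fn) {
  sizes <- vapply(space$layers, length, integer(1))
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    sol <- aco_solution(space, as.integer(grid[i, ]))
    best <- min(best, fitness_fn(sol))
  }
  best
}

# small deterministic test image with structure (bands + a bright spot)
fixture_image <- function(n = 64L, seed = 1L) {
  set.seed(seed)
  img <- matrix(stats::runif(n * n, 0, 0.2), n, n)
  img[(n %/% 4):(n %/% 2), ] <- img[(n %/% 4):(n %/% 2), ] + 0.5
  pmin(img, 1)
}
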