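# Modified Vision Transformer for grayscale B-scans:
#   * multi-scale patch embedding (one token grid per patch size),
#   * windowed multi-head self-attention with a learnable relative
#     positional bias P(offset) and a content-aware additive logit bias
#     gamma * g(x_j) (g = per-patch pixel variance, min-max normalized),
#   * pre-LN residual blocks shared across scales; scales are fused by
#     concatenating mean-pooled per-scale summaries before the dense head.
#
# Attention within a window of Chebyshev radius r is computed as dense
# attention under a -Inf mask: numerically identical to restricting each
# token to its neighbourhood N(i), with the O(N * k) pair count reported by
# count_attention_pairs().

#' Model configuration
#'
#' @param scales integer patch sizes, one token grid per scale.
#' @param d embedding dimension (divisible by `heads`).
#' @param heads attention heads.
#' @param blocks encoder blocks.
#' @param window_radius Chebyshev window radius `r` on the token grid.
#' @param dense_neurons width of the penultimate dense layer.
#' @param n_classes output classes.
#' @param content_gain initial value of the learnable content-weighting
#'   gain `gamma`.
#' @param ff_mult feed-forward expansion factor (hidden width = `ff_mult * d`).
#' @param seed seed for parameter initialization.
#' @return a `vit_config` object.
#' @export
vit_config <- function(scales = c(8L, 16L), d = 64L, heads = 4L, blocks = 2L,
                       window_radius = 1L, dense_neurons = 512L,
                       n_classes = 4L, content_gain = 1, ff_mult = 2L,
                       seed = 1L) {
  cfg <- list(scales = as.integer(scales), d = as.integer(d),
              heads = as.integer(heads), blocks = as.integer(blocks),
              window_radius = as.integer(window_radius),
              dense_neurons = as.integer(dense_neurons),
              n_classes = as.integer(n_classes),
              content_gain = content_gain, ff_mult = as.integer(ff_mult),
              seed = seed)
  if (length(cfg$scales) < 1L || any(cfg$scales < 1L)) stopf("invalid scales")
  if (cfg$d %% cfg$heads != 0L) stopf("d must be divisible by heads")
  if (cfg$n_classes < 2L) stopf("n_classes must be >= 2")
  if (cfg$window_radius < 0L) stopf("window_radius must be >= 0")
  structure(cfg, class = "vit_config")
}

#' Split an image into non-overlapping patches
#'
#' The image is reflect-padded up to whole multiples of the patch size;
#' patches are enumerated row-major from the top-left and flattened
#' column-major, so they reassemble the padded image losslessly.
#'
#' @param image numeric matrix.
#' @param patch patch side length (square patches).
#' @return list with `patches` (token_count x patch^2 matrix), `rows`,
#'   `cols` (token-grid extents) and `padded` (the padded image).
#' @export
extract_patches <- function(image, patch) {
  patch <- as.integer(patch)
  if (patch < 1L) stopf("patch size must be positive")
  H <- nrow(image); W <- ncol(image)
  rows <- ceiling(H / patch); cols <- ceiling(W / patch)
  padded <- image[reflect_index(seq_len(rows * patch), H),
                  reflect_index(seq_len(cols * patch), W), drop = FALSE]
  n <- rows * cols
  P <- matrix(0, n, patch * patch)
  for (gr in seq_len(rows)) {
    for (gc in seq_len(cols)) {
      blk <- padded[(gr - 1L) * patch + seq_len(patch),
                    (gc - 1L) * patch + seq_len(patch), drop = FALSE]
      P[(gr - 1L) * cols + gc, ] <- as.vector(blk)
    }
  }
  list(patches = P, rows = rows, cols = cols, padded = padded)
}

#' Windowed neighbourhood of a token
#'
#' All same-scale tokens within Chebyshev distance `r` on the token grid,
#' always including the token itself.
#'
#' @param i token index (row-major, 1-based).
#' @param rows,cols token-grid extents.
#' @param r window radius.
#' @return sorted integer vector of neighbour token indices.
#' @export
token_neighborhood <- function(i, rows, cols, r) {
  if (i < 1L || i > rows * cols) stopf("token index out of range")
  ri <- (i - 1L) %/% cols + 1L
  ci <- (i - 1L) %% cols + 1L
  rr <- max(1L, ri - r):min(rows, ri + r)
  cc <- max(1L, ci - r):min(cols, ci + r)
  sort(as.vector(outer(rr - 1L, cc, function(a, b) a * cols + b)))
}

# window geometry (mask + relative-offset ids) cached per (rows, cols, r)
.vit_geom_cache <- new.env(parent = emptyenv())

vit_geometry <- function(rows, cols, r) {
  key <- paste(rows, cols, r, sep = "_")
  g <- .vit_geom_cache[[key]]
  if (!is.null(g)) return(g)
  n <- rows * cols
  gr <- (seq_len(n) - 1L) %/% cols + 1L
  gc <- (seq_len(n) - 1L) %% cols + 1L
  dr <- outer(gr, gr, `-`)
  dc <- outer(gc, gc, `-`)
  mask <- abs(dr) <= r & abs(dc) <= r
  side <- 2L * r + 1L
  offid <- matrix(NA_integer_, n, n)
  offid[mask] <- (dr[mask] + r) * side + (dc[mask] + r) + 1L
  g <- list(mask = mask, offid = offid, n = n, n_offsets = side * side,
            in_idx = which(mask))
  g$col_of_in <- ((g$in_idx - 1L) %/% n) + 1L  # column (j) of in-window entries
  .vit_geom_cache[[key]] <- g
  g
}

#' Total attended token pairs under a windowed scheme
#'
#' `sum_i |N(i)|` for a rows x cols grid with Chebyshev radius `r`; always
#' `<= token_count * (2r+1)^2`, versus `token_count^2` for dense attention.
#'
#' @inheritParams token_neighborhood
#' @return integer pair count.
#' @export
count_attention_pairs <- function(rows, cols, r) {
  wr <- vapply(seq_len(rows), function(i)
    min(rows, i + r) - max(1L, i - r) + 1L, numeric(1))
  wc <- vapply(seq_len(cols), function(j)
    min(cols, j + r) - max(1L, j - r) + 1L, numeric(1))
  as.integer(sum(wr) * sum(wc) / 1)  # separable: sum_i wr * sum_j wc
}

#' Content weights of a patch set
#'
#' Per-patch pixel variance, min-max normalized over the image's patches:
#' the flattest patch maps to 0, the most textured to 1; if all variances
#' are equal (e.g. a constant image) every weight is 0.
#'
#' @param patches token_count x patch_len matrix (rows = flattened patches).
#' @return numeric vector of weights in `[0, 1]`.
#' @export
content_weights <- function(patches) {
  v <- pmax(rowMeans(patches^2) - rowMeans(patches)^2, 0)
  rng <- range(v)
  if (diff(rng) <= 0) return(rep(0, length(v)))
  (v - rng[1]) / diff(rng)
}

# layer norm over the feature dimension, rowwise
ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, `*`)
  Y <- sweep(Y, 2L, b, `+`)
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

rowwise_softmax_masked <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)  # exp(-Inf) = 0 handles out-of-window entries
  E / rowSums(E)
}

# multi-head attention core on explicit Q, K, V (N x d); relpos is a
# heads x n_offsets matrix (or NULL for zero bias); g a length-N content
# weight vector (or NULL)
attention_core <- function(Q, K, V, geom, heads, relpos = NULL, g = NULL,
                           gamma = 0) {
  n <- nrow(Q); d <- ncol(Q); dh <- d %/% heads
  out <- matrix(0, n, d)
  A_list <- vector("list", heads)
  gbias <- if (!is.null(g) && gamma != 0)
    matrix(gamma * g, n, n, byrow = TRUE) else NULL
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(relpos)) {
      B <- matrix(0, n, n)
      B[geom$in_idx] <- relpos[h, geom$offid[geom$in_idx]]
      S <- S + B
    }
    if (!is.null(gbias)) S <- S + gbias
    S[!geom$mask] <- -Inf
    A <- rowwise_softmax_masked(S)
    out[, idx] <- A %*% V[, idx, drop = FALSE]
    A_list[[h]] <- A
  }
  list(out = out, A = A_list)
}

#' Windowed multi-head self-attention (stand-alone)
#'
#' Applies windowed attention directly on the given tokens (queries, keys
#' and values all equal the tokens; no learned projections), with optional
#' relative positional bias and content bias. With a window covering the
#' whole grid, zero positional bias and `gamma = 0`, this reduces exactly
#' to dense self-attention.
#'
#' @param tokens N x d token matrix (N = rows * cols).
#' @param rows,cols token-grid extents.
#' @param r window radius.
#' @param heads attention heads (`d` divisible by `heads`).
#' @param relpos optional heads x (2r+1)^2 positional-bias table.
#' @param g optional length-N content weights.
#' @param gamma content-bias gain.
#' @return N x d matrix of attended tokens.
#' @export
windowed_attention <- function(tokens, rows, cols, r, heads = 1L,
                               relpos = NULL, g = NULL, gamma = 0) {
  if (nrow(tokens) != rows * cols) stopf("tokens must have rows*cols rows")
  if (ncol(tokens) %% heads != 0L) stopf("d must be divisible by heads")
  if (!is.null(g) && length(g) != nrow(tokens))
    stopf("g must have one weight per token")
  geom <- vit_geometry(rows, cols, r)
  if (!is.null(relpos) && ncol(relpos) != geom$n_offsets)
    stopf("relpos must have (2r+1)^2 columns")
  attention_core(tokens, tokens, tokens, geom, heads, relpos, g, gamma)$out
}

.xavier <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize model parameters
#'
#' Xavier-normal weights, zero biases, zero relative-position tables (so a
#' fresh model's windowed attention matches the dense oracle exactly when
#' `gamma = 0`), unit layer-norm gains.
#'
#' @param config a [vit_config()].
#' @return a `vit_model` (flat named parameter list + config).
#' @export
vit_init <- function(config = vit_config()) {
  with_seed(config$seed, {
    d <- config$d
    side <- 2L * config$window_radius + 1L
    p <- list()
    for (s in config$scales) {
      key <- as.character(s)
      p[[paste0("emb_W_", key)]] <- .xavier(s * s, d)
      p[[paste0("emb_b_", key)]] <- numeric(d)
      p[[paste0("emb_scale_", key)]] <- stats::rnorm(d, sd = 0.02)
    }
    for (b in seq_len(config$blocks)) {
      pre <- paste0("blk", b, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- numeric(d)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- .xavier(d, d)
      for (w in c("bq", "bk", "bv", "bo")) p[[paste0(pre, w)]] <- numeric(d)
      p[[paste0(pre, "relpos")]] <- matrix(0, config$heads, side * side)
      p[[paste0(pre, "gamma")]] <- config$content_gain
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- .xavier(d, config$ff_mult * d)
      p[[paste0(pre, "b1")]] <- numeric(config$ff_mult * d)
      p[[paste0(pre, "W2")]] <- .xavier(config$ff_mult * d, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
    }
    p[["lnf_g"]] <- rep(1, d)
    p[["lnf_b"]] <- numeric(d)
    p[["head_Wd"]] <- .xavier(d * length(config$scales), config$dense_neurons)
    p[["head_bd"]] <- numeric(config$dense_neurons)
    p[["head_Wout"]] <- .xavier(config$dense_neurons, config$n_classes)
    p[["head_bout"]] <- numeric(config$n_classes)
    structure(list(params = p, config = config), class = "vit_model")
  })
}

#' Multi-scale patch embeddings of one image
#'
#' Per scale: flattened patches projected linearly to dimension `d`, plus
#' a learned per-scale embedding vector added to every token of the scale.
#'
#' @param model a `vit_model`.
#' @param image numeric matrix in `[0, 1]`.
#' @return named list per scale: `tokens` (N_s x d), `rows`, `cols`,
#'   `g` (content weights), `patches`.
#' @export
embed_multiscale <- function(model, image) {
  p <- model$params
  out <- list()
  for (s in model$config$scales) {
    key <- as.character(s)
    ep <- extract_patches(image, s)
    tok <- ep$patches %*% p[[paste0("emb_W_", key)]]
    tok <- sweep(tok, 2L, p[[paste0("emb_b_", key)]] +
                   p[[paste0("emb_scale_", key)]], `+`)
    out[[key]] <- list(tokens = tok, rows = ep$rows, cols = ep$cols,
                       g = content_weights(ep$patches), patches = ep$patches)
  }
  out
}

# full forward pass; keep = TRUE retains every intermediate needed by the
# backward pass in vit_backward()
vit_forward_full <- function(model, image, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  emb <- embed_multiscale(model, image)
  S <- length(cfg$scales)
  pooled <- numeric(0)
  caches <- list()
  for (key in names(emb)) {
    e <- emb[[key]]
    geom <- vit_geometry(e$rows, e$cols, cfg$window_radius)
    X <- e$tokens
    blk_caches <- list()
    for (b in seq_len(cfg$blocks)) {
      pre <- paste0("blk", b, "_")
      l1 <- ln_forward(X, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
      Q <- sweep(l1$Y %*% p[[paste0(pre, "Wq")]], 2L, p[[paste0(pre, "bq")]], `+`)
      K <- sweep(l1$Y %*% p[[paste0(pre, "Wk")]], 2L, p[[paste0(pre, "bk")]], `+`)
      V <- sweep(l1$Y %*% p[[paste0(pre, "Wv")]], 2L, p[[paste0(pre, "bv")]], `+`)
      att <- attention_core(Q, K, V, geom, cfg$heads,
                            relpos = p[[paste0(pre, "relpos")]],
                            g = e$g, gamma = p[[paste0(pre, "gamma")]])
      attn_out <- sweep(att$out %*% p[[paste0(pre, "Wo")]], 2L,
                        p[[paste0(pre, "bo")]], `+`)
      X1 <- X + attn_out
      l2 <- ln_forward(X1, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
      A1 <- sweep(l2$Y %*% p[[paste0(pre, "W1")]], 2L, p[[paste0(pre, "b1")]], `+`)
      H1 <- pmax(A1, 0)
      FF <- sweep(H1 %*% p[[paste0(pre, "W2")]], 2L, p[[paste0(pre, "b2")]], `+`)
      X2 <- X1 + FF
      if (keep)
        blk_caches[[b]] <- list(X = X, l1 = l1, Q = Q, K = K, V = V, att = att,
                                X1 = X1, l2 = l2, A1 = A1, H1 = H1)
      X <- X2
    }
    lf <- ln_forward(X, p[["lnf_g"]], p[["lnf_b"]])
    pooled <- c(pooled, colMeans(lf$Y))
    if (keep)
      caches[[key]] <- list(emb = e, geom = geom, blocks = blk_caches,
                            X_final = X, lf = lf)
  }
  a1 <- as.vector(pooled %*% p[["head_Wd"]]) + p[["head_bd"]]
  h1 <- pmax(a1, 0)
  logits <- as.vector(h1 %*% p[["head_Wout"]]) + p[["head_bout"]]
  z <- logits - max(logits)
  probs <- exp(z) / sum(exp(z))
  res <- list(probs = probs, logits = logits)
  if (keep) {
    res$caches <- caches
    res$pooled <- pooled
    res$a1 <- a1
    res$h1 <- h1
  }
  res
}

#' Class probabilities for one image
#'
#' Full forward pass: multi-scale embedding, windowed-attention encoder
#' blocks, mean pooling per scale, dense head, softmax.
#'
#' @param model a `vit_model`.
#' @param image numeric matrix in `[0, 1]`.
#' @return numeric probability vector of length `n_classes` (sums to 1).
#' @export
vit_forward <- function(model, image) {
  vit_forward_full(model, image, keep = FALSE)$probs
}

#' Class probabilities for a list of images
#'
#' @param model a `vit_model`.
#' @param images list of numeric matrices.
#' @return n x n_classes probability matrix.
#' @export
vit_predict <- function(model, images) {
  t(vapply(images, function(im) vit_forward(model, im),
           numeric(model$config$n_classes)))
}
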