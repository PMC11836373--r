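# Analytic backpropagation and Adam training for the modified ViT.
# Gradients are derived per sample from the caches of vit_forward_full()
# and accumulated over the minibatch; the loss is (optionally weighted)
# categorical cross-entropy.

.zero_like <- function(params) lapply(params, function(p) p * 0)

# gradient of w_y * (-log softmax(logits)[y]) wrt logits
.ce_grad_logits <- function(probs, y, w) {
  d <- probs * w
  d[y] <- d[y] - w
  d
}

# backward for one sample; fw = vit_forward_full(..., keep = TRUE)
vit_backward <- function(model, fw, y, class_w = NULL) {
  cfg <- model$config
  p <- model$params
  w <- if (is.null(class_w)) 1 else class_w[y]
  g <- .zero_like(p)

  dlogits <- .ce_grad_logits(fw$probs, y, w)
  g[["head_bout"]] <- g[["head_bout"]] + dlogits
  g[["head_Wout"]] <- g[["head_Wout"]] + outer(fw$h1, dlogits)
  dh1 <- as.vector(p[["head_Wout"]] %*% dlogits)
  da1 <- dh1 * (fw$a1 > 0)
  g[["head_bd"]] <- g[["head_bd"]] + da1
  g[["head_Wd"]] <- g[["head_Wd"]] + outer(fw$pooled, da1)
  dpooled <- as.vector(p[["head_Wd"]] %*% da1)

  d <- cfg$d
  dh <- d %/% cfg$heads
  offset <- 0L
  for (key in names(fw$caches)) {
    cache <- fw$caches[[key]]
    geom <- cache$geom
    n <- geom$n
    dpool_s <- dpooled[offset + seq_len(d)]
    offset <- offset + d
    # mean pool -> every token row gets dpool_s / n
    dYf <- matrix(dpool_s / n, n, d, byrow = TRUE)
    lb <- ln_backward(dYf, cache$lf, p[["lnf_g"]])
    g[["lnf_g"]] <- g[["lnf_g"]] + lb$dgamma
    g[["lnf_b"]] <- g[["lnf_b"]] + lb$dbeta
    dX <- lb$dX
    for (b in rev(seq_len(cfg$blocks))) {
      pre <- paste0("blk", b, "_")
      bc <- cache$blocks[[b]]
      # feed-forward branch
      dFF <- dX
      g[[paste0(pre, "b2")]] <- g[[paste0(pre, "b2")]] + colSums(dFF)
      g[[paste0(pre, "W2")]] <- g[[paste0(pre, "W2")]] + crossprod(bc$H1, dFF)
      dH1 <- dFF %*% t(p[[paste0(pre, "W2")]])
      dA1 <- dH1 * (bc$A1 > 0)
      g[[paste0(pre, "b1")]] <- g[[paste0(pre, "b1")]] + colSums(dA1)
      g[[paste0(pre, "W1")]] <- g[[paste0(pre, "W1")]] + crossprod(bc$l2$Y, dA1)
      dY2 <- dA1 %*% t(p[[paste0(pre, "W1")]])
      lb2 <- ln_backward(dY2, bc$l2, p[[paste0(pre, "ln2_g")]])
      g[[paste0(pre, "ln2_g")]] <- g[[paste0(pre, "ln2_g")]] + lb2$dgamma
      g[[paste0(pre, "ln2_b")]] <- g[[paste0(pre, "ln2_b")]] + lb2$dbeta
      dX1 <- dX + lb2$dX
      # attention branch
      dAttnOut <- dX1
      g[[paste0(pre, "bo")]] <- g[[paste0(pre, "bo")]] + colSums(dAttnOut)
      g[[paste0(pre, "Wo")]] <- g[[paste0(pre, "Wo")]] +
        crossprod(bc$att$out, dAttnOut)
      dOcat <- dAttnOut %*% t(p[[paste0(pre, "Wo")]])
      dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
      gvec <- cache$emb$g
      for (h in seq_len(cfg$heads)) {
        idx <- (h - 1L) * dh + seq_len(dh)
        A <- bc$att$A[[h]]
        dO_h <- dOcat[, idx, drop = FALSE]
        dA <- tcrossprod(dO_h, bc$V[, idx, drop = FALSE])  # dO V^T
        dV[, idx] <- crossprod(A, dO_h)
        dS <- A * (dA - rowSums(dA * A))
        dQ[, idx] <- dS %*% bc$K[, idx, drop = FALSE] / sqrt(dh)
        dK[, idx] <- crossprod(dS, bc$Q[, idx, drop = FALSE]) / sqrt(dh)
        # relative positional bias: accumulate dS over equal offsets
        ds_in <- dS[geom$in_idx]
        tab <- rowsum(ds_in, geom$offid[geom$in_idx])
        acc <- numeric(geom$n_offsets)
        acc[as.integer(rownames(tab))] <- tab[, 1]
        g[[paste0(pre, "relpos")]][h, ] <- g[[paste0(pre, "relpos")]][h, ] + acc
        # content gain: sum_ij dS[i,j] * g[j]
        g[[paste0(pre, "gamma")]] <- g[[paste0(pre, "gamma")]] +
          sum(colSums(dS) * gvec)
      }
      dY1 <- dQ %*% t(p[[paste0(pre, "Wq")]]) +
        dK %*% t(p[[paste0(pre, "Wk")]]) +
        dV %*% t(p[[paste0(pre, "Wv")]])
      g[[paste0(pre, "bq")]] <- g[[paste0(pre, "bq")]] + colSums(dQ)
      g[[paste0(pre, "bk")]] <- g[[paste0(pre, "bk")]] + colSums(dK)
      g[[paste0(pre, "bv")]] <- g[[paste0(pre, "bv")]] + colSums(dV)
      g[[paste0(pre, "Wq")]] <- g[[paste0(pre, "Wq")]] + crossprod(bc$l1$Y, dQ)
      g[[paste0(pre, "Wk")]] <- g[[paste0(pre, "Wk")]] + crossprod(bc$l1$Y, dK)
      g[[paste0(pre, "Wv")]] <- g[[paste0(pre, "Wv")]] + crossprod(bc$l1$Y, dV)
      lb1 <- ln_backward(dY1, bc$l1, p[[paste0(pre, "ln1_g")]])
      g[[paste0(pre, "ln1_g")]] <- g[[paste0(pre, "ln1_g")]] + lb1$dgamma
      g[[paste0(pre, "ln1_b")]] <- g[[paste0(pre, "ln1_b")]] + lb1$dbeta
      dX <- dX1 + lb1$dX
    }
    # embedding
    skey <- key
    g[[paste0("emb_W_", skey)]] <- g[[paste0("emb_W_", skey)]] +
      crossprod(cache$emb$patches, dX)
    g[[paste0("emb_b_", skey)]] <- g[[paste0("emb_b_", skey)]] + colSums(dX)
    g[[paste0("emb_scale_", skey)]] <- g[[paste0("emb_scale_", skey)]] +
      colSums(dX)
  }
  g
}

# per-sample weighted cross-entropy loss
.sample_loss <- function(probs, y, class_w = NULL) {
  w <- if (is.null(class_w)) 1 else class_w[y]
  w * (-log(max(probs[y], 1e-12)))
}

#' Train the model with Adam
#'
#' Minimizes (optionally class-weighted) categorical cross-entropy by
#' minibatch gradient descent with Adam. Fully deterministic given `seed`.
#'
#' @param model a `vit_model` from [vit_init()].
#' @param dataset an [oct_dataset()] used for training.
#' @param epochs epoch budget (0 returns the model untouched).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param class_w optional per-class loss weights (see [class_weights()]).
#' @param seed seed controlling epoch shuffles.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param verbose print per-epoch mean training loss.
#' @return list with `model` (trained) and `history` (data frame of epoch
#'   and mean training loss).
#' @export
vit_train <- function(model, dataset, epochs = 10L, batch_size = 32L,
                      lr = 1e-3, class_w = NULL, seed = 1L,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      verbose = FALSE) {
  stopifnot(inherits(model, "vit_model"), inherits(dataset, "oct_dataset"))
  n <- length(dataset$labels)
  if (epochs == 0L || n == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(0), loss = numeric(0))))
  m_state <- .zero_like(model$params)
  v_state <- .zero_like(model$params)
  step <- 0L
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1L, n)]
        grads <- .zero_like(model$params)
        bl <- 0
        for (i in batch) {
          fw <- vit_forward_full(model, dataset$images[[i]], keep = TRUE)
          y <- dataset$labels[i]
          bl <- bl + .sample_loss(fw$probs, y, class_w)
          gi <- vit_backward(model, fw, y, class_w)
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + gi[[nm]]
        }
        nb <- length(batch)
        step <- step + 1L
        bc1 <- 1 - beta1^step
        bc2 <- 1 - beta2^step
        for (nm in names(grads)) {
          gmean <- grads[[nm]] / nb
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * gmean
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * gmean^2
          model$params[[nm]] <- model$params[[nm]] -
            lr * (m_state[[nm]] / bc1) / (sqrt(v_state[[nm]] / bc2) + eps)
        }
        losses <- c(losses, bl / nb)
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, history[ep]))
    }
  })
  list(model = model, history = data.frame(epoch = seq_len(epochs),
                                           loss = history))
}
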