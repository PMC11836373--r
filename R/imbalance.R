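# Class-imbalance mitigation: SMOTE oversampling plus inverse-frequency
# weighted categorical cross-entropy. The two are complementary: SMOTE
# rebalances the sample counts by interpolating between same-class
# neighbours; the weighted loss penalizes minority-class mistakes harder
# during training.

# bilinear downsample used only for neighbour search (speed); interpolation
# happens at full resolution between the chosen parents
.downsample_for_nn <- function(img, target = 64L) {
  H <- nrow(img); W <- ncol(img)
  if (H <= target && W <= target) return(img)
  th <- min(H, target); tw <- min(W, target)
  ry <- seq(1, H, length.out = th)
  rx <- seq(1, W, length.out = tw)
  y0 <- floor(ry); y1 <- pmin(y0 + 1, H); fy <- ry - y0
  x0 <- floor(rx); x1 <- pmin(x0 + 1, W); fx <- rx - x0
  a <- img[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    img[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    img[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    img[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

#' SMOTE oversampling of minority classes
#'
#' For each class below its target count, synthesizes new samples by convex
#' interpolation `x_new = x_i + u * (x_nn - x_i)` with `u ~ Uniform(0,1)`,
#' where `x_nn` is one of the `k` nearest same-class neighbours of a
#' randomly chosen original `x_i` (Euclidean distance on flattened,
#' bilinearly downsampled pixels; interpolation at full resolution).
#' Originals are preserved untouched; synthetic samples carry
#' `synthetic = TRUE`.
#'
#' @param dataset an [oct_dataset()].
#' @param k_neighbors neighbour count `k` (clamped to class size - 1).
#' @param target `"majority"` (raise every class to the largest class
#'   count) or an integer vector of per-class target counts.
#' @param seed integer seed.
#' @return the resampled [oct_dataset()].
#' @export
smote_resample <- function(dataset, k_neighbors = 5L, target = "majority",
                           seed = 1L) {
  stopifnot(inherits(dataset, "oct_dataset"))
  counts <- class_counts(dataset)
  C <- length(counts)
  if (identical(target, "majority")) {
    target_counts <- rep(max(counts), C)
  } else {
    target_counts <- as.integer(target)
    if (length(target_counts) != C) stopf("target must have one count per class")
  }
  if (any(target_counts < counts))
    stopf("target counts must be >= current counts (no undersampling)")
  with_seed(seed, {
    new_images <- list(); new_labels <- integer(0)
    for (c in seq_len(C)) {
      need <- target_counts[c] - counts[c]
      if (need == 0L) next
      idx <- which(dataset$labels == c & !dataset$synthetic)
      if (length(idx) < 2L)
        stopf("class '%s' has %d sample(s); SMOTE needs at least 2",
              dataset$class_names[c], length(idx))
      k <- min(k_neighbors, length(idx) - 1L)
      flat <- t(vapply(dataset$images[idx],
                       function(im) as.vector(.downsample_for_nn(im)),
                       numeric(length(.downsample_for_nn(dataset$images[[idx[1]]])))))
      D <- as.matrix(stats::dist(flat))
      nn <- lapply(seq_along(idx), function(i) {
        ord <- order(D[i, ])
        ord[ord != i][seq_len(k)]
      })
      for (s in seq_len(need)) {
        i <- sample.int(length(idx), 1L)
        j <- nn[[i]][sample.int(k, 1L)]
        u <- stats::runif(1L)
        xi <- dataset$images[[idx[i]]]
        xj <- dataset$images[[idx[j]]]
        new_images[[length(new_images) + 1L]] <- xi + u * (xj - xi)
        new_labels <- c(new_labels, c)
      }
    }
    oct_dataset(c(dataset$images, new_images),
                c(dataset$labels, new_labels),
                dataset$class_names,
                c(dataset$synthetic, rep(TRUE, length(new_labels))))
  })
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (C * N_c)`: balanced counts give all-ones, and
#' `sum(w_c * N_c) = N_total` always.
#'
#' @param counts per-class sample counts (all `>= 1`).
#' @return numeric vector of positive class weights.
#' @export
class_weights <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 1)) stopf("every class count must be >= 1")
  sum(counts) / (length(counts) * counts)
}

#' Weighted categorical cross-entropy
#'
#' `(1/n) * sum_i w[y_i] * (-log p_i[y_i])` with probabilities clipped to
#' `[1e-12, 1]` before the log. With unit weights this is the ordinary
#' categorical cross-entropy.
#'
#' @param probs n x C matrix of predicted class probabilities (rows sum to
#'   1 within 1e-6).
#' @param labels integer labels in `1..C`.
#' @param weights per-class positive weights (default: unit weights).
#' @return mean weighted cross-entropy (`>= 0`).
#' @export
weighted_cross_entropy <- function(probs, labels, weights = rep(1, ncol(probs))) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs)) stopf("one label per probability row required")
  if (length(weights) != ncol(probs)) stopf("one weight per class required")
  if (any(weights <= 0)) stopf("weights must be positive")
  if (any(labels < 1L | labels > ncol(probs))) stopf("label out of range")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stopf("probability rows must sum to 1 within 1e-6")
  p <- pmin(pmax(probs[cbind(seq_along(labels), labels)], 1e-12), 1)
  mean(weights[labels] * (-log(p)))
}
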