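# Synthetic OCT-like fixtures.
#
# The generator emulates the gross appearance of retinal B-scans: a stack of
# smooth horizontal bands (retinal layers) with a mild sinusoidal warp,
# multiplicative speckle noise, and class-specific lesions -- CNV: one bright
# ellipse below the band stack; DME: dark round intraretinal fluid pockets;
# Drusen: small upward bumps deforming the bottom (RPE-like) band boundary;
# Normal: clean bands. Classes are separable by construction; the point is a
# controllable, seed-deterministic stand-in for real B-scans, not physical
# realism.

#' Synthetic OCT dataset specification
#'
#' @param height,width image extents in pixels (default 64x64; the test
#'   scale. Real B-scans in this domain are nominally 496x512).
#' @param counts named or positional integer vector of per-class image
#'   counts in the order CNV, DME, Drusen, Normal.
#' @param speckle_sigma multiplicative speckle level `sigma_s`:
#'   `pixel <- pixel * (1 + sigma_s * z)`, `z` standard normal. Default 0.05.
#' @param seed integer seed for dataset generation.
#' @return an `oct_spec` object.
#' @export
oct_spec <- function(height = 64L, width = 64L,
                     counts = c(CNV = 120L, DME = 40L, Drusen = 30L, Normal = 90L),
                     speckle_sigma = 0.05, seed = 1L) {
  if (length(counts) != 4L) stopf("counts must have 4 entries (CNV, DME, Drusen, Normal)")
  counts <- as.integer(counts)
  if (any(counts < 0L)) stopf("counts must be >= 0")
  if (sum(counts > 0L) < 2L) stopf("at least two classes must be non-empty")
  if (!is_scalar_number(speckle_sigma) || speckle_sigma < 0)
    stopf("speckle_sigma must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 counts = stats::setNames(counts, oct_classes()),
                 speckle_sigma = speckle_sigma, seed = seed),
            class = "oct_spec")
}

#' Class names of the synthetic OCT task
#' @return `c("CNV", "DME", "Drusen", "Normal")`.
#' @export
oct_classes <- function() c("CNV", "DME", "Drusen", "Normal")

#' Per-class counts scaled from the reference OCT class ratio
#'
#' Scales the canonical CNV:DME:Drusen:Normal ratio
#' 37206 : 11349 : 8617 : 26323 down to a requested total, preserving the
#' ratio within rounding (the remainder is absorbed by the largest class).
#'
#' @param total total number of images (>= 40 recommended).
#' @return named integer vector of per-class counts summing to `total`.
#' @export
scaled_class_counts <- function(total) {
  ref <- c(CNV = 37206, DME = 11349, Drusen = 8617, Normal = 26323)
  counts <- round(total * ref / sum(ref))
  counts[which.max(counts)] <- counts[which.max(counts)] + (total - sum(counts))
  stats::setNames(as.integer(counts), names(ref))
}

# deterministic band-stack template; consumes a fixed number of RNG draws so
# that every class shares the same base for a given seed
.oct_base <- function(H, W) {
  n_bands <- sample(4:6, 1L)
  # boundaries from ~22% to ~78% of the height, jittered
  fracs <- seq(0.22, 0.78, length.out = n_bands + 1L)
  base_rows <- fracs * H + stats::runif(n_bands + 1L, -0.01, 0.01) * H
  amp <- stats::runif(1L, 0.005, 0.02) * H
  freq <- stats::runif(1L, 0.8, 1.6)
  phase <- stats::runif(1L, 0, 2 * pi)
  x <- seq_len(W)
  warp <- amp * sin(2 * pi * freq * x / W + phase)
  boundaries <- lapply(base_rows, function(b) b + warp)  # each: length W
  palette <- c(0.65, 0.35, 0.75, 0.45, 0.6, 0.3)
  intens <- palette[seq_len(n_bands)] + stats::runif(n_bands, -0.05, 0.05)
  intens <- pmin(pmax(intens, 0.25), 0.9)
  list(n_bands = n_bands, boundaries = boundaries, intensities = intens,
       bg_top = 0.08, bg_bottom = 0.05)
}

.oct_rasterize <- function(base, H, W) {
  img <- matrix(base$bg_top, H, W)
  rowm <- matrix(seq_len(H), H, W)
  bnd <- lapply(base$boundaries, function(b) matrix(b, H, W, byrow = TRUE))
  below_last <- rowm > bnd[[length(bnd)]]
  img[below_last] <- base$bg_bottom
  for (k in seq_len(base$n_bands)) {
    m <- rowm > bnd[[k]] & rowm <= bnd[[k + 1L]]
    img[m] <- base$intensities[k]
  }
  img
}

#' Generate one synthetic OCT-like B-scan
#'
#' Base template draws are consumed before lesion draws, so two classes
#' generated with the same seed share an identical band stack and differ
#' only by the class overlay (this is what makes the lesion-mask tests
#' exact). The lesion mask is attached as attribute `"mask"`.
#'
#' @param class_id one of [oct_classes()].
#' @param spec an [oct_spec()].
#' @param seed optional integer seed; `NULL` draws from the current stream.
#' @return numeric matrix in `[0, 1]` with attributes `mask` (logical
#'   matrix; lesion support) and `class`.
#' @export
generate_oct_like <- function(class_id, spec = oct_spec(), seed = NULL) {
  class_id <- match.arg(class_id, oct_classes())
  with_seed(seed, {
    H <- spec$height; W <- spec$width
    base <- .oct_base(H, W)
    mask <- matrix(FALSE, H, W)
    if (class_id == "Drusen") {
      # deform the bottom boundary upward with small Gaussian bumps
      nb <- sample(4:8, 1L)
      centers <- stats::runif(nb, 0.1, 0.9) * W
      heights <- stats::runif(nb, 3, 6)
      widths <- stats::runif(nb, 2, 3.5)
      x <- seq_len(W)
      last <- length(base$boundaries)
      b0 <- base$boundaries[[last]]
      bump <- rowSums(vapply(seq_len(nb), function(j)
        heights[j] * exp(-(x - centers[j])^2 / (2 * widths[j]^2)),
        numeric(W)))
      base$boundaries[[last]] <- b0 - bump
      img <- .oct_rasterize(base, H, W)
      rowm <- matrix(seq_len(H), H, W)
      mask <- rowm > matrix(b0 - bump, H, W, byrow = TRUE) &
        rowm <= matrix(b0, H, W, byrow = TRUE)
    } else {
      img <- .oct_rasterize(base, H, W)
    }
    if (class_id == "CNV") {
      # bright ellipse below the band stack
      cx <- stats::runif(1L, 0.3, 0.7) * W
      cy <- max(base$boundaries[[length(base$boundaries)]]) +
        stats::runif(1L, 0.04, 0.1) * H
      cy <- min(cy, H - 3)
      ax <- stats::runif(1L, 0.10, 0.16) * W
      ay <- stats::runif(1L, 0.05, 0.09) * H
      gain <- stats::runif(1L, 0.3, 0.45)
      rowm <- matrix(seq_len(H), H, W)
      colm <- matrix(seq_len(W), H, W, byrow = TRUE)
      mask <- ((rowm - cy) / ay)^2 + ((colm - cx) / ax)^2 <= 1
      img[mask] <- img[mask] + gain
    } else if (class_id == "DME") {
      # dark round fluid pockets inside the band stack
      np <- sample(2:3, 1L)
      rowm <- matrix(seq_len(H), H, W)
      colm <- matrix(seq_len(W), H, W, byrow = TRUE)
      top <- min(base$boundaries[[1]]); bot <- max(base$boundaries[[length(base$boundaries)]])
      for (j in seq_len(np)) {
        cx <- stats::runif(1L, 0.15, 0.85) * W
        cy <- stats::runif(1L, top + 0.2 * (bot - top), top + 0.8 * (bot - top))
        r <- stats::runif(1L, 0.07, 0.11) * min(H, W)
        m <- (rowm - cy)^2 + (colm - cx)^2 <= r^2
        img[m] <- img[m] * stats::runif(1L, 0.05, 0.2)
        mask <- mask | m
      }
    }
    if (spec$speckle_sigma > 0) {
      z <- matrix(stats::rnorm(H * W), H, W)
      img <- img * (1 + spec$speckle_sigma * z)
    }
    img <- clip01(img)
    attr(img, "mask") <- mask
    attr(img, "class") <- class_id
    img
  })
}

#' Labelled image dataset container
#'
#' @param images list of numeric matrices in `[0, 1]`, uniform shape.
#' @param labels integer class ids in `1..C`.
#' @param class_names character vector of length `C`.
#' @param synthetic logical flag per sample (`TRUE` for interpolated
#'   SMOTE samples).
#' @return an `oct_dataset` object.
#' @export
oct_dataset <- function(images, labels, class_names,
                        synthetic = rep(FALSE, length(labels))) {
  labels <- as.integer(labels)
  if (length(images) != length(labels))
    stopf("images and labels must have equal length")
  if (length(labels) && (min(labels) < 1L || max(labels) > length(class_names)))
    stopf("labels must lie in 1..%d", length(class_names))
  if (length(synthetic) != length(labels))
    stopf("synthetic flags must match the sample count")
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 synthetic = as.logical(synthetic)),
            class = "oct_dataset")
}

#' @export
print.oct_dataset <- function(x, ...) {
  cat(sprintf("<oct_dataset> %d images (%s synthetic)\n",
              length(x$labels), sum(x$synthetic)))
  counts <- class_counts(x)
  for (i in seq_along(counts))
    cat(sprintf("  %-8s %d\n", x$class_names[i], counts[i]))
  invisible(x)
}

#' Per-class sample counts of a dataset
#' @param dataset an [oct_dataset()].
#' @return named integer vector of length `C`.
#' @export
class_counts <- function(dataset) {
  stats::setNames(
    vapply(seq_along(dataset$class_names),
           function(c) sum(dataset$labels == c), integer(1)),
    dataset$class_names)
}

#' Generate a labelled synthetic OCT dataset
#'
#' Draws exactly the per-class counts in `spec$counts`, then shuffles the
#' sample order; fully determined by `spec$seed`.
#'
#' @param spec an [oct_spec()].
#' @return an [oct_dataset()].
#' @export
generate_dataset <- function(spec = oct_spec()) {
  with_seed(spec$seed, {
    classes <- oct_classes()
    images <- list(); labels <- integer(0)
    for (c in seq_along(classes)) {
      for (i in seq_len(spec$counts[c])) {
        img <- generate_oct_like(classes[c], spec, seed = NULL)
        attr(img, "mask") <- NULL
        attr(img, "class") <- NULL
        images[[length(images) + 1L]] <- img
        labels <- c(labels, c)
      }
    }
    ord <- sample.int(length(labels))
    oct_dataset(images[ord], labels[ord], classes)
  })
}

#' Toy fitness landscapes with known optima
#'
#' Enumerable layered landscapes used as oracles for the ant colony
#' optimizer:
#' * `"additive_4x5"`: 4 layers x 5 candidates, per-layer additive costs,
#'   unique global optimum.
#' * `"deceptive_2x2"`: 2 layers x 2 candidates whose global optimum is off
#'   the greedy per-layer-marginal path.
#' * `"flat"`: constant fitness (non-unique argmin).
#'
#' @param name landscape name.
#' @return list with `space` ([aco_space()]), `fitness_fn` (callable on an
#'   `ant_solution`), `argmin` (choice indices), `min_fitness`, and
#'   `argmin_unique`.
#' @export
toy_landscape <- function(name = c("additive_4x5", "deceptive_2x2", "flat")) {
  name <- match.arg(name)
  if (name == "additive_4x5") {
    costs <- rbind(c(0.9, 0.7, 0.5, 0.3, 0.1),
                   c(0.1, 0.9, 0.7, 0.5, 0.3),
                   c(0.3, 0.1, 0.9, 0.7, 0.5),
                   c(0.5, 0.3, 0.1, 0.9, 0.7))
    space <- aco_space(stats::setNames(
      lapply(1:4, function(l) seq_len(5)), paste0("layer", 1:4)))
    fitness_fn <- function(sol)
      sum(costs[cbind(seq_len(4), sol$choices)])
    list(space = space, fitness_fn = fitness_fn,
         argmin = apply(costs, 1, which.min), min_fitness = sum(apply(costs, 1, min)),
         argmin_unique = TRUE)
  } else if (name == "deceptive_2x2") {
    # global optimum (1,2); greedy per-layer marginals point to (2,2)
    tab <- matrix(c(1.0, 0.45, 0.4, 0.5), 2, 2)  # tab[i,j] = f(choice1=i, choice2=j)
    space <- aco_space(list(layer1 = 1:2, layer2 = 1:2))
    fitness_fn <- function(sol) tab[sol$choices[1], sol$choices[2]]
    list(space = space, fitness_fn = fitness_fn, argmin = c(1L, 2L),
         min_fitness = 0.4, argmin_unique = TRUE, table = tab)
  } else {
    space <- aco_space(list(layer1 = 1:2, layer2 = 1:2))
    list(space = space, fitness_fn = function(sol) 0.5,
         argmin = c(1L, 1L), min_fitness = 0.5, argmin_unique = FALSE)
  }
}

#' Feature matrix with a known informative subset
#'
#' The first `k_informative` columns are class-mean-shifted Gaussians
#' (between-class mean separation of 2 standard deviations); the remaining
#' columns are pure standard-normal noise.
#'
#' @param n samples. @param p features. @param k_informative number of
#'   signal-carrying features. @param n_classes classes (default 4).
#' @param seed integer seed.
#' @return list with `x` (n x p matrix), `y` (integer labels `1..C`) and
#'   `informative` (ground-truth column indices).
#' @export
informative_features <- function(n, p, k_informative, n_classes = 4L, seed = 1L) {
  if (k_informative < 1L || k_informative > p)
    stopf("k_informative must lie in 1..p")
  with_seed(seed, {
    y <- sample(rep(seq_len(n_classes), length.out = n))
    # distinct +/-1 class patterns over the informative columns
    repeat {
      M <- matrix(sample(c(-1, 1), n_classes * k_informative, replace = TRUE),
                  n_classes, k_informative)
      if (nrow(unique(M)) == n_classes || k_informative == 1L) break
    }
    x <- matrix(stats::rnorm(n * p), n, p)
    for (j in seq_len(k_informative))
      x[, j] <- x[, j] + M[y, j]
    list(x = x, y = y, informative = seq_len(k_informative))
  })
}
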