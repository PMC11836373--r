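# Augmentation operators, policy fitness, and ACO search for the best
# augmentation combination. A policy is an ordered list of (operator,
# parameter) pairs; its fitness is the mean loss of a pluggable callback on
# augmented samples plus a lambda-weighted complexity penalty, so cheap
# policies that still help the model win.

# inverse-mapped bilinear sampler with reflect boundary indexing; used by
# rotation and translation so every geometric op is total on [0,1] images
.bilinear_sample <- function(img, src_y, src_x) {
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(src_y); x0 <- floor(src_x)
  fy <- src_y - y0; fx <- src_x - x0
  iy0 <- reflect_index(as.integer(y0), H)
  iy1 <- reflect_index(as.integer(y0) + 1L, H)
  ix0 <- reflect_index(as.integer(x0), W)
  ix1 <- reflect_index(as.integer(x0) + 1L, W)
  v <- img[cbind(iy0, ix0)] * (1 - fy) * (1 - fx) +
    img[cbind(iy1, ix0)] * fy * (1 - fx) +
    img[cbind(iy0, ix1)] * (1 - fy) * fx +
    img[cbind(iy1, ix1)] * fy * fx
  matrix(v, H, W)
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation with reflect padding. Multiples of 90 degrees are
#' applied as exact index permutations.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param degrees rotation angle, counter-clockwise.
#' @return rotated image, same shape, clipped to `[0, 1]`.
#' @export
rotate_image <- function(img, degrees) {
  H <- nrow(img); W <- ncol(img)
  d <- degrees %% 360
  if (d == 0) return(img)
  if (d %in% c(90, 180, 270) && H == W) {
    out <- switch(as.character(d),
                  "90"  = t(img)[rev(seq_len(H)), , drop = FALSE],
                  "180" = img[rev(seq_len(H)), rev(seq_len(W)), drop = FALSE],
                  "270" = t(img)[, rev(seq_len(W)), drop = FALSE])
    return(out)
  }
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse map: rotate destination coords by -theta to find the source
  src_y <- cy + cos(th) * yy + sin(th) * xx
  src_x <- cx - sin(th) * yy + cos(th) * xx
  clip01(.bilinear_sample(img, as.vector(src_y), as.vector(src_x)))
}

#' Translate an image by whole pixels with reflect padding
#' @param img numeric matrix. @param dx,dy shift in columns / rows.
#' @return shifted image, same shape.
#' @export
translate_image <- function(img, dx = 0L, dy = 0L) {
  H <- nrow(img); W <- ncol(img)
  rows <- reflect_index(seq_len(H) - as.integer(dy), H)
  cols <- reflect_index(seq_len(W) - as.integer(dx), W)
  img[rows, cols, drop = FALSE]
}

#' Define an augmentation operator
#'
#' @param name operator name (unique within a menu).
#' @param values finite candidate parameter grid (vector or list).
#' @param fn function `(image, param)` returning a same-shape image; noise
#'   ops may consume the current RNG stream.
#' @param cost_weight contribution weight to the policy complexity score.
#' @return an `aug_op` object.
#' @export
aug_op <- function(name, values, fn, cost_weight = 1) {
  values <- if (is.list(values)) values else as.list(values)
  if (length(values) == 0L) stopf("operator '%s' needs a non-empty grid", name)
  if (!is_scalar_number(cost_weight) || cost_weight < 0)
    stopf("cost_weight must be >= 0")
  structure(list(name = name, values = values, fn = fn,
                 cost_weight = cost_weight), class = "aug_op")
}

#' Default augmentation operator menu
#'
#' Horizontal flip, rotation (+-5, +-10, 90 degrees), brightness shift
#' (+-0.1, +-0.2), contrast scaling (0.8, 1.2), additive Gaussian noise
#' (sigma 0.01, 0.05) and horizontal translation (+-4 px); all cost weight 1.
#'
#' @return named list of [aug_op()] objects.
#' @export
default_augmentation_ops <- function() {
  ops <- list(
    aug_op("flip_horizontal", list(TRUE),
           function(img, p) img[, rev(seq_len(ncol(img))), drop = FALSE]),
    aug_op("rotate", c(-10, -5, 5, 10, 90),
           function(img, p) rotate_image(img, p)),
    aug_op("brightness", c(-0.2, -0.1, 0.1, 0.2),
           function(img, p) clip01(img + p)),
    aug_op("contrast", c(0.8, 1.2),
           function(img, p) clip01((img - 0.5) * p + 0.5)),
    aug_op("gauss_noise", c(0.01, 0.05),
           function(img, p)
             clip01(img + matrix(stats::rnorm(length(img), sd = p),
                                 nrow(img), ncol(img)))),
    aug_op("translate", c(-4, 4),
           function(img, p) translate_image(img, dx = p))
  )
  stats::setNames(ops, vapply(ops, `[[`, character(1), "name"))
}

#' Construct an augmentation policy
#'
#' @param assignments named list mapping operator name to the chosen
#'   parameter (operators absent from the list are off). May be empty.
#' @param ops operator menu (default [default_augmentation_ops()]).
#' @return an `aug_policy`: ordered list of `(op, param)` pairs.
#' @export
aug_policy <- function(assignments = list(), ops = default_augmentation_ops()) {
  if (anyDuplicated(names(assignments)))
    stopf("each operator may appear at most once")
  steps <- list()
  for (nm in names(assignments)) {
    op <- ops[[nm]]
    if (is.null(op)) stopf("unknown operator '%s'", nm)
    p <- assignments[[nm]]
    hit <- vapply(op$values, function(v) isTRUE(all.equal(v, p)), logical(1))
    if (!any(hit)) stopf("parameter %s not on operator '%s' grid", format(p), nm)
    steps[[length(steps) + 1L]] <- list(op = op, param = op$values[[which(hit)[1]]])
  }
  structure(list(steps = steps), class = "aug_policy")
}

#' Apply an augmentation policy to one image
#'
#' Operators are applied in listed order; output is clipped to `[0, 1]`.
#' Stochastic operators (noise) draw from a stream seeded by `seed`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param policy an [aug_policy()].
#' @param seed integer seed (`NULL`: current stream).
#' @return augmented image, same shape.
#' @export
apply_policy <- function(img, policy, seed = NULL) {
  check_image(img)
  with_seed(seed, {
    for (s in policy$steps) img <- s$op$fn(img, s$param)
    clip01(img)
  })
}

# normalized |parameter| position on the op's grid magnitudes: 0 at the
# smallest |value|, 1 at the largest; 0 for degenerate (single-magnitude) grids
.param_magnitude <- function(op, param) {
  mags <- vapply(op$values, function(v)
    if (is.numeric(v)) abs(v) else 0, numeric(1))
  m <- if (is.numeric(param)) abs(param) else 0
  rng <- range(mags)
  if (diff(rng) <= 0) return(0)
  (m - rng[1]) / diff(rng)
}

#' Complexity score of an augmentation policy
#'
#' `sum over active ops of cost_weight * (1 + normalized |parameter|)`,
#' where the parameter magnitude is min-max normalized over the operator's
#' grid. Empty policy scores 0.
#'
#' @param policy an [aug_policy()].
#' @return non-negative complexity score.
#' @export
policy_complexity <- function(policy) {
  if (length(policy$steps) == 0L) return(0)
  sum(vapply(policy$steps, function(s)
    s$op$cost_weight * (1 + .param_magnitude(s$op, s$param)), numeric(1)))
}

#' Augmentation-policy fitness
#'
#' `F(W) = mean over N seeded evaluation samples of loss_fn(augmented
#' sample, label) + lambda * policy_complexity(W)`.
#'
#' @param policy an [aug_policy()].
#' @param loss_fn callback `(augmented_image, label) -> finite loss >= 0`
#'   (e.g. a frozen reference model's cross-entropy on the sample).
#' @param dataset an [oct_dataset()] with at least `n_eval` samples.
#' @param lambda accuracy/complexity trade-off `>= 0`.
#' @param n_eval evaluation sample count `N`.
#' @param seed seed for the evaluation subsample and stochastic ops.
#' @return policy fitness (lower is better).
#' @export
policy_fitness <- function(policy, loss_fn, dataset, lambda = 0.01,
                           n_eval = 16L, seed = 1L) {
  n <- length(dataset$labels)
  if (n == 0L) stopf("dataset is empty")
  if (n < n_eval) stopf("dataset has %d samples but n_eval = %d", n, n_eval)
  with_seed(seed, {
    idx <- sample.int(n, n_eval)
    losses <- vapply(idx, function(i) {
      aug <- apply_policy(dataset$images[[i]], policy, seed = NULL)
      loss_fn(aug, dataset$labels[i])
    }, numeric(1))
    mean(losses) + lambda * policy_complexity(policy)
  })
}

#' ACO search for the best augmentation policy
#'
#' Builds a layered search space with one layer per operator (candidates:
#' `"off"` plus the operator's parameter grid) and minimizes
#' [policy_fitness()] with [aco_optimize()].
#'
#' @inheritParams policy_fitness
#' @param ops operator menu.
#' @param aco_cfg an [aco_config()].
#' @return list with `policy` (decoded best [aug_policy()]), `fitness`,
#'   and `trace`.
#' @export
search_augmentation_policy <- function(ops = default_augmentation_ops(),
                                       loss_fn, dataset, lambda = 0.01,
                                       n_eval = 16L, seed = 1L,
                                       aco_cfg = aco_config(seed = seed)) {
  if (length(ops) == 0L) stopf("operator menu is empty")
  layers <- lapply(ops, function(op) c(list("off"), op$values))
  space <- aco_space(layers)
  decode <- function(sol) {
    assignments <- list()
    for (i in seq_along(ops)) {
      if (sol$choices[i] > 1L)
        assignments[[ops[[i]]$name]] <- ops[[i]]$values[[sol$choices[i] - 1L]]
    }
    aug_policy(assignments, ops)
  }
  fit <- aco_optimize(space, function(sol)
    policy_fitness(decode(sol), loss_fn, dataset, lambda, n_eval, seed),
    aco_cfg)
  list(policy = decode(fit$best), fitness = fit$best$fitness,
       trace = fit$trace)
}

#' Serialize / restore an augmentation policy
#'
#' Policies are written as a flat YAML mapping operator name -> parameter,
#' with `"off"` for inactive operators, so runs are reproducible.
#'
#' @param policy an [aug_policy()]. @param path file path.
#' @param ops operator menu used when reading back.
#' @return `path` / the restored [aug_policy()].
#' @export
write_policy_yaml <- function(policy, path, ops = default_augmentation_ops()) {
  m <- stats::setNames(as.list(rep("off", length(ops))), names(ops))
  for (s in policy$steps) m[[s$op$name]] <- s$param
  yaml::write_yaml(m, path)
  invisible(path)
}

#' @rdname write_policy_yaml
#' @export
read_policy_yaml <- function(path, ops = default_augmentation_ops()) {
  m <- yaml::read_yaml(path)
  m <- m[!vapply(m, identical, logical(1), "off")]
  aug_policy(m, ops)
}
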