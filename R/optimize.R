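# ACO applications: hyperparameter tuning (learning rate, batch size,
# dense-layer width) over a layered grid, and wrapper feature selection
# with a cheap regularized linear softmax as the subset evaluator.

#' Default hyperparameter search space
#'
#' Learning rate {0.1, 0.01, 0.001, 0.0001}, batch size {16, 32, 64},
#' dense-layer width {128, 256, 512, 1024}; the conventional starting
#' point (0.01 / 32 / 512, Adam) is a member of every grid.
#'
#' @return an [aco_space()] with layers `learning_rate`, `batch_size`,
#'   `dense_neurons`.
#' @export
hyperparam_space <- function() {
  aco_space(list(learning_rate = c(0.1, 0.01, 0.001, 0.0001),
                 batch_size = c(16L, 32L, 64L),
                 dense_neurons = c(128L, 256L, 512L, 1024L)))
}

#' Model complexity of a hyperparameter configuration
#'
#' Normalized dense-layer width: `dense_neurons / max(grid)`, in `(0, 1]`.
#' Independent of learning rate and batch size (the only capacity term in
#' the space).
#'
#' @param config named list with a `dense_neurons` entry (e.g. an
#'   `ant_solution$values`).
#' @param space the [hyperparam_space()] the config was drawn from.
#' @return complexity in `(0, 1]`.
#' @export
model_complexity <- function(config, space = hyperparam_space()) {
  grid <- unlist(space$layers$dense_neurons)
  as.numeric(config$dense_neurons) / max(grid)
}

#' Hyperparameter fitness
#'
#' `F(theta) = validation cross-entropy + lambda * model_complexity(theta)`.
#'
#' @param config named list of hyperparameter values.
#' @param train_eval_fn callback taking the config list and returning a
#'   list with at least `loss` (validation mean cross-entropy) and
#'   optionally `accuracy` and `epochs`.
#' @param lambda capacity regularization weight.
#' @param space the search space (for the complexity normalizer).
#' @return fitness (lower is better).
#' @export
hyperparam_fitness <- function(config, train_eval_fn, lambda = 0.1,
                               space = hyperparam_space()) {
  res <- train_eval_fn(config)
  loss <- if (is.list(res)) res$loss else res
  if (!is_scalar_number(loss))
    stopf("train_eval_fn returned a non-finite loss for config (lr=%s, batch=%s, dense=%s)",
          format(config$learning_rate), format(config$batch_size),
          format(config$dense_neurons))
  loss + lambda * model_complexity(config, space)
}

#' ACO hyperparameter tuning
#'
#' Minimizes [hyperparam_fitness()] over the layered grid with
#' [aco_optimize()]; the returned configuration achieved the minimum
#' fitness among every evaluated candidate.
#'
#' @inheritParams hyperparam_fitness
#' @param aco_cfg an [aco_config()].
#' @return list with `config` (named list of chosen values), `fitness`
#'   and `trace`.
#' @export
tune_hyperparams <- function(space = hyperparam_space(), train_eval_fn,
                             lambda = 0.1, aco_cfg = aco_config()) {
  res <- aco_optimize(space, function(sol)
    hyperparam_fitness(sol$values, train_eval_fn, lambda, space), aco_cfg)
  list(config = res$best$values, fitness = res$best$fitness,
       trace = res$trace)
}

# regularized linear softmax evaluated on a seeded stratified 70/30 split;
# returns the validation mean cross-entropy
.subset_eval <- function(x, y, cols, split_seed = 1L, glmnet_lambda = 0.01) {
  C <- length(unique(y))
  tr <- te <- integer(0)
  with_seed(split_seed, {
    for (c in sort(unique(y))) {
      idx <- sample(which(y == c))
      ntr <- max(2L, floor(0.7 * length(idx)))
      tr <- c(tr, idx[seq_len(ntr)])
      te <- c(te, idx[-seq_len(ntr)])
    }
  })
  xs <- x[, cols, drop = FALSE]
  # glmnet needs >= 2 columns; duplicate a single selected feature
  if (ncol(xs) == 1L) xs <- cbind(xs, 0)
  fit <- glmnet::glmnet(xs[tr, , drop = FALSE], factor(y[tr], levels = sort(unique(y))),
                        family = "multinomial",
                        lambda = glmnet_lambda * c(10, 4, 1),
                        standardize = FALSE)
  pr <- predict(fit, xs[te, , drop = FALSE], s = glmnet_lambda,
                type = "response")[, , 1]
  weighted_cross_entropy(pr, match(y[te], sort(unique(y))), rep(1, C))
}

#' ACO wrapper feature selection
#'
#' One {exclude, include} layer per feature; each ant's subset is scored
#' by the validation cross-entropy of a regularized linear softmax
#' (glmnet, fixed seed, stratified 70/30 split) plus
#' `lambda * |subset| / p`. The empty subset is inadmissible (infinite
#' fitness), so the returned mask always contains at least one feature.
#'
#' @param x n x p feature matrix (`n >= 10`).
#' @param y integer class labels (at least two classes).
#' @param lambda subset-size penalty weight.
#' @param aco_cfg an [aco_config()]; its seed drives the whole search.
#' @param split_seed seed of the train/validation split used by the
#'   subset evaluator.
#' @return list with `mask` (logical length p), `fitness`, `trace`.
#' @export
select_features_aco <- function(x, y, lambda = 0.02,
                                aco_cfg = aco_config(n_ants = 15L,
                                                     max_iterations = 40L,
                                                     patience = 10L),
                                split_seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 10L) stopf("need at least 10 samples")
  if (length(unique(y)) < 2L) stopf("labels are degenerate (single class)")
  space <- aco_space(stats::setNames(
    lapply(seq_len(p), function(j) c(FALSE, TRUE)), paste0("f", seq_len(p))))
  fitness_fn <- function(sol) {
    cols <- which(sol$choices == 2L)
    if (length(cols) == 0L) return(Inf)
    .subset_eval(x, y, cols, split_seed) + lambda * length(cols) / p
  }
  res <- aco_optimize(space, fitness_fn, aco_cfg)
  mask <- res$best$choices == 2L
  if (!any(mask)) stopf("search returned an empty subset")  # unreachable
  list(mask = mask, fitness = res$best$fitness, trace = res$trace)
}
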