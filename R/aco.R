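# Generic ant colony optimizer over a layered graph of discrete choices.
#
# Each layer is one decision variable (a hyperparameter, an augmentation
# slot, a feature's include/exclude switch); each candidate value carries a
# pheromone trail tau. Ants build a full solution by sampling one candidate
# per layer with probability proportional to tau^alpha; trails evaporate at
# rate rho each iteration and the iteration-best ant deposits
# Q / (1 + fitness) along its path. Fitness is minimized (losses).

#' Construct a layered discrete search space
#'
#' @param layers named list; each element is the vector (or list) of
#'   candidate values for that layer. Candidate display labels must be
#'   unique within a layer.
#' @return an `aco_space` object.
#' @examples
#' aco_space(list(lr = c(0.1, 0.01), batch = c(16, 32, 64)))
#' @export
aco_space <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L)
    stopf("layers must be a non-empty list")
  if (is.null(names(layers)) || any(names(layers) == "") ||
      anyDuplicated(names(layers)))
    stopf("layers must have unique non-empty names")
  layers <- lapply(layers, function(l) if (is.list(l)) l else as.list(l))
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (length(l) == 0L) stopf("layer '%s' has no candidates", nm)
    labs <- vapply(l, function(v) paste(format(v), collapse = "/"), character(1))
    if (anyDuplicated(labs)) stopf("layer '%s' has duplicate candidate labels", nm)
  }
  structure(list(layers = layers), class = "aco_space")
}

#' ACO configuration
#'
#' @param n_ants ants per iteration.
#' @param rho evaporation rate in `(0, 1]`.
#' @param q_scale deposit scale `Q >= 0`; the iteration-best ant deposits
#'   `Q / (1 + fitness)`.
#' @param alpha pheromone exponent `>= 0` used in selection probabilities.
#' @param tau0 initial trail value `> 0`.
#' @param tau_min positive floor applied to every trail after updates.
#' @param max_iterations iteration budget.
#' @param patience iterations without best-so-far improvement before an
#'   early stop.
#' @param seed integer seed for the optimizer's private random stream, or
#'   `NULL` to draw from the session stream.
#' @param elitist if `TRUE`, the global best ant also deposits each iteration.
#' @return an `aco_config` object.
#' @export
aco_config <- function(n_ants = 10L, rho = 0.3, q_scale = 1, alpha = 1,
                       tau0 = 1, tau_min = 0.05, max_iterations = 50L,
                       patience = 10L, seed = NULL, elitist = FALSE) {
  cfg <- list(n_ants = as.integer(n_ants), rho = rho, q_scale = q_scale,
              alpha = alpha, tau0 = tau0, tau_min = tau_min,
              max_iterations = as.integer(max_iterations),
              patience = as.integer(patience), seed = seed,
              elitist = isTRUE(elitist))
  if (cfg$n_ants < 1L) stopf("n_ants must be positive")
  if (!is_scalar_number(rho) || rho <= 0 || rho > 1)
    stopf("rho must lie in (0, 1]")
  if (!is_scalar_number(q_scale) || q_scale < 0) stopf("q_scale must be >= 0")
  if (!is_scalar_number(alpha) || alpha < 0) stopf("alpha must be >= 0")
  if (!is_scalar_number(tau0) || tau0 <= 0) stopf("tau0 must be > 0")
  if (!is_scalar_number(tau_min) || tau_min <= 0 || tau_min > tau0)
    stopf("tau_min must satisfy 0 < tau_min <= tau0")
  if (cfg$max_iterations < 1L) stopf("max_iterations must be positive")
  if (cfg$patience < 1L) stopf("patience must be positive")
  structure(cfg, class = "aco_config")
}

#' Initialize pheromone trails
#'
#' Every candidate of every layer starts at `tau0`; the iteration counter
#' starts at 0.
#'
#' @param space an [aco_space()].
#' @param config an [aco_config()].
#' @return an `aco_pheromone` object (per-layer numeric trail vectors).
#' @export
aco_init_pheromone <- function(space, config) {
  stopifnot(inherits(space, "aco_space"), inherits(config, "aco_config"))
  tau <- lapply(space$layers, function(l) rep(config$tau0, length(l)))
  structure(list(tau = tau, iteration = 0L), class = "aco_pheromone")
}

#' Per-layer selection probabilities
#'
#' @param pheromone an `aco_pheromone`.
#' @param config an [aco_config()].
#' @return list of per-layer probability vectors `tau^alpha / sum(tau^alpha)`.
#' @export
aco_selection_probs <- function(pheromone, config) {
  lapply(pheromone$tau, function(tau) {
    w <- tau^config$alpha
    w / sum(w)
  })
}

#' Sample one ant solution
#'
#' Chooses, independently per layer, candidate `c` with probability
#' `tau_c^alpha / sum(tau^alpha)`. Fitness is left unset (`NA`).
#'
#' @param space an [aco_space()].
#' @param pheromone an `aco_pheromone` shaped like `space`.
#' @param config an [aco_config()].
#' @return an `ant_solution` with integer `choices` (one index per layer),
#'   named list `values`, and `fitness = NA`.
#' @export
aco_sample_solution <- function(space, pheromone, config) {
  probs <- aco_selection_probs(pheromone, config)
  choices <- vapply(probs, function(p) {
    if (length(p) == 1L) 1L
    else sample.int(length(p), 1L, prob = p)
  }, integer(1))
  aco_solution(space, choices)
}

#' Build an ant solution from explicit choices
#' @param space an [aco_space()].
#' @param choices integer vector, one candidate index per layer.
#' @param fitness optional evaluated fitness.
#' @return an `ant_solution`.
#' @export
aco_solution <- function(space, choices, fitness = NA_real_) {
  nl <- length(space$layers)
  if (length(choices) != nl) stopf("need exactly one choice per layer")
  choices <- as.integer(choices)
  for (i in seq_len(nl)) {
    if (choices[i] < 1L || choices[i] > length(space$layers[[i]]))
      stopf("choice %d out of range for layer '%s'", choices[i],
            names(space$layers)[i])
  }
  values <- mapply(function(l, c) l[[c]], space$layers, choices,
                   SIMPLIFY = FALSE)
  structure(list(choices = choices, values = values, fitness = fitness),
            class = "ant_solution")
}

#' Pheromone deposit for a fitness value
#'
#' `delta = Q / (1 + fitness)`: non-negative and decreasing in the loss.
#'
#' @param fitness finite loss `>= 0` (infinite fitness deposits 0).
#' @param q_scale deposit scale `Q >= 0`.
#' @return deposit amount.
#' @export
aco_deposit_amount <- function(fitness, q_scale) {
  if (!is.numeric(fitness) || length(fitness) != 1L || is.na(fitness) ||
      fitness < 0)
    stopf("fitness must be a single non-negative number")
  if (!is_scalar_number(q_scale) || q_scale < 0) stopf("q_scale must be >= 0")
  if (is.infinite(fitness)) return(0)
  q_scale / (1 + fitness)
}

#' Evaporate trails and deposit along the best path
#'
#' Candidates on `best`'s path get `tau' = (1 - rho) * tau + delta`; all
#' others `tau' = (1 - rho) * tau`; every trail is then floored at
#' `tau_min` and the iteration counter advances.
#'
#' @param pheromone an `aco_pheromone`.
#' @param best an evaluated `ant_solution`.
#' @param delta deposit amount `>= 0`.
#' @param config an [aco_config()].
#' @return the updated `aco_pheromone`.
#' @export
aco_update_pheromone <- function(pheromone, best, delta, config) {
  if (!is_scalar_number(delta) || delta < 0) stopf("delta must be >= 0")
  tau <- pheromone$tau
  for (i in seq_along(tau)) {
    tau[[i]] <- (1 - config$rho) * tau[[i]]
    tau[[i]][best$choices[i]] <- tau[[i]][best$choices[i]] + delta
    tau[[i]] <- pmax(tau[[i]], config$tau_min)
  }
  pheromone$tau <- tau
  pheromone$iteration <- pheromone$iteration + 1L
  pheromone
}

#' Run the ant colony optimizer
#'
#' Iterates: sample `n_ants` solutions, evaluate each with `fitness_fn`,
#' let the iteration-best ant (ties: lowest ant index) deposit
#' `Q / (1 + fitness)` after evaporation, and record a convergence trace.
#' Stops at `max_iterations` or after `patience` iterations without
#' best-so-far improvement. The returned best is the minimum-fitness
#' solution among all evaluated ants.
#'
#' @param space an [aco_space()].
#' @param fitness_fn function taking an `ant_solution` and returning a
#'   finite loss `>= 0` (`Inf` is tolerated and never wins).
#' @param config an [aco_config()].
#' @return list with `best` (evaluated `ant_solution`), `trace` (data frame
#'   with columns `iteration`, `best_fitness`, `best_so_far`), `pheromone`
#'   and `n_evaluated`.
#' @export
aco_optimize <- function(space, fitness_fn, config = aco_config()) {
  stopifnot(inherits(space, "aco_space"), is.function(fitness_fn),
            inherits(config, "aco_config"))
  with_seed(config$seed, {
    pher <- aco_init_pheromone(space, config)
    best_global <- NULL
    trace <- vector("list", config$max_iterations)
    stall <- 0L
    n_eval <- 0L
    t_done <- 0L
    for (t in seq_len(config$max_iterations)) {
      ants <- vector("list", config$n_ants)
      fits <- numeric(config$n_ants)
      for (a in seq_len(config$n_ants)) {
        sol <- aco_sample_solution(space, pher, config)
        f <- tryCatch(fitness_fn(sol), error = function(e)
          stopf("fitness_fn failed on choices [%s]: %s",
                paste(sol$choices, collapse = ", "), conditionMessage(e)))
        if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0)
          stopf("fitness_fn must return a single non-negative number (choices [%s])",
                paste(sol$choices, collapse = ", "))
        sol$fitness <- f
        ants[[a]] <- sol
        fits[a] <- f
        n_eval <- n_eval + 1L
      }
      ib <- which.min(fits)  # ties -> lowest ant index
      iter_best <- ants[[ib]]
      improved <- is.null(best_global) || iter_best$fitness < best_global$fitness
      if (improved) best_global <- iter_best
      stall <- if (improved) 0L else stall + 1L
      pher <- aco_update_pheromone(
        pher, iter_best,
        aco_deposit_amount(iter_best$fitness, config$q_scale), config)
      if (config$elitist && !identical(best_global$choices, iter_best$choices)) {
        # extra elitist deposit without an extra evaporation step
        for (i in seq_along(pher$tau)) {
          j <- best_global$choices[i]
          pher$tau[[i]][j] <- pher$tau[[i]][j] +
            aco_deposit_amount(best_global$fitness, config$q_scale)
        }
      }
      trace[[t]] <- data.frame(iteration = t,
                               best_fitness = iter_best$fitness,
                               best_so_far = best_global$fitness)
      t_done <- t
      if (stall >= config$patience) break
    }
    list(best = best_global,
         trace = do.call(rbind, trace[seq_len(t_done)]),
         pheromone = pher,
         n_evaluated = n_eval)
  })
}

#' Write a convergence trace as CSV
#'
#' Columns `iteration`, `best_fitness`, `best_so_far`.
#'
#' @param trace data frame as returned in `aco_optimize()$trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("iteration", "best_fitness", "best_so_far")],
                   path, row.names = FALSE)
  invisible(path)
}
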