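#' GA run configuration
#'
#' @param generations maximum number of generations (default 100).
#' @param elite_fraction fraction of the population carried unchanged
#'   (default 0.1; elite count = round(fraction x pop size)).
#' @param crossover_rate,mutation_rate independent per-slot application
#'   probabilities (default 0.8 and 0.8 — both high because the many
#'   molecular mutations are undersampled at typical low mutation rates).
#' @param selection "stochastic_uniform" (default), "roulette" or
#'   "tournament" (k = 2).
#' @param stall_gen_limit stop when the best fitness has improved by less
#'   than `tol_fun` over this many generations (default 100).
#' @param tol_fun minimum improvement counted as progress (default 0.02).
#' @param tol_con accepted for completeness; constraints enter as penalties,
#'   so no nonlinear-constraint solver consumes it (inert).
#' @param rescore_elites re-evaluate elites each generation; needed only for
#'   non-deterministic scorers, where best fitness may then fluctuate.
#' @param seed RNG seed for the run.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(generations = 100L, elite_fraction = 0.1,
                      crossover_rate = 0.8, mutation_rate = 0.8,
                      selection = c("stochastic_uniform", "roulette", "tournament"),
                      stall_gen_limit = 100L, tol_fun = 0.02, tol_con = 0.01,
                      rescore_elites = FALSE, seed = 1L) {
  selection <- match.arg(selection)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    mol_error("GA rates must lie in [0, 1]", "config_error")
  }
  if (elite_fraction < 0 || elite_fraction > 1) {
    mol_error("elite_fraction must lie in [0, 1]", "config_error")
  }
  structure(list(generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 selection = selection,
                 stall_gen_limit = as.integer(stall_gen_limit),
                 tol_fun = tol_fun, tol_con = tol_con,
                 rescore_elites = isTRUE(rescore_elites),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# rank-based selection weights: fitnesses are negative-is-better and
# unbounded, so weights are 1/sqrt(rank) — sign-safe and scale-free
selection_weights <- function(fitness) {
  r <- rank(fitness, ties.method = "average")
  w <- 1 / sqrt(r)
  w / sum(w)
}

#' Select parents from an evaluated population
#'
#' Stochastic-uniform (default) lays the rank-based weights on a line and
#' samples with one random start and equal steps; roulette draws
#' independently from the same weights; tournament plays k = 2 matches.
#' An all-failure population (every fitness at the sentinel 0) falls back to
#' uniform random selection with a warning.
#'
#' @param fitness numeric vector of fitness values (minimization).
#' @param n number of parents to draw.
#' @param method selection method.
#' @return integer vector of n selected indices.
#' @export
select_parents <- function(fitness, n,
                           method = c("stochastic_uniform", "roulette", "tournament")) {
  method <- match.arg(method)
  if (n == 0) return(integer(0))
  m <- length(fitness)
  if (all(fitness == 0)) {
    warning("all individuals carry the failure sentinel; selecting uniformly")
    return(sample.int(m, n, replace = TRUE))
  }
  if (method == "tournament") {
    a <- sample.int(m, n, replace = TRUE)
    b <- sample.int(m, n, replace = TRUE)
    return(ifelse(fitness[a] <= fitness[b], a, b))
  }
  w <- selection_weights(fitness)
  if (method == "roulette") {
    return(sample.int(m, n, replace = TRUE, prob = w))
  }
  # stochastic uniform: single spin, equally spaced pointers
  edges <- cumsum(w)
  step <- 1 / n
  pointers <- stats::runif(1, 0, step) + step * (seq_len(n) - 1)
  idx <- findInterval(pointers, c(0, edges), rightmost.closed = TRUE)
  pmin(idx, m)
}

#' Produce the next generation
#'
#' The elite (best `elite_fraction`) is copied unchanged; every remaining
#' slot is filled from selected parents with crossover applied at
#' `crossover_rate` (else a parent copy) followed by mutation at
#' `mutation_rate`. New individuals are evaluated; population size is
#' preserved.
#'
#' @param chromosomes character vector of the current population.
#' @param records `fitness_records` for the current population.
#' @param scorer,molecular,adme,constraints as in [evaluate_fitness()].
#' @param ga a [ga_config()].
#' @param operators an [operator_config()].
#' @param cache optional environment memoizing chromosome -> record row
#'   (valid for deterministic scorers).
#' @return list(chromosomes, records).
#' @export
next_generation <- function(chromosomes, records, scorer, ga,
                            operators = operator_config(),
                            molecular = operators$molecular,
                            adme = adme_config(),
                            constraints = list(),
                            cache = NULL) {
  if (isTRUE(ga$rescore_elites)) cache <- NULL
  n <- length(chromosomes)
  n_elite <- min(n, round(ga$elite_fraction * n))
  ord <- order(records$fitness)
  elite_idx <- ord[seq_len(n_elite)]
  out_chr <- character(n)
  out_chr[seq_len(n_elite)] <- chromosomes[elite_idx]
  kept_records <- records[elite_idx, , drop = FALSE]

  fill <- n - n_elite
  if (fill > 0) {
    parents <- select_parents(records$fitness, 2L * fill, method = ga$selection)
    for (s in seq_len(fill)) {
      pa <- chromosomes[parents[2L * s - 1L]]
      pb <- chromosomes[parents[2L * s]]
      child <- pa
      ga_cx <- stats::runif(1) < ga$crossover_rate
      ga_mu <- stats::runif(1) < ga$mutation_rate
      g <- parse_smiles(child, molecular)
      if (ga_cx) {
        kids <- crossover_molecules(g, parse_smiles(pb, molecular), operators)
        g <- kids[[1]]
      }
      if (ga_mu) g <- mutate_molecule(g, operators)
      out_chr[n_elite + s] <- write_smiles(g)
    }
  }
  if (isTRUE(ga$rescore_elites)) {
    recs <- evaluate_population(out_chr, scorer, molecular, adme, constraints,
                                NULL)
  } else {
    new_records <- evaluate_population(out_chr[seq_len(n) > n_elite], scorer,
                                       molecular, adme, constraints, cache)
    recs <- rbind(kept_records, new_records)
  }
  rownames(recs) <- NULL
  list(chromosomes = out_chr, records = recs)
}

evaluate_population <- function(chromosomes, scorer, molecular, adme,
                                constraints, cache = NULL) {
  if (!length(chromosomes)) {
    return(failure_record("x")[0, , drop = FALSE])
  }
  use_cache <- !is.null(cache) && isTRUE(scorer$deterministic)
  rows <- vector("list", length(chromosomes))
  todo <- integer(0)
  for (i in seq_along(chromosomes)) {
    key <- chromosomes[i]
    if (use_cache && !is.null(cache[[key]])) {
      rows[[i]] <- cache[[key]]
    } else {
      todo <- c(todo, i)
    }
  }
  if (length(todo)) {
    fresh <- evaluate_fitness(chromosomes[todo], scorer, molecular, adme,
                              constraints)
    for (k in seq_along(todo)) {
      row <- fresh[k, , drop = FALSE]
      rows[[todo[k]]] <- row
      if (use_cache) cache[[chromosomes[todo[k]]]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

generation_record <- function(gen, chromosomes, records) {
  list(generation = gen,
       chromosomes = chromosomes,
       fitness = records$fitness,
       records = records,
       best_fitness = min(records$fitness),
       mean_fitness = mean(records$fitness))
}

#' Run the genetic algorithm
#'
#' Evaluates the initial population, then iterates selection, elitism,
#' crossover, mutation and evaluation until `generations` is reached or the
#' best fitness has improved by less than `tol_fun` over `stall_gen_limit`
#' generations. Every generation is appended to the history and, when
#' `checkpoint_path` is given, checkpointed (including the RNG state) so an
#' interrupted run restarts identically via [resume_ga()].
#'
#' @param population character vector of SMILES chromosomes, or a file path
#'   readable by [load_population()].
#' @param scorer a scorer object.
#' @param ga a [ga_config()]; its `seed` seeds the run.
#' @param operators an [operator_config()].
#' @param adme an [adme_config()].
#' @param constraints constraint list as in [evaluate_fitness()].
#' @param checkpoint_path optional checkpoint file, rewritten each generation.
#' @param trace print a per-generation best/mean line.
#' @param plot_file optional png of best/mean fitness per generation.
#' @return an object of class `run_history`.
#' @export
run_ga <- function(population, scorer, ga = ga_config(),
                   operators = operator_config(),
                   adme = adme_config(), constraints = list(),
                   checkpoint_path = NULL, trace = FALSE, plot_file = NULL) {
  molecular <- operators$molecular
  if (length(population) == 1 && file.exists(population)) {
    population <- load_population(population, molecular)
  }
  set.seed(ga$seed)
  cache <- new.env(parent = emptyenv())
  records <- evaluate_population(population, scorer, molecular, adme,
                                 constraints, cache)
  history <- list(generations = list(generation_record(0L, population, records)),
                  ga = ga, molecular = molecular, adme = adme,
                  scorer_identity = scorer$identity)
  class(history) <- "run_history"
  run_ga_loop(history, scorer, operators, adme, constraints, cache,
              checkpoint_path, trace, plot_file)
}

run_ga_loop <- function(history, scorer, operators, adme, constraints, cache,
                        checkpoint_path, trace = FALSE, plot_file = NULL) {
  ga <- history$ga
  molecular <- history$molecular
  gens <- history$generations
  cur <- gens[[length(gens)]]
  chromosomes <- cur$chromosomes
  records <- cur$records
  best_seq <- vapply(gens, `[[`, 0, "best_fitness")
  start_gen <- cur$generation + 1L
  if (start_gen <= ga$generations) {
    for (g in start_gen:ga$generations) {
      step <- next_generation(chromosomes, records, scorer, ga, operators,
                              molecular, adme, constraints, cache)
      chromosomes <- step$chromosomes
      records <- step$records
      gens[[length(gens) + 1L]] <- generation_record(g, chromosomes, records)
      best_seq <- c(best_seq, min(records$fitness))
      if (trace) {
        message(sprintf("gen %3d  best %10.4f  mean %10.4f", g,
                        min(records$fitness), mean(records$fitness)))
      }
      history$generations <- gens
      if (!is.null(checkpoint_path)) {
        save_checkpoint(history, checkpoint_path)
      }
      k <- length(best_seq)
      if (k > ga$stall_gen_limit &&
          (best_seq[k - ga$stall_gen_limit] - best_seq[k]) < ga$tol_fun) {
        break
      }
    }
  }
  history$generations <- gens
  if (!is.null(checkpoint_path)) save_checkpoint(history, checkpoint_path)
  if (!is.null(plot_file)) plot_history(history, plot_file)
  history
}

#' @export
print.run_history <- function(x, ...) {
  g <- x$generations
  cat(sprintf("<run_history> %d generations, population %d, scorer %s\n",
              length(g) - 1L, length(g[[1]]$chromosomes), x$scorer_identity))
  cat(sprintf("  best fitness: %.4f  (generation %d)\n",
              min(vapply(g, `[[`, 0, "best_fitness")),
              which.min(vapply(g, `[[`, 0, "best_fitness")) - 1L))
  invisible(x)
}

#' Best/mean fitness trace of a run
#' @param history a `run_history`.
#' @return data.frame with generation, best, mean.
#' @export
fitness_trace <- function(history) {
  data.frame(generation = vapply(history$generations, `[[`, 0L, "generation"),
             best = vapply(history$generations, `[[`, 0, "best_fitness"),
             mean = vapply(history$generations, `[[`, 0, "mean_fitness"))
}

plot_history <- function(history, path) {
  tr <- fitness_trace(history)
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  plot(tr$generation, tr$mean, type = "l", col = "grey40",
       xlab = "generation", ylab = "fitness",
       ylim = range(c(tr$best, tr$mean)),
       main = "Population fitness (lower is better)")
  graphics::lines(tr$generation, tr$best, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("mean", "best"),
                   col = c("grey40", "firebrick"), lwd = c(1, 2), bty = "n")
  invisible(path)
}

checkpoint_format <- "evoligand-checkpoint"
checkpoint_version <- 1L

#' Checkpoint a run history (with RNG state) to a file
#'
#' The checkpoint is a versioned serialized object containing the full
#' history and the RNG state at the moment of saving, so a resumed run
#' continues with the identical random stream.
#'
#' @param history a `run_history`.
#' @param path destination file.
#' @return invisibly, the path.
#' @export
save_checkpoint <- function(history, path) {
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  obj <- list(format = checkpoint_format, version = checkpoint_version,
              history = history, rng_state = rng)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint
#' @param path checkpoint file.
#' @return list with `history` and `rng_state`.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    mol_error(sprintf("corrupt checkpoint '%s': %s", path, conditionMessage(e)),
              "checkpoint_error")
  })
  if (!is.list(obj) || !identical(obj$format, checkpoint_format)) {
    mol_error(sprintf("'%s' is not a checkpoint file", path), "checkpoint_error")
  }
  if (!identical(obj$version, checkpoint_version)) {
    mol_error(sprintf("checkpoint version %s not supported (expected %d)",
                      obj$version, checkpoint_version), "checkpoint_error")
  }
  obj
}

#' Resume an interrupted run from a checkpoint
#'
#' Restores the stored RNG state and continues the generational loop; with
#' the same scorer and configs the continuation is identical to the
#' uninterrupted run.
#'
#' @param checkpoint_path checkpoint written by [run_ga()].
#' @param scorer the scorer used by the original run.
#' @param operators an [operator_config()] (must match the original run).
#' @param constraints constraint list of the original run.
#' @param trace,plot_file as in [run_ga()].
#' @return the completed `run_history`.
#' @export
resume_ga <- function(checkpoint_path, scorer,
                      operators = operator_config(),
                      constraints = list(), trace = FALSE, plot_file = NULL) {
  cp <- load_checkpoint(checkpoint_path)
  history <- cp$history
  if (!is.null(cp$rng_state)) {
    assign(".Random.seed", cp$rng_state, envir = globalenv())
  }
  operators$molecular <- history$molecular
  cache <- new.env(parent = emptyenv())
  run_ga_loop(history, scorer, operators, history$adme, constraints, cache,
              checkpoint_path, trace, plot_file)
}
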