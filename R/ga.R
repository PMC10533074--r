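#' Genetic-algorithm configuration
#'
#' Defaults follow the published search setting: 5 generations, population
#' size 10, 5 best parents kept, crossover rate 0.5, mutation rate 0.1, and
#' a 20-epoch training budget per fitness evaluation.
#'
#' @param generations Number of generations `G`.
#' @param population_size Population size `L`.
#' @param n_best_parents Elite parent count `K` (`0 < K < L`; `K >= 2` so
#'   offspring pairs exist).
#' @param crossover_rate Probability of performing the tail swap per pair.
#' @param mutation_rate Per-gene resampling probability.
#' @param epochs_per_eval Training epochs per fitness evaluation.
#' @param master_seed Seed governing the whole run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(generations = 5L, population_size = 10L,
                      n_best_parents = 5L, crossover_rate = 0.5,
                      mutation_rate = 0.1, epochs_per_eval = 20L,
                      master_seed = 1L) {
  cfg <- structure(list(
    generations = as.integer(generations),
    population_size = as.integer(population_size),
    n_best_parents = as.integer(n_best_parents),
    crossover_rate = crossover_rate,
    mutation_rate = mutation_rate,
    epochs_per_eval = as.integer(epochs_per_eval),
    master_seed = as.integer(master_seed)
  ), class = "ga_config")
  if (cfg$n_best_parents <= 0L ||
      cfg$n_best_parents >= cfg$population_size) {
    stop("need 0 < n_best_parents < population_size", call. = FALSE)
  }
  if (cfg$n_best_parents < 2L) {
    stop("n_best_parents must be at least 2 to form offspring pairs",
         call. = FALSE)
  }
  if (cfg$crossover_rate < 0 || cfg$crossover_rate > 1 ||
      cfg$mutation_rate < 0 || cfg$mutation_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  # offspring count 2(K-1) must be able to fill the L-K vacancies
  if (2L * (cfg$n_best_parents - 1L) <
      cfg$population_size - cfg$n_best_parents) {
    stop("offspring shortfall: 2*(K-1) < L-K for K = ", cfg$n_best_parents,
         ", L = ", cfg$population_size, call. = FALSE)
  }
  if (cfg$generations < 1L || cfg$epochs_per_eval < 1L) {
    stop("generations and epochs_per_eval must be positive", call. = FALSE)
  }
  cfg
}

new_individual <- function(genome, id, fitness = NA_real_) {
  list(genome = genome, fitness = fitness, id = as.integer(id))
}

pop_fitness <- function(pop) {
  vapply(pop, function(ind) ind$fitness, numeric(1))
}

#' Fitness function from a training/validation split
#'
#' Returns a fitness closure for [run_search()]: each genome is decoded,
#' built and trained for `epochs` epochs with its own optimizer, learning
#' rate and batch size, then scored by pixel accuracy at threshold 0.5 on
#' the validation images. The training seed is derived deterministically
#' from the genome and `master_seed`, so identical genomes always receive
#' identical fitness. Training divergence (non-finite loss) degrades to
#' fitness 0 with a warning.
#'
#' @param train_images,train_masks Training split.
#' @param val_images,val_masks Validation split.
#' @param epochs Training epochs per evaluation.
#' @param master_seed Base seed folded into each genome's training seed.
#' @return A `function(genome) -> fitness in [0, 1]`.
#' @export
training_fitness <- function(train_images, train_masks, val_images,
                             val_masks, epochs = 20L, master_seed = 1L) {
  stopifnot(length(train_images) == length(train_masks),
            length(val_images) == length(val_masks),
            length(train_images) > 0L, length(val_images) > 0L)
  in_ch <- n_channels_of(train_images[[1]])
  function(g) {
    arch <- decode_architecture(g, in_channels = in_ch)
    fit <- tryCatch(
      train_network(arch, train_images, train_masks,
                    epochs = epochs, seed = genome_hash(g, master_seed)),
      error = function(e) {
        warning("training failed (", conditionMessage(e),
                "); fitness set to 0", call. = FALSE)
        NULL
      })
    if (is.null(fit)) return(0)
    if (fit$diverged) {
      warning("training diverged; fitness set to 0", call. = FALSE)
      return(0)
    }
    mean_pixel_accuracy(fit$network, val_images, val_masks)
  }
}

#' Evaluate all unscored individuals of a population
#'
#' Applies `fitness_fn` to every individual whose fitness is unset; cached
#' fitness values (elite parents carried over) are never recomputed.
#'
#' @param pop List of individuals.
#' @param fitness_fn `function(genome) -> fitness in [0, 1]`.
#' @return The population with all fitness values set.
#' @export
evaluate_population <- function(pop, fitness_fn) {
  for (i in seq_along(pop)) {
    if (is.na(pop[[i]]$fitness)) {
      f <- fitness_fn(pop[[i]]$genome)
      stopifnot(is.finite(f), f >= 0, f <= 1)
      pop[[i]]$fitness <- f
    }
  }
  pop
}

#' Select the K fittest individuals
#'
#' Stable sort by fitness descending, ties broken by smaller (older)
#' individual id, so selection is fully reproducible.
#'
#' @param pop Fully evaluated population.
#' @param k Number of parents to keep.
#' @return The `k` best individuals, fitness-descending.
#' @export
select_best <- function(pop, k) {
  f <- pop_fitness(pop)
  if (anyNA(f)) stop("population has unevaluated individuals", call. = FALSE)
  stopifnot(k >= 1L, k <= length(pop))
  ids <- vapply(pop, function(ind) ind$id, integer(1))
  pop[order(-f, ids)][seq_len(k)]
}

#' Single-point crossover of two genomes
#'
#' With probability `rate`, draws a cut point uniformly between genes 1 and
#' 9 and exchanges the gene tails of the two parents; both children are
#' repaired back into the search space. Otherwise returns copies of the
#' parents.
#'
#' @param p1,p2 Parent genomes.
#' @param rate Crossover probability.
#' @param space Search space for repair.
#' @param cut Optional fixed cut point in `1:9` (testing hook); `NULL` draws
#'   at random.
#' @return A list of two valid genomes.
#' @export
crossover_pair <- function(p1, p2, rate = 0.5, space = search_space(),
                           cut = NULL) {
  if (is.null(cut)) {
    if (stats::runif(1) >= rate) return(list(p1, p2))
    cut <- sample.int(9L, 1L)
  }
  v1 <- as.numeric(p1)
  v2 <- as.numeric(p2)
  tail_idx <- (cut + 1L):10L
  c1 <- v1; c1[tail_idx] <- v2[tail_idx]
  c2 <- v2; c2[tail_idx] <- v1[tail_idx]
  list(repair_genome(c1, space), repair_genome(c2, space))
}

#' Per-gene mutation
#'
#' Each gene is independently resampled from its domain with probability
#' `rate` (log-uniformly for the learning rate); the result is repaired, so
#' mutation is closed over valid genomes.
#'
#' @param g Genome to mutate.
#' @param rate Per-gene mutation probability.
#' @param space Search space.
#' @return A valid genome.
#' @export
mutate_genome <- function(g, rate = 0.1, space = search_space()) {
  if (rate <= 0) return(g)
  v <- as.numeric(g)
  hit <- stats::runif(10L) < rate
  if (!any(hit)) return(g)
  doms <- list(space$blocks_domain, space$filters_domain,
               space$kernel_domain, space$activation_domain,
               space$pooling_domain, space$bn_domain, space$dropout_domain,
               space$optimizer_domain, NULL, space$batch_domain)
  for (i in which(hit)) {
    v[i] <- if (i == 9L) {
      exp(stats::runif(1, log(space$lr_range[1]), log(space$lr_range[2])))
    } else {
      dom <- doms[[i]]
      dom[sample.int(length(dom), 1L)]
    }
  }
  repair_genome(v, space)
}

#' Generate the offspring population
#'
#' The `K` sorted parents form `K - 1` successive overlapping pairs (1,2),
#' (2,3), ..., (K-1,K); each pair undergoes [crossover_pair()] and both
#' children are then mutated, yielding `2(K-1)` offspring with fresh ids and
#' unset fitness.
#'
#' @param parents Fitness-sorted elite parents (length `K >= 2`).
#' @param config A `ga_config`.
#' @param space Search space.
#' @param next_id First id to assign to the offspring.
#' @return A list of `2(K-1)` individuals.
#' @export
generate_offspring <- function(parents, config, space = search_space(),
                               next_id = 1L) {
  k <- length(parents)
  if (k < 2L) stop("need at least two parents", call. = FALSE)
  offspring <- list()
  for (i in seq_len(k - 1L)) {
    kids <- crossover_pair(parents[[i]]$genome, parents[[i + 1L]]$genome,
                           config$crossover_rate, space)
    for (kid in kids) {
      kid <- mutate_genome(kid, config$mutation_rate, space)
      offspring[[length(offspring) + 1L]] <-
        new_individual(kid, id = next_id)
      next_id <- next_id + 1L
    }
  }
  offspring
}

#' Elitist environmental selection
#'
#' Forms the next generation from the `K` best of the current population
#' plus the `|Pt| - K` best offspring, keeping population size constant.
#' Elites retain their cached fitness, so the best fitness never decreases.
#'
#' @param pop Current population `Pt` (fully evaluated).
#' @param offspring Offspring population `Qt` (fully evaluated).
#' @param k Number of elites kept.
#' @return The next population, same size as `pop`.
#' @export
environmental_selection <- function(pop, offspring, k) {
  n_fill <- length(pop) - k
  if (length(offspring) < n_fill) {
    stop("not enough offspring (", length(offspring), ") to fill ", n_fill,
         " slots", call. = FALSE)
  }
  c(select_best(pop, k), select_best(offspring, n_fill))
}

#' Run the architecture search
#'
#' The full generational loop: initialize `L` random genomes; for each of
#' `G` generations evaluate the population, keep the `K` fittest as parents,
#' breed `2(K-1)` offspring by successive-pair crossover and per-gene
#' mutation, evaluate them, and apply elitist environmental selection. The
#' best individual ever seen is returned together with a per-generation log.
#'
#' @param config A [ga_config()].
#' @param fitness_fn `function(genome) -> [0, 1]`; typically
#'   [training_fitness()], or any deterministic surrogate.
#' @param space Search space to sample and mutate in.
#' @return A list of class `ga_result` with `best` (individual), `log`
#'   (data.frame: generation, best_fitness, mean_fitness, evaluations,
#'   best_genome), and `population` (final generation).
#' @export
#' @examples
#' cheap <- function(g) 1 / (1 + count_parameters(g) / 1e5)
#' res <- run_search(ga_config(generations = 3, master_seed = 42), cheap)
#' res$log$best_fitness
run_search <- function(config, fitness_fn, space = search_space()) {
  stopifnot(inherits(config, "ga_config"), is.function(fitness_fn))
  validate_search_space(space)
  with_local_seed(config$master_seed, {
    next_id <- 1L
    pop <- lapply(seq_len(config$population_size), function(i) {
      new_individual(sample_genome(space), id = i)
    })
    next_id <- config$population_size + 1L
    evals <- 0L
    log_rows <- vector("list", config$generations)
    best <- NULL
    for (t in seq_len(config$generations)) {
      n_new <- sum(is.na(pop_fitness(pop)))
      pop <- evaluate_population(pop, fitness_fn)
      evals <- evals + n_new
      parents <- select_best(pop, config$n_best_parents)
      offspring <- generate_offspring(parents, config, space,
                                      next_id = next_id)
      next_id <- next_id + length(offspring)
      offspring <- evaluate_population(offspring, fitness_fn)
      evals <- evals + length(offspring)
      pop <- environmental_selection(pop, offspring,
                                     config$n_best_parents)
      gen_best <- select_best(pop, 1L)[[1L]]
      if (is.null(best) || gen_best$fitness > best$fitness) best <- gen_best
      log_rows[[t]] <- data.frame(
        generation = t,
        best_fitness = best$fitness,
        mean_fitness = mean(pop_fitness(pop)),
        evaluations = evals,
        best_genome = jsonlite::toJSON(unclass(best$genome),
                                       auto_unbox = TRUE, digits = NA),
        stringsAsFactors = FALSE)
    }
    structure(list(best = best, log = do.call(rbind, log_rows),
                   population = pop, config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("architecture search result (", nrow(x$log), " generations, ",
      x$log$evaluations[nrow(x$log)], " evaluations)\n", sep = "")
  cat("best fitness:", format(x$best$fitness), "\n")
  print(x$best$genome)
  invisible(x)
}
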