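make_pop <- function(fitness, ids = seq_along(fitness)) {
  lapply(seq_along(fitness), function(i) {
    list(genome = genome(3, 2, 3), fitness = fitness[i],
         id = as.integer(ids[i]))
  })
}

test_that("select_best sorts by fitness with id tie-breaks", {
  pop <- make_pop(c(0.2, 0.9, 0.5))
  best <- select_best(pop, 2)
  expect_equal(sapply(best, `[[`, "fitness"), c(0.9, 0.5))

  tied <- make_pop(c(0.5, 0.5, 0.5), ids = c(3, 1, 2))
  expect_equal(sapply(select_best(tied, 2), `[[`, "id"), c(1L, 2L))

  full <- select_best(pop, 3)
  expect_equal(sapply(full, `[[`, "fitness"), c(0.9, 0.5, 0.2))
  expect_error(select_best(make_pop(c(0.1, NA)), 1), "unevaluated")
})

test_that("single-point crossover swaps gene tails and stays valid", {
  p1 <- lung_genome()
  p2 <- liver_genome()
  kids <- crossover_pair(p1, p2, cut = 5)
  # genes 6-10 exchanged
  expect_equal(as.numeric(kids[[1]]), c(5, 8, 5, 2, 1, 1, 0, 3, 1e-4, 4))
  expect_equal(as.numeric(kids[[2]]), c(7, 8, 4, 1, 1, 0, 0, 3, 1e-4, 8))

  set.seed(3)
  same <- crossover_pair(p1, p1, rate = 1)
  expect_equal(same[[1]], p1)
  expect_equal(same[[2]], p1)

  set.seed(4)
  none <- crossover_pair(p1, p2, rate = 0)
  expect_equal(none[[1]], p1)
  expect_equal(none[[2]], p2)

  set.seed(5)
  for (i in 1:30) {
    kids <- crossover_pair(sample_genome(), sample_genome(), rate = 1)
    expect_silent(validate_genome(kids[[1]]))
    expect_silent(validate_genome(kids[[2]]))
  }
})

test_that("mutation is identity at rate 0 and closed at rate 1", {
  g <- lung_genome()
  expect_equal(mutate_genome(g, rate = 0), g)
  set.seed(6)
  for (i in 1:200) {
    m <- mutate_genome(sample_genome(), rate = 1)
    expect_silent(validate_genome(m))
    expect_true(m$n_blocks %% 2L == 1L)
  }
})

test_that("observed per-gene mutation frequency matches the resampling model", {
  # From a fixed start genome, a gene visibly changes when it is hit (prob
  # `rate`) AND the uniform redraw lands on a different value. Change
  # probabilities per gene, given domains {3..7 with even->odd repair},
  # {2,4,8}, {3..7}, {1,2,3}, {1,2}, {0,1}, {0,1}, {1..4}, continuous LR,
  # {4,8,16,32} and start (5,8,5,2,1,0,0,3,5e-4,8):
  g0 <- genome(5, 8, 5, activation = 2, pooling = 1, batch_norm = 0,
               dropout = 0, optimizer = 3, learning_rate = 5e-4,
               batch_size = 8)
  rate <- 0.3
  p_change <- rate * c(3 / 5, 2 / 3, 4 / 5, 2 / 3, 1 / 2, 1 / 2, 1 / 2,
                       3 / 4, 1, 3 / 4)
  n <- 1000
  set.seed(8)
  changed <- numeric(10)
  for (i in seq_len(n)) {
    m <- mutate_genome(g0, rate = rate)
    changed <- changed + (as.numeric(m) != as.numeric(g0))
  }
  expected <- n * sum(p_change)
  sd3 <- 3 * sqrt(sum(n * p_change * (1 - p_change)))
  expect_lt(abs(sum(changed) - expected), sd3)
})

test_that("offspring generation uses successive pairs, yielding 2(K-1) children", {
  set.seed(9)
  parents <- lapply(1:5, function(i) {
    list(genome = sample_genome(), fitness = 1 - i / 10, id = i)
  })
  cfg <- ga_config(master_seed = 1)
  q <- generate_offspring(parents, cfg, next_id = 100L)
  expect_length(q, 8L)
  expect_equal(sapply(q, `[[`, "id"), 100:107)
  expect_true(all(is.na(sapply(q, `[[`, "fitness"))))
  for (kid in q) expect_silent(validate_genome(kid$genome))

  q2 <- generate_offspring(parents[1:2], cfg)
  expect_length(q2, 2L)
  expect_error(generate_offspring(parents[1], cfg), "two parents")
})

test_that("environmental selection keeps elites plus the best offspring", {
  pt <- make_pop(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  qt <- make_pop(c(0.85, 0.65, 0.30, 0.20), ids = 7:10)
  nxt <- environmental_selection(pt, qt, k = 3)
  expect_length(nxt, 6L)
  expect_setequal(sapply(nxt, `[[`, "fitness"),
                  c(0.9, 0.8, 0.7, 0.85, 0.65, 0.30))
  expect_gte(max(sapply(nxt, `[[`, "fitness")),
             max(sapply(pt, `[[`, "fitness")))
  # boundary: exactly enough offspring admits them all
  nxt2 <- environmental_selection(pt, qt, k = 2)
  expect_setequal(sapply(nxt2, `[[`, "fitness"),
                  c(0.9, 0.8, 0.85, 0.65, 0.30, 0.20))
  expect_error(environmental_selection(pt, qt[1:1], k = 3),
               "not enough offspring")
})

test_that("evaluate_population never recomputes cached fitness", {
  calls <- 0L
  fn <- function(g) {
    calls <<- calls + 1L
    0.5
  }
  pop <- make_pop(c(0.9, NA, NA))
  pop <- evaluate_population(pop, fn)
  expect_equal(calls, 2L)
  expect_equal(sapply(pop, `[[`, "fitness"), c(0.9, 0.5, 0.5))
  evaluate_population(pop, fn)
  expect_equal(calls, 2L)
})

test_that("the search loop conserves population size, is elitist and reproducible", {
  surrogate <- function(g) 1 / (1 + count_parameters(g) / 1e5)
  cfg <- ga_config(generations = 4, population_size = 6, n_best_parents = 3,
                   master_seed = 77)
  r1 <- run_search(cfg, surrogate)
  r2 <- run_search(cfg, surrogate)
  expect_equal(r1$best$genome, r2$best$genome)
  expect_length(r1$population, 6L)
  expect_true(all(diff(r1$log$best_fitness) >= 0))
  expect_equal(nrow(r1$log), 4L)
  # generation 1 evaluates the full population plus 2(K-1) offspring;
  # later generations only evaluate the fresh offspring (elites are cached)
  expect_equal(r1$log$evaluations, cumsum(c(6 + 4, rep(4, 3))))
  for (ind in r1$population) expect_silent(validate_genome(ind$genome))
})

test_that("selection pressure finds smaller models than random sampling", {
  surrogate <- function(g) 1 / (1 + count_parameters(g))
  cfg <- ga_config(generations = 10, population_size = 10,
                   n_best_parents = 5, master_seed = 13)
  res <- run_search(cfg, surrogate)
  best_count <- count_parameters(res$best$genome)
  set.seed(14)
  random_counts <- replicate(100, count_parameters(sample_genome()))
  expect_lte(best_count, median(random_counts))
})

test_that("identical genomes receive identical training fitness", {
  ds <- tiny_dataset(n = 10, size = 16)
  fn <- training_fitness(ds$images[1:7], ds$masks[1:7], ds$images[8:10],
                         ds$masks[8:10], epochs = 1, master_seed = 5)
  g <- genome(3, 2, 3, learning_rate = 1e-3)
  pop <- list(list(genome = g, fitness = NA_real_, id = 1L),
              list(genome = g, fitness = NA_real_, id = 2L))
  pop <- evaluate_population(pop, fn)
  f <- sapply(pop, `[[`, "fitness")
  expect_equal(f[1], f[2])
  expect_true(all(f >= 0 & f <= 1))
})

test_that("all-background validation with an all-background predictor scores 1", {
  blank_img <- matrix(0, 16, 16)
  blank_mask <- matrix(0, 16, 16)
  fn <- training_fitness(list(blank_img), list(blank_mask),
                         list(blank_img), list(blank_mask),
                         epochs = 2, master_seed = 3)
  g <- genome(3, 2, 3, learning_rate = 1e-3)
  # an all-zero input with Dice loss drives predictions to background
  expect_equal(fn(g), 1)
})

test_that("configuration errors are raised eagerly", {
  expect_error(ga_config(population_size = 4, n_best_parents = 4),
               "n_best_parents < population_size")
  expect_error(ga_config(population_size = 10, n_best_parents = 1),
               "at least 2")
  expect_error(ga_config(crossover_rate = 1.5), "rates")
  expect_error(ga_config(population_size = 10, n_best_parents = 3),
               "offspring shortfall")
})
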