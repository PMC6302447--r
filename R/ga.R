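# Genetic algorithm over the probability simplex, maximizing the AUC of a
# weighted-average ensemble. Chromosomes are real weight vectors repaired to
# the simplex (clip at zero, renormalize); selection is fitness-proportional
# roulette; crossover is a convex (arithmetic) combination, which keeps
# children on the simplex by construction; mutation adds Gaussian noise then
# repairs. Crossover/mutation probabilities adapt to each chromosome's
# fitness relative to the population mean and maximum, and elitism carries
# the best chromosome unchanged, which makes the best fitness monotone
# non-decreasing across generations.

#' Genetic algorithm configuration
#'
#' @param population_size number of chromosomes (default 100; must be at
#'   least the number of base predictors so the simplex corners can seed
#'   the initial population).
#' @param generations number of update generations (default 200).
#' @param seed integer seed.
#' @param elitism number of top chromosomes carried over unchanged (>= 1
#'   keeps the best-fitness trajectory monotone).
#' @param crossover_bounds,mutation_bounds `c(min, max)` probability bounds
#'   for the adaptive operator schedule: a chromosome at or below the
#'   population-mean fitness uses the max probability, the population best
#'   uses the min, with linear interpolation in between.
#' @param mutation_sd standard deviation of the Gaussian mutation noise.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 200L, seed = 1L,
                      elitism = 1L, crossover_bounds = c(0.6, 0.95),
                      mutation_bounds = c(0.02, 0.25), mutation_sd = 0.1) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  if (population_size < 2L) stop("population_size must be >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  if (elitism < 0L || elitism >= population_size) stop("invalid elitism count")
  stopifnot(length(crossover_bounds) == 2L, length(mutation_bounds) == 2L,
            diff(crossover_bounds) >= 0, diff(mutation_bounds) >= 0)
  structure(list(population_size = population_size, generations = generations,
                 seed = as.integer(seed), elitism = as.integer(elitism),
                 crossover_bounds = crossover_bounds,
                 mutation_bounds = mutation_bounds,
                 mutation_sd = mutation_sd),
            class = "ga_config")
}

#' Validate / construct an ensemble weight vector
#'
#' Weights must be non-negative and sum to 1 (tolerance 1e-9).
#'
#' @param w numeric vector.
#' @return `w`, with class `weight_vector`.
#' @export
weight_vector <- function(w) {
  w <- as.numeric(w)
  if (any(w < -1e-12)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  structure(pmax(w, 0), class = "weight_vector")
}

# clip-at-zero + renormalize repair; all-zero chromosomes become uniform
repair_simplex <- function(w) {
  w <- pmax(w, 0)
  s <- sum(w)
  if (s <= 0) rep(1 / length(w), length(w)) else w / s
}

# linear adaptive schedule between bounds, driven by fitness rank position
adaptive_rate <- function(fitness, bounds) {
  f_mean <- mean(fitness)
  f_max <- max(fitness)
  p <- rep(bounds[2L], length(fitness))
  if (f_max > f_mean + 1e-15) {
    above <- fitness > f_mean
    frac <- (fitness[above] - f_mean) / (f_max - f_mean)
    p[above] <- bounds[2L] - diff(bounds) * frac
  }
  p
}

#' One generation of the GA
#'
#' Selection (fitness-proportional), adaptive arithmetic crossover,
#' adaptive Gaussian mutation with simplex repair, then elitist
#' replacement. Uses the current RNG state (seed upstream).
#'
#' @param population matrix, one simplex chromosome per row.
#' @param fitness fitness value per chromosome (higher is better).
#' @param config a [ga_config()].
#' @return matrix of the same shape: the next population, rows 1..elitism
#'   holding the preserved elite.
#' @export
ga_step <- function(population, fitness, config) {
  pop_n <- nrow(population)
  stopifnot(length(fitness) == pop_n)
  sel_w <- fitness - min(fitness) + 1e-12
  parents <- sample.int(pop_n, 2L * pop_n, replace = TRUE, prob = sel_w)
  pc <- adaptive_rate(fitness, config$crossover_bounds)
  pm <- adaptive_rate(fitness, config$mutation_bounds)
  children <- matrix(0, pop_n, ncol(population))
  for (i in seq_len(pop_n)) {
    p1 <- parents[2L * i - 1L]; p2 <- parents[2L * i]
    child <- if (runif(1) < max(pc[p1], pc[p2])) {
      a <- runif(1)
      a * population[p1, ] + (1 - a) * population[p2, ]
    } else {
      population[p1, ]
    }
    if (runif(1) < max(pm[p1], pm[p2])) {
      child <- child + rnorm(length(child), sd = config$mutation_sd)
    }
    children[i, ] <- repair_simplex(child)
  }
  if (config$elitism > 0L) {
    elite <- order(fitness, decreasing = TRUE)[seq_len(config$elitism)]
    children[seq_len(config$elitism), ] <- population[elite, , drop = FALSE]
  }
  children
}

#' Optimize ensemble weights by genetic algorithm
#'
#' Searches the simplex of weight vectors for the combination of base
#' predictor probabilities maximizing AUC on the fitness set. The initial
#' population contains the N simplex corners (each single predictor alone),
#' so the result can never score below the best single predictor, plus
#' random Dirichlet draws; elitism keeps the best-so-far fitness monotone
#' non-decreasing.
#'
#' @param scores numeric matrix (instances x predictors) of base predictor
#'   probabilities on the fitness set, or a list of `base_predictor`s whose
#'   stored training probabilities are used.
#' @param labels binary labels of the fitness set.
#' @param config a [ga_config()].
#' @return a [weight_vector()] with attributes `fitness` (final AUC) and
#'   `trace` (data.frame: generation, best, mean fitness).
#' @export
ga_optimize_weights <- function(scores, labels, config = ga_config()) {
  if (is.list(scores) && all(vapply(scores, inherits, logical(1), "base_predictor"))) {
    scores <- do.call(cbind, lapply(scores, `[[`, "train_proba"))
  }
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  stopifnot(nrow(scores) == length(labels))
  if (length(unique(labels)) < 2L) stop("fitness data must contain both classes")
  n_pred <- ncol(scores)
  if (n_pred == 1L) {
    return(structure(weight_vector(1),
                     fitness = roc_auc(labels, scores[, 1L]), trace = NULL))
  }
  if (config$population_size < n_pred) {
    stop(sprintf("population_size (%d) must be >= number of predictors (%d) for corner seeding",
                 config$population_size, n_pred))
  }
  set.seed(config$seed)
  pop <- diag(n_pred)
  extra <- config$population_size - n_pred
  if (extra > 0L) {
    g <- matrix(-log(runif(extra * n_pred)), extra, n_pred)  # Dirichlet(1)
    pop <- rbind(pop, g / rowSums(g))
  }
  fit_fun <- function(w) roc_auc(labels, drop(scores %*% w))
  fitness <- apply(pop, 1L, fit_fun)
  trace <- data.frame(generation = 0L, best = max(fitness), mean = mean(fitness))
  for (gen in seq_len(config$generations)) {
    pop <- ga_step(pop, fitness, config)
    fitness <- apply(pop, 1L, fit_fun)
    trace <- rbind(trace, data.frame(generation = gen, best = max(fitness),
                                     mean = mean(fitness)))
  }
  best <- which.max(fitness)
  structure(weight_vector(repair_simplex(pop[best, ])),
            fitness = fitness[best], trace = trace)
}
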