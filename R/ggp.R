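#' Hyperparameter grammar for the CNN architecture search
#'
#' Option sets for every gene of a CNN genome. Defaults: kernel sizes 1-5,
#' strides 1-3, filters starting at 16 and doubling after every convolution,
#' learning rates on a log grid from 1 to 1e-5, dropout rates {0.1, 0.5, 1},
#' epoch counts {10, 50, 100}, fully connected widths {32, 64, 128, 256,
#' 512}, batch size fixed at 16. The number of convolutional blocks is drawn
#' from `n_conv_range` (a search-space bound the hyperparameter table leaves
#' open; default 1-4).
#'
#' @param n_conv_range Length-2 integer range for the number of conv blocks.
#' @return A `grammar` object.
#' @export
default_grammar <- function(n_conv_range = c(1L, 4L)) {
  g <- list(kernel_sizes = 1:5, strides = 1:3, filter_start = 16L,
            learning_rates = c(1, 0.1, 0.01, 0.001, 1e-4, 1e-5),
            dropout_rates = c(0.1, 0.5, 1), epoch_options = c(10L, 50L, 100L),
            fc_units_options = c(32L, 64L, 128L, 256L, 512L),
            batch_size = 16L,
            n_conv_range = as.integer(n_conv_range))
  stopifnot(all(lengths(g[c("kernel_sizes", "strides", "learning_rates",
                            "dropout_rates", "epoch_options",
                            "fc_units_options")]) > 0))
  structure(g, class = "grammar")
}

# sample from an option set without base sample()'s scalar surprise
pick <- function(set, n = 1L) set[sample.int(length(set), n, replace = TRUE)]

new_genome <- function(n_conv, kernels, strides, learning_rate, dropout_rate,
                       n_epochs, fc_units) {
  structure(list(n_conv = as.integer(n_conv), kernels = as.integer(kernels),
                 strides = as.integer(strides),
                 learning_rate = as.numeric(learning_rate),
                 dropout_rate = as.numeric(dropout_rate),
                 n_epochs = as.integer(n_epochs),
                 fc_units = as.integer(fc_units)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("Genome: %d conv (k=%s, s=%s), lr=%g, dropout=%g, epochs=%d, fc=%d\n",
              x$n_conv, paste(x$kernels, collapse = ","),
              paste(x$strides, collapse = ","), x$learning_rate,
              x$dropout_rate, x$n_epochs, x$fc_units))
  invisible(x)
}

genome_is_valid <- function(genome, grammar, input_shape) {
  ok <- genome$n_conv >= grammar$n_conv_range[1] &&
    genome$n_conv <= grammar$n_conv_range[2] &&
    length(genome$kernels) == genome$n_conv &&
    length(genome$strides) == genome$n_conv &&
    all(genome$kernels %in% grammar$kernel_sizes) &&
    all(genome$strides %in% grammar$strides) &&
    genome$learning_rate %in% grammar$learning_rates &&
    genome$dropout_rate %in% grammar$dropout_rates &&
    genome$n_epochs %in% grammar$epoch_options &&
    genome$fc_units %in% grammar$fc_units_options
  if (!ok) return(FALSE)
  tryCatch({
    genome_to_model(genome, input_shape, warn_dropout = FALSE)
    TRUE
  }, error = function(e) FALSE)
}

#' Sample a random genome from the grammar
#'
#' Rejection-resampled until the induced architecture keeps all spatial
#' dimensions positive on the given input shape.
#'
#' @param grammar A [default_grammar()].
#' @param input_shape `c(H, W, C)` input tensor shape.
#' @param seed Integer seed.
#' @param max_tries Resampling budget before giving up (default 200).
#' @return A `genome`.
#' @export
sample_genome <- function(grammar, input_shape, seed = 1L, max_tries = 200L) {
  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)
  for (try in seq_len(max_tries)) {
    n_conv <- pick(seq(grammar$n_conv_range[1], grammar$n_conv_range[2]))
    g <- new_genome(
      n_conv,
      pick(grammar$kernel_sizes, n_conv),
      pick(grammar$strides, n_conv),
      pick(grammar$learning_rates),
      pick(grammar$dropout_rates),
      pick(grammar$epoch_options),
      pick(grammar$fc_units_options))
    if (genome_is_valid(g, grammar, input_shape)) return(g)
  }
  stop("no valid genome found after ", max_tries,
       " tries (input shape too small for the grammar?)")
}

#' Map a genome to a model spec and training configuration
#'
#' Deterministic: conv blocks are `conv(k, stride) -> batchnorm -> relu ->
#' maxpool(2, 2)` with filter counts 16, 32, 64, ... doubling per block, then
#' flatten, dense(fc_units), dropout, dense(2), softmax. A dropout gene of 1
#' (the grammar contains it, but a literal rate of 1 would zero the layer) is
#' capped to 0.99 with a warning.
#'
#' @param genome A `genome`.
#' @param input_shape `c(H, W, C)`.
#' @param warn_dropout Emit the dropout-cap warning (default TRUE).
#' @return List with `spec` (a `model_spec`) and `config` (a
#'   [train_config()]).
#' @export
genome_to_model <- function(genome, input_shape, warn_dropout = TRUE) {
  stopifnot(inherits(genome, "genome"))
  bad <- character(0)
  if (length(genome$kernels) != genome$n_conv) bad <- c(bad, "kernels")
  if (length(genome$strides) != genome$n_conv) bad <- c(bad, "strides")
  if (any(genome$kernels < 1)) bad <- c(bad, "kernels")
  if (any(genome$strides < 1)) bad <- c(bad, "strides")
  if (genome$dropout_rate <= 0) bad <- c(bad, "dropout_rate")
  if (length(bad))
    stop("invalid genome genes: ", paste(unique(bad), collapse = ", "))
  rate <- genome$dropout_rate
  if (rate >= 1) {
    if (warn_dropout)
      warning("dropout gene 1 capped to rate 0.99 (rate 1 would zero the layer)")
    rate <- 0.99
  }
  layers <- list()
  for (i in seq_len(genome$n_conv)) {
    layers <- c(layers, list(
      layer_conv(genome$kernels[i], genome$strides[i], 16L * 2L^(i - 1L),
                 name = paste0("conv", i)),
      layer_batchnorm(), layer_relu(), layer_maxpool(2L, 2L)))
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(genome$fc_units, name = "fc1"),
                           layer_dropout(rate),
                           layer_dense(2L, name = "logits"),
                           layer_softmax()))
  list(spec = new_model_spec(layers, input_shape),
       config = train_config(learning_rate = genome$learning_rate,
                             dropout_rate = rate,
                             batch_size = 16L,
                             n_epochs = genome$n_epochs))
}

resize_layer_genes <- function(genome, n_conv, grammar) {
  k <- genome$kernels; s <- genome$strides
  while (length(k) < n_conv) {
    k <- c(k, pick(grammar$kernel_sizes))
    s <- c(s, pick(grammar$strides))
  }
  genome$kernels <- k[seq_len(n_conv)]
  genome$strides <- s[seq_len(n_conv)]
  genome$n_conv <- as.integer(n_conv)
  genome
}

#' Genetic operators on genomes
#'
#' `mutate_genome` resamples each gene independently with probability
#' `rate` from its grammar option set (layer gene vectors are resized when the
#' conv-count gene mutates). `crossover_genomes` picks each gene uniformly
#' from one of the two parents. Both resample until the offspring induces a
#' valid architecture.
#'
#' @param genome,g1,g2 Parent genomes.
#' @param rate Per-gene mutation probability in `[0, 1]`.
#' @param grammar The grammar.
#' @param input_shape `c(H, W, C)` used for validity checking.
#' @param seed Integer seed.
#' @return A valid offspring `genome`.
#' @export
mutate_genome <- function(genome, rate, grammar, input_shape, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)
  for (try in 1:200) {
    g <- genome
    if (stats::runif(1) < rate) {
      n_conv <- pick(seq(grammar$n_conv_range[1], grammar$n_conv_range[2]))
      g <- resize_layer_genes(g, n_conv, grammar)
    }
    for (i in seq_len(g$n_conv)) {
      if (stats::runif(1) < rate) g$kernels[i] <- pick(grammar$kernel_sizes)
      if (stats::runif(1) < rate) g$strides[i] <- pick(grammar$strides)
    }
    if (stats::runif(1) < rate) g$learning_rate <- pick(grammar$learning_rates)
    if (stats::runif(1) < rate) g$dropout_rate <- pick(grammar$dropout_rates)
    if (stats::runif(1) < rate) g$n_epochs <- pick(grammar$epoch_options)
    if (stats::runif(1) < rate) g$fc_units <- pick(grammar$fc_units_options)
    if (genome_is_valid(g, grammar, input_shape)) return(g)
  }
  genome  # fall back to the (valid) parent if mutation keeps breaking validity
}

#' @rdname mutate_genome
#' @export
crossover_genomes <- function(g1, g2, grammar, input_shape, seed = 1L) {
  old <- set_local_seed(derive_seed(seed, 0L))
  on.exit(restore_seed(old), add = TRUE)
  for (try in 1:200) {
    n_conv <- if (stats::runif(1) < 0.5) g1$n_conv else g2$n_conv
    pick <- function(a, b) if (stats::runif(1) < 0.5) a else b
    kernels <- integer(n_conv); strides <- integer(n_conv)
    for (i in seq_len(n_conv)) {
      ka <- if (i <= g1$n_conv) g1$kernels[i] else g2$kernels[i]
      kb <- if (i <= g2$n_conv) g2$kernels[i] else g1$kernels[i]
      kernels[i] <- pick(ka, kb)
      sa <- if (i <= g1$n_conv) g1$strides[i] else g2$strides[i]
      sb <- if (i <= g2$n_conv) g2$strides[i] else g1$strides[i]
      strides[i] <- pick(sa, sb)
    }
    g <- new_genome(n_conv, kernels, strides,
                    pick(g1$learning_rate, g2$learning_rate),
                    pick(g1$dropout_rate, g2$dropout_rate),
                    pick(g1$n_epochs, g2$n_epochs),
                    pick(g1$fc_units, g2$fc_units))
    if (genome_is_valid(g, grammar, input_shape)) return(g)
  }
  g1
}

genome_key <- function(genome) {
  paste(genome$n_conv, paste(genome$kernels, collapse = ","),
        paste(genome$strides, collapse = ","), genome$learning_rate,
        genome$dropout_rate, genome$n_epochs, genome$fc_units, sep = "|")
}

#' Evolve CNN architectures by grammar-based genetic programming
#'
#' Generational GA with tournament selection (size 3), uniform crossover
#' (probability 0.9), per-gene mutation (rate 0.1) and elitism. Fitness is
#' supplied by `fitness_fn(genome)` (validation accuracy in the full
#' pipeline); each distinct genome is evaluated at most once (fitness cache),
#' a fitness function error scores the individual 0 and is logged. Ties in
#' fitness are broken toward fewer parameters.
#'
#' @param grammar A [default_grammar()].
#' @param input_shape `c(H, W, C)`.
#' @param fitness_fn Function `genome -> numeric` (higher is better).
#' @param population_size Population size (>= 2; default 10).
#' @param n_generations Number of generations after the initial one
#'   (default 5).
#' @param elitism_k Number of best individuals copied unchanged (>= 1).
#' @param p_crossover Crossover probability (default 0.9).
#' @param mutation_rate Per-gene mutation rate (default 0.1).
#' @param seed Integer seed.
#' @return List with `best` (list `genome`, `fitness`), `history`
#'   (per-generation best/mean fitness), `population`, and `n_evaluations`.
#' @export
evolve <- function(grammar, input_shape, fitness_fn,
                   population_size = 10L, n_generations = 5L,
                   elitism_k = 1L, p_crossover = 0.9, mutation_rate = 0.1,
                   seed = 1L) {
  if (population_size < 2L) stop("'population_size' must be >= 2")
  if (elitism_k < 1L) stop("'elitism_k' must be >= 1")

  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  evaluate <- function(genome) {
    key <- genome_key(genome)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_evals <<- n_evals + 1L
    fit <- tryCatch(as.numeric(fitness_fn(genome)), error = function(e) {
      message("fitness evaluation failed (scored 0): ", conditionMessage(e))
      0
    })
    cache[[key]] <- fit
    fit
  }
  n_params <- function(genome)
    count_params(genome_to_model(genome, input_shape, warn_dropout = FALSE)$spec)
  better <- function(f1, p1, f2, p2) (f1 > f2) || (f1 == f2 && p1 < p2)

  pop <- lapply(seq_len(population_size), function(i)
    sample_genome(grammar, input_shape, seed = derive_seed(seed, 100L + i)))
  fits <- vapply(pop, evaluate, numeric(1))
  pars <- vapply(pop, n_params, numeric(1))

  history <- data.frame(generation = 0L, best = max(fits), mean = mean(fits))
  old <- set_local_seed(derive_seed(seed, 7L))
  on.exit(restore_seed(old), add = TRUE)

  for (gen in seq_len(n_generations)) {
    ord <- order(-fits, pars)
    elite <- pop[ord[seq_len(elitism_k)]]
    tournament <- function() {
      ids <- sample.int(population_size, 3L, replace = TRUE)
      j <- ids[order(-fits[ids], pars[ids])[1]]
      pop[[j]]
    }
    offspring <- elite
    while (length(offspring) < population_size) {
      child_seed <- derive_seed(seed, 10000L * gen + length(offspring) +
                                  sample.int(1000L, 1L))
      if (stats::runif(1) < p_crossover) {
        child <- crossover_genomes(tournament(), tournament(), grammar,
                                   input_shape, seed = child_seed)
      } else {
        child <- tournament()
      }
      child <- mutate_genome(child, mutation_rate, grammar, input_shape,
                             seed = derive_seed(child_seed, 1L))
      offspring[[length(offspring) + 1L]] <- child
    }
    pop <- offspring
    fits <- vapply(pop, evaluate, numeric(1))
    pars <- vapply(pop, n_params, numeric(1))
    history <- rbind(history, data.frame(generation = gen, best = max(fits),
                                         mean = mean(fits)))
  }
  ord <- order(-fits, pars)
  list(best = list(genome = pop[[ord[1]]], fitness = fits[ord[1]]),
       history = history,
       population = pop, fitness = fits, n_evaluations = n_evals)
}

#' Serialize a genome (or search history) as JSON
#'
#' @param genome A `genome`.
#' @param path File path.
#' @return `read_genome` returns the `genome`.
#' @export
write_genome <- function(genome, path) {
  jsonlite::write_json(unclass(genome), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_genome(x$n_conv, x$kernels, x$strides, x$learning_rate, x$dropout_rate,
             x$n_epochs, x$fc_units)
}
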