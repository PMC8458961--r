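shape16 <- c(16L, 16L, 4L)

test_that("sampled genomes respect the grammar option sets", {
  gr <- default_grammar()
  genomes <- lapply(1:1000, function(s) sample_genome(gr, shape16, seed = s))
  ks <- unlist(lapply(genomes, `[[`, "kernels"))
  ss <- unlist(lapply(genomes, `[[`, "strides"))
  expect_true(all(ks %in% 1:5))
  expect_true(all(ss %in% 1:3))
  expect_true(all(vapply(genomes, `[[`, numeric(1), "learning_rate") %in%
                    gr$learning_rates))
  expect_true(all(vapply(genomes, `[[`, integer(1), "fc_units") %in%
                    gr$fc_units_options))
  expect_identical(sample_genome(gr, shape16, seed = 77),
                   sample_genome(gr, shape16, seed = 77))
  # filter doubling rule appears in the induced specs
  g <- genomes[[1]]
  spec <- genome_to_model(g, shape16, warn_dropout = FALSE)$spec
  filt <- vapply(Filter(function(l) l$kind == "conv2d", spec$layers),
                 `[[`, integer(1), "n_filters")
  expect_identical(filt, as.integer(16 * 2^(seq_len(g$n_conv) - 1)))
})

test_that("genome sampling errors on hopeless inputs", {
  gr <- default_grammar(n_conv_range = c(4L, 4L))
  gr$kernel_sizes <- 5L
  gr$strides <- 3L
  expect_error(sample_genome(gr, c(8L, 8L, 2L), seed = 1, max_tries = 20),
               "no valid genome")
})

test_that("genome-to-model mapping is deterministic and mirrors the pinned architecture", {
  g <- neurocam:::new_genome(3L, c(5L, 5L, 5L), c(1L, 1L, 1L), 0.001, 0.5,
                             50L, 64L)
  gm <- genome_to_model(g, c(60L, 73L, 60L))
  pinned <- build_modified_lenet5(c(60, 73, 60), fc_units = 64L)
  strip <- function(s) lapply(s$layers, function(l) l[setdiff(names(l), "name")])
  expect_identical(strip(gm$spec), strip(pinned))
  expect_identical(gm$config$learning_rate, 0.001)
  expect_identical(gm$config$n_epochs, 50L)
  expect_identical(genome_to_model(g, c(60L, 73L, 60L))$spec, gm$spec)

  gdrop <- neurocam:::new_genome(1L, 3L, 1L, 0.01, 1, 10L, 32L)
  expect_warning(gm2 <- genome_to_model(gdrop, shape16), "0.99")
  kinds <- vapply(gm2$spec$layers, `[[`, "", "kind")
  expect_identical(gm2$spec$layers[[which(kinds == "dropout")]]$rate, 0.99)
})

test_that("the genome-to-spec mapping is injective on a small enumerable grammar", {
  combos <- expand.grid(k1 = c(1L, 3L), k2 = c(1L, 3L), s1 = 1:2, s2 = 1:2,
                        fc = c(32L, 64L))
  keys <- apply(combos, 1, function(r) {
    g <- neurocam:::new_genome(2L, c(r[["k1"]], r[["k2"]]),
                               c(r[["s1"]], r[["s2"]]), 0.01, 0.5, 10L,
                               r[["fc"]])
    gm <- genome_to_model(g, shape16, warn_dropout = FALSE)
    paste(jsonlite::toJSON(gm$spec$layers, auto_unbox = TRUE),
          jsonlite::toJSON(unclass(gm$config), auto_unbox = TRUE))
  })
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("mutation and crossover always yield grammar-valid genomes", {
  gr <- default_grammar()
  parents <- lapply(1:20, function(s) sample_genome(gr, shape16, seed = s))
  for (i in 1:2500) {
    p <- parents[[(i %% 20) + 1]]
    q <- parents[[((i + 7) %% 20) + 1]]
    child <- if (i %% 2 == 0)
      mutate_genome(p, 0.3, gr, shape16, seed = i)
    else
      crossover_genomes(p, q, gr, shape16, seed = i)
    expect_true(neurocam:::genome_is_valid(child, gr, shape16))
  }
})

test_that("degenerate operator settings leave genomes unchanged", {
  gr <- default_grammar()
  g <- sample_genome(gr, shape16, seed = 3)
  expect_identical(mutate_genome(g, 0, gr, shape16, seed = 1), g)

  singleton <- default_grammar(n_conv_range = c(2L, 2L))
  singleton$kernel_sizes <- 3L; singleton$strides <- 1L
  singleton$learning_rates <- 0.01; singleton$dropout_rates <- 0.5
  singleton$epoch_options <- 10L; singleton$fc_units_options <- 64L
  gs <- sample_genome(singleton, shape16, seed = 1)
  expect_identical(mutate_genome(gs, 1, singleton, shape16, seed = 9), gs)
  expect_identical(crossover_genomes(g, g, gr, shape16, seed = 5), g)
})

test_that("evolution under elitism is monotone, cached and deterministic", {
  gr <- default_grammar()
  n_calls <- 0L
  seen <- new.env()
  toy_fitness <- function(genome) {
    n_calls <<- n_calls + 1L
    seen[[neurocam:::genome_key(genome)]] <- TRUE
    spec <- genome_to_model(genome, shape16, warn_dropout = FALSE)$spec
    -abs(count_params(spec) - 50000)
  }
  res <- evolve(gr, shape16, toy_fitness, population_size = 8L,
                n_generations = 10L, elitism_k = 1L, seed = 11)
  expect_true(all(diff(res$history$best) >= 0))
  expect_identical(res$best$fitness, max(res$history$best))
  # cache: one evaluation per distinct genome
  expect_lte(n_calls, length(ls(seen)))
  expect_identical(res$n_evaluations, n_calls)

  n_calls <- 0L
  res2 <- evolve(gr, shape16, toy_fitness, population_size = 8L,
                 n_generations = 10L, elitism_k = 1L, seed = 11)
  expect_identical(res2$history, res$history)

  # population of clones: best equals every member's fitness
  singleton <- default_grammar(n_conv_range = c(1L, 1L))
  singleton$kernel_sizes <- 3L; singleton$strides <- 1L
  singleton$learning_rates <- 0.01; singleton$dropout_rates <- 0.5
  singleton$epoch_options <- 10L; singleton$fc_units_options <- 64L
  res3 <- evolve(singleton, shape16, toy_fitness, population_size = 4L,
                 n_generations = 2L, seed = 2)
  expect_identical(res3$history$best, res3$history$mean)
})

test_that("failing fitness evaluations score zero and are logged", {
  gr <- default_grammar()
  expect_message(
    res <- evolve(gr, shape16, function(g) stop("boom"),
                  population_size = 3L, n_generations = 1L, seed = 4),
    "fitness evaluation failed")
  expect_identical(res$best$fitness, 0)
})

test_that("genome JSON round-trips", {
  g <- sample_genome(default_grammar(), shape16, seed = 21)
  path <- tempfile(fileext = ".json")
  write_genome(g, path)
  expect_identical(read_genome(path), g)
  unlink(path)
})
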