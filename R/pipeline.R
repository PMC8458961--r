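# End-to-end orchestration: config loading/validation, stage execution and a
# JSON-lines run log. Single-threaded and deterministic given the config seed.

config_defaults <- function() {
  list(
    data = NULL,                 # existing cohort directory; NULL -> simulate
    out = "neurocam_out",
    seed = 42L,
    shape = c(32L, 32L, 16L),
    n_regions = 10L,
    n_per_group = 16L,
    amplitude = 3,
    target_labels = c(1L, 2L, 3L, 4L),
    baseline = 0,
    noise_sd = 1,
    smooth_sigma = 1,
    channel_axis = "z",
    fractions = c(0.8, 0.1, 0.1),
    augment = 10L,
    learning_rate = 0.001,
    batch_size = 16L,
    n_epochs = 25L,
    dropout = 0.5,
    search = FALSE,
    population_size = 6L,
    n_generations = 3L,
    with_svm = TRUE,
    explain_layer = "last",
    q = 90,
    min_size = 20L,
    write_volumes = FALSE
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON config, rejects unknown keys (naming the offender),
#' fills defaults for everything omitted, and validates values. A config
#' containing only a data path is valid: every other field has a default.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param x A named list of config values.
#' @export
as_run_config <- function(x) {
  defaults <- config_defaults()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(x)] <- x
  if (!is.null(cfg$data) && !dir.exists(cfg$data))
    stop("data directory does not exist: ", cfg$data)
  if (length(cfg$seed) != 1L || is.na(cfg$seed) || cfg$seed < 0)
    stop("'seed' must be a nonnegative integer")
  cfg$seed <- as.integer(cfg$seed)
  if (abs(sum(cfg$fractions) - 1) > 1e-8)
    stop("'fractions' must sum to 1")
  cfg$channel_axis <- match.arg(cfg$channel_axis, c("z", "x", "y"))
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Expects `mask.nii.gz`, `parcellation.nii.gz`, `demographics.tsv` and one
#' `<subject_id>.nii.gz` per subject; an optional `region_names.tsv`
#' (columns `label`, `name`) overrides the generic parcel names.
#'
#' @param dir Cohort directory.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  mask_v <- read_volume(file.path(dir, "mask.nii.gz"))
  parc_v <- read_volume(file.path(dir, "parcellation.nii.gz"))
  parc <- array(as.integer(round(parc_v$data)), dim = dim(parc_v$data))
  labels <- sort(setdiff(unique(as.vector(parc)), 0L))
  region_names <- sprintf("parcel_%02d", labels)
  names(region_names) <- labels
  rn_path <- file.path(dir, "region_names.tsv")
  if (file.exists(rn_path)) {
    rn <- utils::read.delim(rn_path, stringsAsFactors = FALSE)
    region_names[as.character(rn$label)] <- rn$name
  }
  geometry <- structure(list(mask = array(as.integer(mask_v$data != 0),
                                          dim = dim(mask_v$data)),
                             parcellation = parc,
                             region_names = region_names,
                             affine = mask_v$affine),
                        class = "brain_geometry")
  demo <- utils::read.delim(file.path(dir, "demographics.tsv"),
                            stringsAsFactors = FALSE)
  vols <- lapply(demo$subject_id, function(id)
    read_volume(file.path(dir, paste0(id, ".nii.gz")), subject_id = id))
  names(vols) <- demo$subject_id
  structure(list(subjects = demo, volumes = vols, geometry = geometry),
            class = "cohort")
}

#' Run the full classification-and-explanation pipeline
#'
#' Executes simulate (when no data directory is given), split, train (the
#' pinned modified LeNet-5, plus the SVM baseline and optionally a GGP
#' architecture search), explanation with the best-validation-accuracy model
#' (ties toward fewer parameters), and the per-class region report. Every
#' stage appends to a JSON-lines run log recording seeds, the config hash
#' and produced artifacts.
#'
#' @param config A `run_config` from [load_config()]/[as_run_config()].
#' @return Invisibly, a list with the results table, fits, region tables and
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  chash <- config_hash(config)
  log_entry <- function(stage, ...) {
    entry <- c(list(stage = stage, seed = config$seed, config_hash = chash),
               list(...))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null", digits = NA),
        "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- "init"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  save_config(config, file.path(out_dir, "config_used.yaml"))

  # ---- data -----------------------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$data)) read_cohort(config$data)
    else {
      geometry <- make_brain_geometry(config$shape, config$n_regions,
                                      seed = derive_seed(config$seed, 101L))
      eff <- effect_spec(config$target_labels, config$amplitude)
      co <- simulate_cohort(geometry, config$n_per_group, eff,
                            baseline = config$baseline,
                            noise_sd = config$noise_sd,
                            smooth_sigma = config$smooth_sigma,
                            seed = derive_seed(config$seed, 1L))
      if (config$write_volumes) write_cohort(co, file.path(out_dir, "cohort"))
      utils::write.table(co$subjects, file.path(out_dir, "demographics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      co
    }
  })
  log_entry("simulate", n_subjects = nrow(cohort$subjects))

  # ---- split ----------------------------------------------------------
  split <- run_stage("split",
    split_cohort(cohort, config$fractions, stratify_by_group = TRUE,
                 seed = derive_seed(config$seed, 2L)))
  split_path <- file.path(out_dir, "split.tsv")
  utils::write.table(split[, c("subject_id", "part")], split_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_entry("split", artifact = split_path)

  data <- run_stage("pack",
    prepare_cnn_data(cohort, split, axis = config$channel_axis,
                     augment = config$augment,
                     seed = derive_seed(config$seed, 3L)))

  # ---- train ----------------------------------------------------------
  results <- list()
  candidates <- list()
  lenet_fit <- run_stage("train", {
    spec <- build_modified_lenet5(data$input_shape, dropout = config$dropout)
    cfg <- train_config(learning_rate = config$learning_rate,
                        batch_size = config$batch_size,
                        n_epochs = config$n_epochs,
                        dropout_rate = config$dropout,
                        seed = derive_seed(config$seed, 4L))
    train_cnn(spec, cfg, data$train$x, data$train$y, data$val$x, data$val$y)
  })
  acc <- evaluate_cnn(lenet_fit, data$test$x, data$test$y)
  val_acc <- utils::tail(lenet_fit$history$val_acc, 1)
  results$lenet <- list(technique = "Modified LeNet-5", accuracy = acc,
                        n_test = length(data$test$y))
  candidates$lenet <- list(fit = lenet_fit, val_acc = val_acc,
                           n_params = count_params(lenet_fit$model$spec))
  log_entry("train", technique = "Modified LeNet-5", test_accuracy = acc,
            val_accuracy = val_acc,
            n_params = count_params(lenet_fit$model$spec))

  if (isTRUE(config$with_svm)) {
    svm_res <- run_stage("train_svm", {
      feats <- cohort_features(cohort)
      parts <- split$part[match(cohort$subjects$subject_id, split$subject_id)]
      train_svm_baseline(feats, cohort$subjects$group, parts,
                         seed = derive_seed(config$seed, 5L))
    })
    results$svm <- svm_res
    log_entry("train_svm", test_accuracy = svm_res$accuracy,
              C = svm_res$config$C)
  }

  if (isTRUE(config$search)) {
    search_res <- run_stage("search", {
      fitness <- function(genome) {
        gm <- genome_to_model(genome, data$input_shape, warn_dropout = FALSE)
        gm$config$n_epochs <- min(gm$config$n_epochs, config$n_epochs)
        fit <- train_cnn(gm$spec, gm$config, data$train$x, data$train$y,
                         data$val$x, data$val$y,
                         seed = derive_seed(config$seed, 6L))
        utils::tail(fit$history$val_acc, 1) / 100
      }
      evolve(default_grammar(), data$input_shape, fitness,
             population_size = config$population_size,
             n_generations = config$n_generations,
             seed = derive_seed(config$seed, 7L))
    })
    gpath <- file.path(out_dir, "best_genome.json")
    write_genome(search_res$best$genome, gpath)
    jsonlite::write_json(search_res$history,
                         file.path(out_dir, "search_history.json"),
                         dataframe = "rows", digits = NA)
    gm <- genome_to_model(search_res$best$genome, data$input_shape,
                          warn_dropout = FALSE)
    gm$config$n_epochs <- min(gm$config$n_epochs, config$n_epochs)
    ggp_fit <- train_cnn(gm$spec, gm$config, data$train$x, data$train$y,
                         data$val$x, data$val$y,
                         seed = derive_seed(config$seed, 6L))
    ggp_acc <- evaluate_cnn(ggp_fit, data$test$x, data$test$y)
    results$ggp <- list(technique = "Best GGP 2D CNN", accuracy = ggp_acc,
                        n_test = length(data$test$y))
    candidates$ggp <- list(fit = ggp_fit,
                           val_acc = utils::tail(ggp_fit$history$val_acc, 1),
                           n_params = count_params(ggp_fit$model$spec))
    log_entry("search", best_fitness = search_res$best$fitness,
              test_accuracy = ggp_acc, artifact = gpath)
  }

  table <- make_results_table(results)
  table_path <- file.path(out_dir, "results.tsv")
  utils::write.table(table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(utils::capture.output(print(table)),
             file.path(out_dir, "results.txt"))
  log_entry("results", artifact = table_path)

  # ---- explain + report ----------------------------------------------
  best_name <- names(candidates)[order(
    -vapply(candidates, `[[`, numeric(1), "val_acc"),
    vapply(candidates, `[[`, numeric(1), "n_params"))][1]
  best_fit <- candidates[[best_name]]$fit
  ckpt <- file.path(out_dir, "best_model.rds")
  saveRDS(best_fit, ckpt)
  log_entry("select_model", model = best_name,
            val_accuracy = candidates[[best_name]]$val_acc, checkpoint = ckpt)

  tables <- run_stage("explain", {
    mask <- cohort$geometry$mask
    preds <- rep(NA_integer_, nrow(cohort$subjects))
    sal_vols <- vector("list", nrow(cohort$subjects))
    for (i in seq_len(nrow(cohort$subjects))) {
      v <- zscore_volume(cohort$volumes[[i]], mask)
      ct <- pack_slices_as_channels(v, config$channel_axis)
      pr <- cnn_forward(best_fit$model, ct$data)$probs
      preds[i] <- which.max(pr[1, ]) - 1L
      cls <- as.integer(cohort$subjects$group[i] == "DYS")
      sal <- guided_gradcam(best_fit$model, ct, class_index = cls,
                            layer = config$explain_layer)
      sal_vols[[i]] <- saliency_to_volume(sal, axis = config$channel_axis,
                                          affine = cohort$geometry$affine,
                                          subject_id = cohort$subjects$subject_id[i])
    }
    out_tables <- list()
    for (grp in c("DYS", "TYP")) {
      sel <- cohort$subjects$group == grp
      correct <- preds[sel] == as.integer(grp == "DYS")
      gs <- group_mean_saliency(lapply(sal_vols[sel], `[[`, "data"),
                                correct = correct,
                                use_all = !any(correct))
      gs$data[mask == 0L] <- 0
      gpath <- file.path(out_dir, sprintf("group_saliency_%s.nii.gz", grp))
      write_volume(brain_volume(gs$data, cohort$geometry$affine), gpath)
      bin <- threshold_map(gs$data, mask, q = config$q)
      cl <- connected_clusters(bin, min_size = config$min_size)
      tab <- region_table(cl, gs$data, cohort$geometry)
      tpath <- file.path(out_dir, sprintf("region_table_%s.tsv", grp))
      write_region_table(tab, tpath)
      writeLines(utils::capture.output(print(tab)),
                 file.path(out_dir, sprintf("region_table_%s.txt", grp)))
      log_entry("report", group = grp, artifact = tpath,
                saliency = gpath, n_clusters = length(attr(cl, "sizes")))
      out_tables[[grp]] <- tab
    }
    out_tables
  })

  invisible(list(results = table, fits = candidates, region_tables = tables,
                 split = split, out_dir = out_dir))
}
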