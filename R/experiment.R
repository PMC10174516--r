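#' Experiment configuration
#'
#' Describes the comparison grid: models x population sizes x with/without
#' wrapper feature selection x repeated runs. Defaults mirror the published
#' run table (domain range `[-1, 1]`, epoch budget 50, population sizes 25
#' to 50) at a desk-scale number of runs.
#'
#' @param models character vector of registry names (see
#'   [classifier_spec()]).
#' @param pop_sizes integer vector of optimizer population sizes.
#' @param with_hgso logical vector of selection flags to cross (default
#'   `c(FALSE, TRUE)`).
#' @param runs repetitions per grid cell.
#' @param epochs optimizer iteration budget per selection run.
#' @param domain_range optimizer box (default `c(-1, 1)`).
#' @param optimizer_strategy `"hgso"`, `"aqo"`, or `"hybrid"`.
#' @param fitness_classifier classifier scoring subsets inside the wrapper
#'   (default `"knn"`, the cheapest; set to the cell's model for a full
#'   wrapper at much higher cost).
#' @param lambda accuracy weight of the wrapper fitness.
#' @param seed_base integer; the per-cell seed is derived from it and the
#'   cell index, and the per-run data seed from it and the run id (so runs
#'   are paired across models for the signed-rank comparison).
#' @param data_source a [generator_spec()], a `gs_dataset`, or a CSV path
#'   (its label column must be named `outcome`).
#' @param classifier_seed seed offset for model fitting.
#' @param extra opaque passthrough list kept in the manifest (e.g. run-table
#'   fields with no operational meaning here, such as an `lsa_epoch`).
#' @return Object of class `gs_experiment_config`.
#' @export
experiment_config <- function(models = c("knn", "rf", "c45", "ann", "svm", "rf_svm"),
                              pop_sizes = c(25L, 30L, 35L, 40L, 45L, 50L),
                              with_hgso = c(FALSE, TRUE), runs = 1L,
                              epochs = 50L, domain_range = c(-1, 1),
                              optimizer_strategy = "hgso",
                              fitness_classifier = "knn", lambda = 0.99,
                              seed_base = 1L, data_source = generator_spec(),
                              classifier_seed = 1L, extra = list()) {
  stopifnot(length(pop_sizes) >= 1L, runs >= 1L, epochs >= 1L,
            length(domain_range) == 2L, domain_range[1] < domain_range[2],
            length(models) >= 1L)
  structure(
    list(models = models, pop_sizes = as.integer(pop_sizes),
         with_hgso = as.logical(with_hgso), runs = as.integer(runs),
         epochs = as.integer(epochs), domain_range = domain_range,
         optimizer_strategy = optimizer_strategy,
         fitness_classifier = fitness_classifier, lambda = lambda,
         seed_base = as.integer(seed_base), data_source = data_source,
         classifier_seed = as.integer(classifier_seed), extra = extra),
    class = "gs_experiment_config"
  )
}

resolve_data <- function(data_source, run_seed) {
  if (inherits(data_source, "gs_dataset")) return(data_source)
  if (inherits(data_source, "gs_generator_spec")) {
    spec <- data_source
    spec$seed <- run_seed
    return(generate_dataset(spec)$dataset)
  }
  if (is.character(data_source) && length(data_source) == 1L) {
    return(load_csv(data_source, "outcome"))
  }
  stop("unsupported data_source", call. = FALSE)
}

#' Run the full comparison grid
#'
#' For every cell (model, pop size, selection flag, run): resolve the data
#' (generated data is seeded by the run id, so all models of a run see the
#' same records), split 80/20, optionally run the wrapper selector at the
#' cell's population size, fit the model, and score macro metrics on the
#' test half. A failing cell is recorded (`status = "error"`) and the grid
#' continues.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-cell progress to stderr.
#' @return Object of class `gs_results_table`: list with `results` (one row
#'   per cell), `traces` (per selection run), `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "gs_experiment_config"))
  grid <- expand.grid(run_id = seq_len(config$runs),
                      with_hgso = config$with_hgso,
                      pop_size = config$pop_sizes,
                      model = config$models,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  traces <- list()
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    cell_seed <- derive_seed(config$seed_base, cell)
    run_seed <- derive_seed(config$seed_base, g$run_id)
    out <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      dataset <- resolve_data(config$data_source, run_seed)
      n_feat <- ncol(dataset$features)
      best_fitness <- NA_real_
      if (g$with_hgso) {
        fs <- fitness_spec(lambda = config$lambda,
                           classifier = config$fitness_classifier,
                           domain_range = config$domain_range,
                           seed = cell_seed)
        sel <- select_features(dataset, optimizer = config$optimizer_strategy,
                               spec = fs, n_agents = g$pop_size,
                               max_iter = config$epochs, seed = cell_seed)
        traces[[sprintf("model=%s_pop=%d_run=%d", g$model, g$pop_size,
                        g$run_id)]] <- sel$trace
        dataset <- apply_mask(dataset, sel$best_mask)
        n_feat <- ncol(dataset$features)
        best_fitness <- sel$best_fitness
      }
      split <- train_test_split(dataset, seed = run_seed)
      cspec <- classifier_spec(g$model,
                               seed = derive_seed(config$classifier_seed,
                                                  cell))
      pred <- fit_predict(cspec, split)
      m <- macro_metrics(confusion(split$test$labels, pred$labels,
                                   split$test$class_names))
      data.frame(model = g$model, pop_size = g$pop_size,
                 with_hgso = g$with_hgso, run_id = g$run_id,
                 seed = cell_seed, accuracy = m$accuracy,
                 recall = m$recall, precision = m$precision,
                 f_measure = m$f_measure, sensitivity = m$sensitivity,
                 n_features = n_feat, best_fitness = best_fitness,
                 wall_time = proc.time()[["elapsed"]] - t0,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(model = g$model, pop_size = g$pop_size,
                 with_hgso = g$with_hgso, run_id = g$run_id,
                 seed = cell_seed, accuracy = NA_real_, recall = NA_real_,
                 precision = NA_real_, f_measure = NA_real_,
                 sensitivity = NA_real_, n_features = NA_integer_,
                 best_fitness = NA_real_, wall_time = NA_real_,
                 status = paste("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    if (verbose) {
      message(sprintf("[%d/%d] %s pop=%d hgso=%s run=%d -> %s",
                      cell, nrow(grid), g$model, g$pop_size, g$with_hgso,
                      g$run_id, out$status))
    }
    rows[[cell]] <- out
  }
  structure(list(results = do.call(rbind, rows), traces = traces,
                 config = config),
            class = "gs_results_table")
}

#' @export
print.gs_results_table <- function(x, ...) {
  cat("<gs_results_table> ", nrow(x$results), " cells (",
      sum(x$results$status != "ok"), " failed)\n", sep = "")
  invisible(x)
}

# population SD (divide by n), the convention declared in every report
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Aggregate results over grouping keys
#'
#' Per group: mean, min, max and population SD (divide by n) of every metric
#' and of the selected-feature count. Empty groups are dropped with a
#' warning.
#'
#' @param results a `gs_results_table`.
#' @param group_by character vector of grouping columns (default
#'   `c("model", "with_hgso")`).
#' @return data.frame, one row per group x metric.
#' @export
summarize_results <- function(results, group_by = c("model", "with_hgso")) {
  stopifnot(inherits(results, "gs_results_table"))
  df <- results$results[results$results$status == "ok", , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no successful cells to summarize")
    return(data.frame())
  }
  metrics <- c("accuracy", "recall", "precision", "f_measure",
               "sensitivity", "n_features")
  key <- interaction(df[group_by], drop = TRUE, sep = "|")
  out <- do.call(rbind, lapply(split(df, key), function(grp) {
    do.call(rbind, lapply(metrics, function(mname) {
      v <- grp[[mname]]
      cbind(grp[1, group_by, drop = FALSE],
            data.frame(metric = mname, mean = mean(v), min = min(v),
                       max = max(v), sd = pop_sd(v), n = length(v)))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Paired signed-rank comparison of two models
#'
#' Pairs the two models' accuracies by `run_id` (and pop size / flag, which
#' must be aggregated or filtered beforehand if several are present) and
#' applies [wilcoxon_signed_rank()].
#'
#' @param results a `gs_results_table`.
#' @param model_a,model_b registry names present in the results.
#' @param metric column to compare (default `"accuracy"`).
#' @param with_hgso restrict to one selection flag (default `TRUE`).
#' @return A `gs_wilcoxon` result.
#' @export
compare_models <- function(results, model_a, model_b, metric = "accuracy",
                           with_hgso = TRUE) {
  stopifnot(inherits(results, "gs_results_table"))
  df <- results$results[results$results$status == "ok" &
                          results$results$with_hgso == with_hgso, ]
  pick <- function(mod) {
    sub <- df[df$model == mod, c("run_id", "pop_size", metric)]
    if (nrow(sub) == 0L) stop("no runs for model '", mod, "'", call. = FALSE)
    sub[order(sub$run_id, sub$pop_size), ]
  }
  a <- pick(model_a)
  b <- pick(model_b)
  if (nrow(a) != nrow(b) || !all(a$run_id == b$run_id) ||
      !all(a$pop_size == b$pop_size)) {
    stop("pairing error: runs of '", model_a, "' and '", model_b,
         "' do not align by (run_id, pop_size)", call. = FALSE)
  }
  if (nrow(a) < 5L) stop("need >= 5 paired runs", call. = FALSE)
  wilcoxon_signed_rank(a[[metric]], b[[metric]])
}

#' Export a results bundle to a directory
#'
#' Writes `results.csv` (metrics; the wall-time column is withheld so a
#' re-run under the same config is byte-identical), `summary.csv`,
#' optionally `wilcoxon.json` for given model pairs, one convergence CSV per
#' stored selection trace, and `manifest.json` listing every emitted file
#' with its MD5 checksum together with the config and library versions.
#'
#' @param results a `gs_results_table`.
#' @param out_dir output directory (created if needed).
#' @param compare list of 2-element character vectors of model names to test
#'   against each other (default none).
#' @return invisible character vector of the emitted file paths.
#' @export
export_report <- function(results, out_dir, compare = list()) {
  stopifnot(inherits(results, "gs_results_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  emitted <- character(0)
  write_stable_csv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], format_full)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
    emitted <<- c(emitted, path)
  }
  res_cols <- setdiff(names(results$results), "wall_time")
  write_stable_csv(results$results[res_cols],
                   file.path(out_dir, "results.csv"))
  write_stable_csv(summarize_results(results),
                   file.path(out_dir, "summary.csv"))
  if (length(compare)) {
    w <- lapply(compare, function(pair) {
      r <- compare_models(results, pair[1], pair[2])
      list(model_a = pair[1], model_b = pair[2], statistic = r$statistic,
           p_value = r$p_value, n_effective = r$n_effective,
           method = r$method)
    })
    wpath <- file.path(out_dir, "wilcoxon.json")
    jsonlite::write_json(w, wpath, digits = NA, auto_unbox = TRUE)
    emitted <- c(emitted, wpath)
  }
  if (length(results$traces)) {
    tdir <- file.path(out_dir, "convergence")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(results$traces)) {
      tpath <- file.path(tdir, paste0(nm, ".csv"))
      write_stable_csv(results$traces[[nm]], tpath)
    }
  }
  manifest <- list(
    config = serialize_config(results$config),
    sd_convention = "population (divide by n)",
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("gasselect")),
    files = lapply(emitted, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, digits = NA, auto_unbox = TRUE)
  invisible(c(emitted, mpath))
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (inherits(out$data_source, "gs_generator_spec")) {
    out$data_source <- c(list(kind = "generator"),
                         unclass(out$data_source))
  } else if (inherits(out$data_source, "gs_dataset")) {
    out$data_source <- list(kind = "in-memory dataset",
                            n = nrow(out$data_source$features))
  } else {
    out$data_source <- list(kind = "csv", path = out$data_source)
  }
  out
}
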