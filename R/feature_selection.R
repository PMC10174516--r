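#' Binarize a continuous position into a feature mask
#'
#' Component j selects feature j iff it exceeds 0.5 (strict). Note that with
#' the default `[-1, 1]` domain range only the top quarter of the range
#' selects a feature; pass `domain_range = c(0, 1)` to the selection config
#' for the symmetric alternative.
#'
#' @param position numeric vector.
#' @param threshold selection threshold (default 0.5).
#' @return Object of class `gs_feature_mask`: logical vector with attribute
#'   `count`.
#' @examples
#' binarize(c(0.7, 0.2, 0.5)) # TRUE FALSE FALSE
#' @export
binarize <- function(position, threshold = 0.5) {
  bits <- as.numeric(position) > threshold
  structure(bits, count = sum(bits), class = "gs_feature_mask")
}

#' @export
print.gs_feature_mask <- function(x, ...) {
  cat("<gs_feature_mask> ", attr(x, "count"), "/", length(x),
      " features selected\n", sep = "")
  invisible(x)
}

#' Wrapper-fitness specification
#'
#' The objective of the binary wrapper: `Fit = lambda * gamma +
#' (1 - lambda) * |BX| / D`, where `gamma` is the holdout misclassification
#' rate of `classifier` trained on the masked training features and
#' evaluated on the masked test features, and `|BX|/D` the selected
#' fraction. `lambda` close to 1 prioritizes accuracy over parsimony; the
#' conventional 0.99 is the default. An all-zero mask is never fitted: it
#' receives the penalty `1 + lambda`, worse than any feasible fitness.
#'
#' @param lambda accuracy weight in `[0, 1]` (default 0.99).
#' @param classifier name of the registered classifier scoring subsets
#'   (default `"knn"`) or a full [classifier_spec()].
#' @param domain_range optimizer box for the continuous positions (default
#'   `c(-1, 1)`).
#' @param threshold binarization threshold (default 0.5).
#' @param seed integer seed for the subset classifier.
#' @return Object of class `gs_fitness_spec`.
#' @export
fitness_spec <- function(lambda = 0.99, classifier = "knn",
                         domain_range = c(-1, 1), threshold = 0.5,
                         seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, length(domain_range) == 2,
            domain_range[1] < domain_range[2])
  cspec <- if (inherits(classifier, "gs_classifier_spec")) {
    classifier
  } else {
    classifier_spec(classifier, seed = seed)
  }
  structure(
    list(lambda = lambda, classifier = cspec, domain_range = domain_range,
         threshold = threshold, seed = as.integer(seed)),
    class = "gs_fitness_spec"
  )
}

#' Wrapper fitness of a feature mask
#'
#' @param mask logical vector (or [binarize()] output) over the features.
#' @param split a [train_test_split()] pair.
#' @param spec a [fitness_spec()].
#' @return scalar fitness (smaller is better).
#' @export
subset_fitness <- function(mask, split, spec) {
  stopifnot(inherits(split, "gs_split"), inherits(spec, "gs_fitness_spec"))
  bits <- as.logical(mask)
  d <- length(bits)
  if (d != ncol(split$train$features)) {
    stop("mask length ", d, " != feature count ",
         ncol(split$train$features), call. = FALSE)
  }
  if (!any(bits)) return(1 + spec$lambda) # all-zero mask: penalty, no fit
  train <- mask_dataset(split$train, bits)
  test <- mask_dataset(split$test, bits)
  pred <- tryCatch(
    gs_predict(gs_fit(make_classifier(spec$classifier), train),
               test$features),
    error = function(e) stop("classifier failed on mask [",
                             paste(as.integer(bits), collapse = ""), "]: ",
                             conditionMessage(e), call. = FALSE)
  )
  err <- mean(pred$labels != test$labels)
  spec$lambda * err + (1 - spec$lambda) * sum(bits) / d
}

mask_dataset <- function(dataset, bits) {
  gs_dataset(dataset$features[, bits, drop = FALSE],
             dataset$labels, dataset$feature_names[bits],
             dataset$class_names)
}

#' Restrict a dataset to the selected features
#'
#' @param dataset a [gs_dataset()].
#' @param mask logical vector of length equal to the feature count.
#' @return a [gs_dataset()] with the selected columns, names preserved in
#'   order.
#' @export
apply_mask <- function(dataset, mask) {
  stopifnot(inherits(dataset, "gs_dataset"))
  bits <- as.logical(mask)
  if (length(bits) != ncol(dataset$features)) {
    stop("mask length ", length(bits), " != feature count ",
         ncol(dataset$features), call. = FALSE)
  }
  mask_dataset(dataset, bits)
}

#' Metaheuristic wrapper feature selection
#'
#' Runs an optimizer (HGSO, AQO, or their sequential hybrid) over continuous
#' positions in the configured domain range with objective
#' `subset_fitness(binarize(position))`, caching fitness by mask bits (many
#' positions binarize identically, and the classifier fit dominates the
#' cost). Returns the best mask, its fitness, the optimization trace, and
#' test metrics of the subset classifier on the reduced feature set.
#'
#' @param dataset a [gs_dataset()] with at least two classes.
#' @param optimizer `"hgso"`, `"aqo"`, or `"hybrid"`.
#' @param spec a [fitness_spec()].
#' @param n_agents,max_iter optimizer budget (defaults 10 solutions, 100
#'   iterations — the repeated-comparison protocol configuration).
#' @param seed integer seed driving the split and the optimizer.
#' @param fraction training fraction of the inner holdout (default 0.8).
#' @param ... passed to [run_optimizer()] (`hgso_control`, `aqo_control`).
#' @return Object of class `gs_selection_result`: `best_mask`,
#'   `best_fitness`, `trace`, `reduced_test_metrics`, `split_seed`, `seed`,
#'   `n_evaluations` (distinct masks fitted).
#' @export
select_features <- function(dataset, optimizer = "hgso",
                            spec = fitness_spec(), n_agents = 10L,
                            max_iter = 100L, seed = 1L, fraction = 0.8,
                            ...) {
  stopifnot(inherits(dataset, "gs_dataset"))
  split <- train_test_split(dataset, fraction = fraction, seed = seed)
  if (length(unique(split$train$labels)) < 2L ||
      length(unique(split$test$labels)) < 2L) {
    stop("need >= 2 classes present in both split halves", call. = FALSE)
  }
  d <- ncol(dataset$features)
  cache <- new.env(parent = emptyenv())
  objective <- function(position) {
    bits <- as.logical(binarize(position, spec$threshold))
    key <- paste(as.integer(bits), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- subset_fitness(bits, split, spec)
    cache[[key]] <- val
    val
  }
  space <- search_space(d, spec$domain_range[1], spec$domain_range[2])
  res <- run_optimizer(objective, space, strategy = optimizer,
                       n_agents = n_agents, max_iter = max_iter,
                       seed = seed, ...)
  best_mask <- binarize(res$best_position, spec$threshold)
  if (!any(best_mask)) {
    stop("selection degenerate: optimizer returned an all-zero mask ",
         "(best fitness ", format(res$best_fitness), ")", call. = FALSE)
  }
  reduced <- apply_mask(split$test, best_mask)
  reduced_train <- apply_mask(split$train, best_mask)
  pred <- gs_predict(gs_fit(make_classifier(spec$classifier), reduced_train),
                     reduced$features)
  metrics <- macro_metrics(confusion(reduced$labels, pred$labels,
                                     reduced$class_names))
  structure(
    list(best_mask = best_mask, best_fitness = res$best_fitness,
         trace = res$trace, reduced_test_metrics = metrics,
         split_seed = split$seed, seed = as.integer(seed),
         n_evaluations = length(ls(cache))),
    class = "gs_selection_result"
  )
}

#' @export
print.gs_selection_result <- function(x, ...) {
  cat("<gs_selection_result> ", attr(x$best_mask, "count"), "/",
      length(x$best_mask), " features, fitness ",
      format(x$best_fitness), "\n", sep = "")
  print(x$reduced_test_metrics)
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Mask as a 0/1 string plus fitness, seed and metric record; the selected
#' feature names go to a plain-text sidecar when `names_path` is given.
#'
#' @param result a `gs_selection_result`.
#' @param dataset the dataset it was computed on (for feature names).
#' @param json_path output JSON path.
#' @param names_path optional plain-text path for the selected names.
#' @return invisible `json_path`.
#' @export
write_selection <- function(result, dataset, json_path, names_path = NULL) {
  bits <- as.logical(result$best_mask)
  jsonlite::write_json(
    list(mask = paste(as.integer(bits), collapse = ""),
         n_selected = sum(bits),
         best_fitness = result$best_fitness,
         seed = result$seed,
         test_metrics = result$reduced_test_metrics[
           c("accuracy", "recall", "precision", "f_measure", "sensitivity")]),
    json_path, digits = NA, auto_unbox = TRUE
  )
  if (!is.null(names_path)) {
    writeLines(dataset$feature_names[bits], names_path)
  }
  invisible(json_path)
}
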