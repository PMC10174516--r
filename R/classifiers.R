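#' Classifier specification
#'
#' Names one of the registered learners with its hyperparameters. The
#' registry covers the five base learners compared in the clinical study —
#' k-NN, random forest (bagged gini trees with per-node feature
#' subsampling), a C4.5-style tree (entropy / gain-ratio splitting), a
#' single-hidden-layer neural network, an RBF-kernel SVM (random Fourier
#' feature approximation, one-vs-rest squared-hinge) — plus the `rf_svm`
#' "double classifier" that soft-votes the RF and SVM probability vectors.
#'
#' Hyperparameter defaults: `knn` k = 5; `rf` 100 trees, mtry = floor(sqrt(p));
#' `c45` gain-ratio criterion, no depth cap (depth 30); `ann` one hidden
#' layer of 64 tanh units, Adam, early stopping; `svm` RBF gamma = 1/p,
#' 200 random Fourier features, cost 1; `rf_svm` combine = "vote"
#' (soft-voting mean) or "stack" (RF out-of-fold probabilities fed to the
#' SVM).
#'
#' @param name one of `"knn"`, `"rf"`, `"c45"`, `"ann"`, `"svm"`, `"rf_svm"`.
#' @param hyperparams named list overriding the defaults above.
#' @param seed integer seed making fitting deterministic.
#' @return Object of class `gs_classifier_spec`.
#' @export
classifier_spec <- function(name, hyperparams = list(), seed = 1L) {
  registry <- names(classifier_defaults)
  if (!is.character(name) || length(name) != 1L || !name %in% registry) {
    stop("unknown classifier '", paste(name, collapse = ","),
         "'; valid names: ", paste(registry, collapse = ", "), call. = FALSE)
  }
  defaults <- classifier_defaults[[name]]
  bad <- setdiff(names(hyperparams), names(defaults))
  if (length(bad)) {
    stop("unknown hyperparameter(s) for '", name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(name = name, hyperparams = hp, seed = as.integer(seed)),
            class = "gs_classifier_spec")
}

classifier_defaults <- list(
  knn = list(k = 5L),
  rf = list(n_trees = 100L, mtry = NULL, max_depth = 30L, min_split = 2L,
            min_leaf = 1L),
  c45 = list(max_depth = 30L, min_split = 2L, min_leaf = 1L,
             criterion = "gainratio"),
  ann = list(hidden = 64L, maxit = 300L, lr = 0.01, weight_decay = 1e-4,
             patience = 25L, tol = 1e-6),
  svm = list(gamma = NULL, rff_dim = 200L, cost = 1, maxit = 100L),
  rf_svm = list(combine = "vote", stack_folds = 5L, rf = list(),
                svm = list())
)

#' Instantiate a classifier handle from a spec
#'
#' @param spec a [classifier_spec()].
#' @return A handle of class `gs_classifier` exposing [gs_fit()] /
#'   [gs_predict()].
#' @export
make_classifier <- function(spec) {
  stopifnot(inherits(spec, "gs_classifier_spec"))
  structure(list(spec = spec),
            class = c(paste0("gs_clf_", spec$name), "gs_classifier"))
}

#' Fit a classifier on a training dataset
#'
#' @param classifier a [make_classifier()] handle.
#' @param train a [gs_dataset()] with at least two classes present.
#' @return A fitted model usable with [gs_predict()].
#' @export
gs_fit <- function(classifier, train) UseMethod("gs_fit")

#' Predict class labels and probabilities
#'
#' @param model a fitted model from [gs_fit()].
#' @param features numeric matrix of test features (same columns as
#'   training).
#' @return Object of class `gs_prediction`: list with `labels` (character)
#'   and `probabilities` (rows summing to 1; `labels` is always the row-wise
#'   argmax, ties broken by class order).
#' @export
gs_predict <- function(model, features) UseMethod("gs_predict")

check_train <- function(train) {
  stopifnot(inherits(train, "gs_dataset"))
  present <- unique(train$labels)
  if (length(present) < 2L) {
    stop("degenerate training set: a single class present", call. = FALSE)
  }
  invisible(train)
}

prediction_set <- function(prob, class_names) {
  prob <- as.matrix(prob)
  colnames(prob) <- class_names
  rs <- rowSums(prob)
  rs[rs == 0] <- 1
  prob <- prob / rs
  labels <- class_names[max.col(prob, ties.method = "first")]
  structure(list(labels = labels, probabilities = prob),
            class = "gs_prediction")
}

#' @export
print.gs_prediction <- function(x, ...) {
  cat("<gs_prediction> ", length(x$labels), " rows, classes: ",
      paste(colnames(x$probabilities), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' One-call fit + predict on a train/test split
#'
#' @param spec a [classifier_spec()].
#' @param split a [train_test_split()] result.
#' @return A `gs_prediction` for the test rows.
#' @export
fit_predict <- function(spec, split) {
  stopifnot(inherits(split, "gs_split"))
  if (!identical(split$train$feature_names, split$test$feature_names)) {
    stop("train and test feature schemas differ", call. = FALSE)
  }
  model <- gs_fit(make_classifier(spec), split$train)
  gs_predict(model, split$test$features)
}

## ---- k-NN ------------------------------------------------------------

#' @export
gs_fit.gs_clf_knn <- function(classifier, train) {
  check_train(train)
  structure(
    list(spec = classifier$spec, x = train$features,
         y = factor(train$labels, levels = train$class_names),
         class_names = train$class_names),
    class = c("gs_fit_knn", "gs_fitted")
  )
}

#' @export
gs_predict.gs_fit_knn <- function(model, features) {
  k <- min(model$spec$hyperparams$k, nrow(model$x))
  idx <- FNN::knnx.index(model$x, as.matrix(features), k = k)
  C <- length(model$class_names)
  yi <- as.integer(model$y)
  prob <- t(apply(idx, 1, function(nb) tabulate(yi[nb], nbins = C) / k))
  if (nrow(as.matrix(features)) == 1L) prob <- matrix(prob, nrow = 1)
  prediction_set(prob, model$class_names)
}

## ---- trees and forest -------------------------------------------------

criterion_code <- function(criterion) {
  switch(criterion, gini = 0L, entropy = 1L, gainratio = 2L,
         stop("unknown criterion '", criterion, "'", call. = FALSE))
}

#' @export
gs_fit.gs_clf_c45 <- function(classifier, train) {
  check_train(train)
  hp <- classifier$spec$hyperparams
  y <- as.integer(factor(train$labels, levels = train$class_names)) - 1L
  tree <- .cpp_grow_tree(train$features, y, length(train$class_names),
                         criterion_code(hp$criterion), hp$max_depth,
                         hp$min_split, hp$min_leaf, 0L,
                         classifier$spec$seed)
  structure(list(spec = classifier$spec, tree = tree,
                 class_names = train$class_names),
            class = c("gs_fit_c45", "gs_fitted"))
}

#' @export
gs_predict.gs_fit_c45 <- function(model, features) {
  prob <- .cpp_predict_tree(model$tree, as.matrix(features))
  prediction_set(prob, model$class_names)
}

#' Depth of a fitted tree
#' @param model a fitted `c45` model.
#' @return integer depth (0 = a single leaf).
#' @export
tree_depth <- function(model) {
  tr <- model$tree
  depth_of <- function(node, d) {
    if (tr$feature[node] < 0) return(d)
    max(depth_of(tr$left[node] + 1L, d + 1L),
        depth_of(tr$right[node] + 1L, d + 1L))
  }
  depth_of(1L, 0L)
}

#' @export
gs_fit.gs_clf_rf <- function(classifier, train) {
  check_train(train)
  hp <- classifier$spec$hyperparams
  p <- ncol(train$features)
  mtry <- hp$mtry %||% max(1L, floor(sqrt(p)))
  y <- as.integer(factor(train$labels, levels = train$class_names)) - 1L
  n <- nrow(train$features)
  trees <- with_rng_seed(classifier$spec$seed, {
    lapply(seq_len(hp$n_trees), function(b) {
      boot <- sample.int(n, n, replace = TRUE)
      tree_seed <- sample.int(.Machine$integer.max, 1L)
      .cpp_grow_tree(train$features[boot, , drop = FALSE], y[boot],
                     length(train$class_names), 0L, hp$max_depth,
                     hp$min_split, hp$min_leaf, as.integer(mtry), tree_seed)
    })
  })
  structure(list(spec = classifier$spec, trees = trees,
                 class_names = train$class_names),
            class = c("gs_fit_rf", "gs_fitted"))
}

#' @export
gs_predict.gs_fit_rf <- function(model, features) {
  features <- as.matrix(features)
  prob <- Reduce(`+`, lapply(model$trees,
                             function(tr) .cpp_predict_tree(tr, features)))
  prediction_set(prob / length(model$trees), model$class_names)
}

## ---- single-hidden-layer neural network --------------------------------

#' @export
gs_fit.gs_clf_ann <- function(classifier, train) {
  check_train(train)
  hp <- classifier$spec$hyperparams
  x <- train$features
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  C <- length(train$class_names)
  yi <- as.integer(factor(train$labels, levels = train$class_names))
  Y <- matrix(0, nrow(xs), C)
  Y[cbind(seq_len(nrow(xs)), yi)] <- 1
  p <- ncol(xs)
  H <- hp$hidden

  params <- with_rng_seed(classifier$spec$seed, {
    r1 <- sqrt(6 / (p + H))
    r2 <- sqrt(6 / (H + C))
    list(W1 = matrix(runif(p * H, -r1, r1), p, H), b1 = numeric(H),
         W2 = matrix(runif(H * C, -r2, r2), H, C), b2 = numeric(C))
  })
  # full-batch Adam on cross-entropy + L2; early stop on loss plateau
  m <- lapply(params, function(z) z * 0)
  v <- lapply(params, function(z) z * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  n <- nrow(xs)
  best_loss <- Inf; stall <- 0L
  for (it in seq_len(hp$maxit)) {
    A1 <- tanh(sweep(xs %*% params$W1, 2, params$b1, "+"))
    Z2 <- sweep(A1 %*% params$W2, 2, params$b2, "+")
    Z2 <- Z2 - apply(Z2, 1, max)
    P <- exp(Z2)
    P <- P / rowSums(P)
    loss <- -mean(log(P[cbind(seq_len(n), yi)] + 1e-12)) +
      hp$weight_decay * (sum(params$W1^2) + sum(params$W2^2)) / 2
    if (loss < best_loss - hp$tol) {
      best_loss <- loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= hp$patience) break
    }
    dZ2 <- (P - Y) / n
    grads <- list(
      W1 = crossprod(xs, (dZ2 %*% t(params$W2)) * (1 - A1^2)) +
        hp$weight_decay * params$W1,
      b1 = colSums((dZ2 %*% t(params$W2)) * (1 - A1^2)),
      W2 = crossprod(A1, dZ2) + hp$weight_decay * params$W2,
      b2 = colSums(dZ2)
    )
    for (nm in names(params)) {
      m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * grads[[nm]]
      v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - b1m^it)
      vhat <- v[[nm]] / (1 - b2m^it)
      params[[nm]] <- params[[nm]] - hp$lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(spec = classifier$spec, params = params, center = mu,
                 scale = sg, class_names = train$class_names),
            class = c("gs_fit_ann", "gs_fitted"))
}

#' @export
gs_predict.gs_fit_ann <- function(model, features) {
  xs <- sweep(sweep(as.matrix(features), 2, model$center), 2, model$scale,
              "/")
  A1 <- tanh(sweep(xs %*% model$params$W1, 2, model$params$b1, "+"))
  Z2 <- sweep(A1 %*% model$params$W2, 2, model$params$b2, "+")
  Z2 <- Z2 - apply(Z2, 1, max)
  P <- exp(Z2)
  prediction_set(P / rowSums(P), model$class_names)
}

## ---- RBF SVM (random Fourier features, one-vs-rest) --------------------

#' @export
gs_fit.gs_clf_svm <- function(classifier, train) {
  check_train(train)
  hp <- classifier$spec$hyperparams
  x <- train$features
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  p <- ncol(xs)
  gamma <- hp$gamma %||% (1 / p)
  D <- hp$rff_dim
  rff <- with_rng_seed(classifier$spec$seed, {
    list(W = matrix(rnorm(p * D, sd = sqrt(2 * gamma)), p, D),
         b = runif(D, 0, 2 * pi))
  })
  Z <- sqrt(2 / D) * cos(sweep(xs %*% rff$W, 2, rff$b, "+"))
  n <- nrow(Z)
  lambda <- 1 / (hp$cost * n)
  C <- length(train$class_names)
  yi <- as.integer(factor(train$labels, levels = train$class_names))
  # one-vs-rest squared hinge, fitted by BFGS with analytic gradient
  weights <- matrix(0, D + 1L, C)
  for (k in seq_len(C)) {
    yk <- ifelse(yi == k, 1, -1)
    obj <- function(w) {
      f <- Z %*% w[1:D] + w[D + 1L]
      slack <- pmax(0, 1 - yk * f)
      lambda / 2 * sum(w[1:D]^2) + mean(slack^2)
    }
    grd <- function(w) {
      f <- drop(Z %*% w[1:D] + w[D + 1L])
      slack <- pmax(0, 1 - yk * f)
      coef <- -2 * slack * yk / n
      c(lambda * w[1:D] + drop(crossprod(Z, coef)), sum(coef))
    }
    fit <- optim(numeric(D + 1L), obj, grd, method = "BFGS",
                 control = list(maxit = hp$maxit))
    weights[, k] <- fit$par
  }
  structure(list(spec = classifier$spec, weights = weights, rff = rff,
                 center = mu, scale = sg, class_names = train$class_names),
            class = c("gs_fit_svm", "gs_fitted"))
}

#' @export
gs_predict.gs_fit_svm <- function(model, features) {
  xs <- sweep(sweep(as.matrix(features), 2, model$center), 2, model$scale,
              "/")
  D <- nrow(model$weights) - 1L
  Z <- sqrt(2 / D) * cos(sweep(xs %*% model$rff$W, 2, model$rff$b, "+"))
  dec <- sweep(Z %*% model$weights[1:D, , drop = FALSE], 2,
               model$weights[D + 1L, ], "+")
  # softmax over one-vs-rest margins as the probability surrogate
  dec <- dec - apply(dec, 1, max)
  P <- exp(dec)
  prediction_set(P / rowSums(P), model$class_names)
}

## ---- RF-SVM double classifier ------------------------------------------

#' @export
gs_fit.gs_clf_rf_svm <- function(classifier, train) {
  check_train(train)
  hp <- classifier$spec$hyperparams
  seed <- classifier$spec$seed
  rf_spec <- classifier_spec("rf", hp$rf, seed = seed)
  svm_spec <- classifier_spec("svm", hp$svm, seed = derive_seed(seed, 1L))
  rf_model <- tryCatch(gs_fit(make_classifier(rf_spec), train),
                       error = function(e) stop("RF component failed: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  if (identical(hp$combine, "stack")) {
    # stacking: RF out-of-fold class probabilities become the SVM inputs
    oof <- rf_oof_probabilities(rf_spec, train, hp$stack_folds)
    stack_train <- gs_dataset(oof, train$labels,
                              paste0("rf_prob_", train$class_names),
                              train$class_names)
    svm_model <- tryCatch(gs_fit(make_classifier(svm_spec), stack_train),
                          error = function(e) stop("SVM component failed: ",
                                                   conditionMessage(e),
                                                   call. = FALSE))
  } else {
    svm_model <- tryCatch(gs_fit(make_classifier(svm_spec), train),
                          error = function(e) stop("SVM component failed: ",
                                                   conditionMessage(e),
                                                   call. = FALSE))
  }
  structure(list(spec = classifier$spec, rf = rf_model, svm = svm_model,
                 combine = hp$combine, class_names = train$class_names),
            class = c("gs_fit_rf_svm", "gs_fitted"))
}

rf_oof_probabilities <- function(rf_spec, train, folds) {
  n <- nrow(train$features)
  fold_id <- with_rng_seed(derive_seed(rf_spec$seed, 2L),
                           sample(rep_len(seq_len(folds), n)))
  C <- length(train$class_names)
  oof <- matrix(1 / C, n, C)
  for (f in seq_len(folds)) {
    tr_rows <- which(fold_id != f)
    te_rows <- which(fold_id == f)
    if (length(unique(train$labels[tr_rows])) < 2L) next
    sub <- gs_dataset(train$features[tr_rows, , drop = FALSE],
                      train$labels[tr_rows], train$feature_names,
                      train$class_names)
    mod <- gs_fit(make_classifier(rf_spec), sub)
    oof[te_rows, ] <-
      gs_predict(mod, train$features[te_rows, , drop = FALSE])$probabilities
  }
  oof
}

#' @export
gs_predict.gs_fit_rf_svm <- function(model, features) {
  rf_pred <- gs_predict(model$rf, features)
  if (identical(model$combine, "stack")) {
    svm_pred <- gs_predict(model$svm, rf_pred$probabilities)
    return(prediction_set(svm_pred$probabilities, model$class_names))
  }
  svm_pred <- gs_predict(model$svm, features)
  prediction_set((rf_pred$probabilities + svm_pred$probabilities) / 2,
                 model$class_names)
}

#' Combine RF and SVM probabilities for a test block in one call
#'
#' Convenience wrapper mirroring the double-classifier contract: fit both
#' components on `train` and return the soft-voted (or stacked) prediction
#' for `test_features`.
#'
#' @param train a [gs_dataset()].
#' @param test_features numeric matrix.
#' @param spec a [classifier_spec()] with name `"rf_svm"`.
#' @return A `gs_prediction`.
#' @export
rf_svm_predict <- function(train, test_features, spec = classifier_spec("rf_svm")) {
  stopifnot(identical(spec$name, "rf_svm"))
  model <- gs_fit(make_classifier(spec), train)
  gs_predict(model, test_features)
}
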