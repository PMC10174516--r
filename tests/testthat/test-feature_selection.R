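test_that("binarize thresholds strictly at 0.5", {
  expect_equal(as.logical(binarize(c(0.7, 0.2, 0.5))),
               c(TRUE, FALSE, FALSE))
  expect_equal(attr(binarize(c(0.7, 0.2, 0.5)), "count"), 1L)
  expect_true(all(binarize(c(0.51, 0.9, 1))))
  expect_false(any(binarize(c(-1, 0, 0.5))))
  expect_true(all(binarize(c(0.2, 0.3), threshold = 0.1)))
})

test_that("subset_fitness combines holdout error and subset size", {
  sp <- exact_error_split() # k=1 nearest neighbour error exactly 0.1
  spec <- fitness_spec(lambda = 0.99,
                       classifier = classifier_spec("knn", list(k = 1L)))
  mask <- rep(FALSE, 37)
  mask[1:10] <- TRUE # informative column + 9 constants
  fit <- subset_fitness(mask, sp, spec)
  expect_equal(fit, 0.99 * 0.1 + 0.01 * 10 / 37, tolerance = 1e-12)
  expect_lt(abs(fit - 0.101703), 1e-6) # agreement at the printed precision

  # lambda = 1: the size term vanishes
  spec1 <- fitness_spec(lambda = 1,
                        classifier = classifier_spec("knn", list(k = 1L)))
  expect_equal(subset_fitness(mask, sp, spec1), 0.1, tolerance = 1e-12)

  # perfect subset with all features: Fit = (1 - lambda)
  full <- rep(TRUE, 37)
  sp0 <- exact_error_split(n_wrong = 0L)
  expect_equal(subset_fitness(full, sp0, spec), 0.01, tolerance = 1e-12)

  # all-zero mask: penalty 1 + lambda, no classifier fit
  expect_equal(subset_fitness(rep(FALSE, 37), sp, spec), 1.99)
  expect_error(subset_fitness(rep(TRUE, 5), sp, spec), "mask length")
})

test_that("fitness is monotone in error and in mask size", {
  spec <- fitness_spec(lambda = 0.9,
                       classifier = classifier_spec("knn", list(k = 1L)))
  sp_worse <- exact_error_split(n_wrong = 8L)
  sp_better <- exact_error_split(n_wrong = 2L)
  mask <- c(TRUE, rep(FALSE, 36))
  expect_gt(subset_fitness(mask, sp_worse, spec),
            subset_fitness(mask, sp_better, spec))
  bigger <- rep(FALSE, 37)
  bigger[1:20] <- TRUE # same error (extra columns constant), more features
  expect_gt(subset_fitness(bigger, sp_better, spec),
            subset_fitness(mask, sp_better, spec))
})

test_that("apply_mask projects columns and keeps names", {
  d <- gs_dataset(matrix(1:12, 4, 3), rep(c("a", "b"), 2),
                  c("f1", "f2", "f3"))
  expect_identical(apply_mask(d, rep(TRUE, 3)), d)
  proj <- apply_mask(d, c(TRUE, FALSE, TRUE))
  expect_equal(proj$feature_names, c("f1", "f3"))
  expect_equal(ncol(proj$features), 2L)
  expect_error(apply_mask(d, c(TRUE, FALSE)), "mask length")
})

test_that("select_features is deterministic and caches mask fitness", {
  g <- small_generated(per_class = 20L, n_informative = 2L, n_noise = 6L,
                       effect_size = 3, seed = 4)
  s1 <- select_features(g$dataset, "hgso", fitness_spec(), n_agents = 6,
                        max_iter = 8, seed = 3)
  s2 <- select_features(g$dataset, "hgso", fitness_spec(), n_agents = 6,
                        max_iter = 8, seed = 3)
  expect_identical(s1$best_mask, s2$best_mask)
  expect_identical(s1$best_fitness, s2$best_fitness)
  expect_identical(s1$trace, s2$trace)
  # cache: distinct masks evaluated is far below total evaluations
  expect_lte(s1$n_evaluations, 6 * 9)
  expect_gte(attr(s1$best_mask, "count"), 1L)
})

test_that("lambda = 0 drives the mask toward a single feature", {
  g <- small_generated(per_class = 15L, n_informative = 2L, n_noise = 8L,
                       seed = 2)
  sel <- select_features(g$dataset, "hgso",
                         fitness_spec(lambda = 0), n_agents = 10,
                         max_iter = 20, seed = 6)
  expect_lte(attr(sel$best_mask, "count"), 2L)
  expect_equal(sel$best_fitness, attr(sel$best_mask, "count") /
                 length(sel$best_mask), tolerance = 1e-12)
})

test_that("a single strongly informative feature is recovered", {
  hits <- vapply(1:5, function(s) {
    g <- generate_dataset(generator_spec(
      class_counts = rep(30L, 4L), n_informative = 1L, n_noise = 9L,
      effect_size = 4, binary_noise_frac = 0, seed = s
    ))
    sel <- select_features(g$dataset, "hgso", fitness_spec(), n_agents = 8,
                           max_iter = 15, seed = s)
    as.logical(sel$best_mask)[1]
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("every optimizer strategy drives the selection loop", {
  g <- small_generated(per_class = 15L, n_informative = 2L, n_noise = 4L,
                       effect_size = 3, seed = 8)
  for (strat in c("hgso", "aqo", "hybrid")) {
    sel <- select_features(g$dataset, strat, fitness_spec(), n_agents = 6,
                           max_iter = 6, seed = 2)
    expect_s3_class(sel, "gs_selection_result")
    expect_true(all(diff(sel$trace$best_fitness) <= 0))
  }
})

test_that("selection results serialize to JSON with a 0/1 mask string", {
  g <- small_generated(per_class = 15L, n_informative = 2L, n_noise = 4L,
                       seed = 3)
  sel <- select_features(g$dataset, "hgso", fitness_spec(), n_agents = 6,
                         max_iter = 5, seed = 1)
  js <- withr::local_tempfile(fileext = ".json")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_selection(sel, g$dataset, js, txt)
  out <- jsonlite::read_json(js)
  expect_equal(nchar(out$mask), ncol(g$dataset$features))
  expect_equal(out$n_selected, attr(sel$best_mask, "count"))
  expect_length(readLines(txt), attr(sel$best_mask, "count"))
})
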