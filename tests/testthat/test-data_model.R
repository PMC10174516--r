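test_that("load_csv parses, validates and reports cell coordinates", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f1,f2,outcome", "1,2,a", "3,4,b", "5,6,a"), p)
  d <- load_csv(p, "outcome")
  expect_s3_class(d, "gs_dataset")
  expect_equal(dim(d$features), c(3L, 2L))
  expect_equal(d$feature_names, c("f1", "f2"))
  expect_equal(d$class_names, c("a", "b"))

  writeLines(c("f1,outcome", "1,w", "2,x", "3,y", "4,z"), p)
  expect_length(load_csv(p, "outcome")$class_names, 4L)

  writeLines(c("f1,f2,outcome", "1,,a"), p)
  expect_error(load_csv(p, "outcome"), "empty cell at row 1, column 'f2'")
  writeLines(c("f1,f2,outcome", "1,oops,a"), p)
  expect_error(load_csv(p, "outcome"), "non-numeric value 'oops' at row 1")
  expect_error(load_csv(p, "missing_col"), "label column")
  expect_error(load_csv(file.path(tempdir(), "no-such.csv"), "outcome"),
               "file not found")
})

test_that("write_csv/load_csv round-trips doubles to full precision", {
  d <- gs_dataset(matrix(c(pi, exp(1), 1 / 3, sqrt(2), 1e-17, -2.5e8), 3, 2),
                  c("a", "b", "a"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_csv(d, p)
  back <- load_csv(p, "outcome")
  expect_identical(back$features, d$features)
  expect_identical(back$labels, d$labels)
})

test_that("gs_dataset enforces its invariants", {
  expect_error(gs_dataset(matrix(0, 3, 1), c("a", "b")), "rows")
  expect_error(gs_dataset(matrix(NA_real_, 2, 1), c("a", "b")), "missing")
  expect_error(gs_dataset(matrix(0, 2, 1), c("a", "b"),
                          feature_names = c("x", "y")), "length")
  expect_error(gs_dataset(matrix(0, 2, 1), c("a", "z"),
                          class_names = c("a", "b")), "outside class_names")
})

test_that("encode_features applies declared rules and min-max range", {
  raw <- data.frame(
    severity = c("mild", "moderate", "severe", "mild"),
    marker = c(0, 5, 10, 5),
    flag = c("no", "yes", "yes", "no"),
    site = c("L", "R", "L", "M"),
    stringsAsFactors = FALSE
  )
  rules <- list(
    severity = list(type = "ordinal", map = c(mild = 0, moderate = 1,
                                              severe = 2)),
    marker = list(type = "numeric"),
    flag = list(type = "ordinal", map = c(no = 0, yes = 1)),
    site = list(type = "onehot")
  )
  enc01 <- encode_features(raw, rules, domain_range = c(0, 1))
  expect_equal(unname(enc01[, "severity"]), c(0, 0.5, 1, 0))
  expect_equal(unname(enc01[, "flag"]), c(0, 1, 1, 0)) # binary stays 0/1
  expect_equal(colnames(enc01),
               c("severity", "marker", "flag", "site.L", "site.M", "site.R"))

  # numeric [0,5,10] min-max to [-1,1] -> [-1,0,1]
  enc <- encode_features(raw, rules)
  expect_equal(unname(enc[, "marker"]), c(-1, 0, 1, 0))

  # unseen category: strict errors, lenient maps to midpoint
  raw2 <- raw
  raw2$severity[1] <- "critical"
  expect_error(encode_features(raw2, rules), "unseen category")
  lenient <- encode_features(raw2, rules, strict = FALSE,
                             domain_range = c(0, 2))
  expect_true(is.finite(lenient[1, "severity"]))

  expect_error(encode_features(raw, rules[-1]), "no encoding rule")
})

test_that("constant columns map to the domain midpoint", {
  raw <- data.frame(const = c(7, 7, 7), var = c(1, 2, 3))
  rules <- list(const = list(type = "numeric"), var = list(type = "numeric"))
  enc <- encode_features(raw, rules, domain_range = c(-1, 1))
  expect_equal(unname(enc[, "const"]), c(0, 0, 0))
  enc2 <- encode_features(raw, rules, domain_range = c(0, 4))
  expect_equal(unname(enc2[, "const"]), c(2, 2, 2))
})

test_that("encoding is idempotent on already-normalized numeric input", {
  m <- matrix(c(-1, 0, 1, -1, 1, 0.5), 3, 2)
  raw <- as.data.frame(m)
  rules <- list(V1 = list(type = "numeric"), V2 = list(type = "numeric"))
  once <- encode_features(raw, rules, domain_range = c(-1, 1))
  twice <- encode_features(as.data.frame(once), rules,
                           domain_range = c(-1, 1))
  expect_equal(unname(twice), unname(once), tolerance = 1e-12)
})

test_that("missing cells are rejected unless imputation is requested", {
  raw <- data.frame(x = c(1, NA, 3))
  rules <- list(x = list(type = "numeric"))
  expect_error(encode_features(raw, rules), "missing value")
  imp <- encode_features(raw, rules, impute = TRUE, domain_range = c(0, 1))
  expect_false(anyNA(imp))
})

test_that("train_test_split sizes, determinism, stratification", {
  counts <- c(800L, 700L, 850L, 650L)
  labels <- rep(letters[1:4], times = counts)
  d <- gs_dataset(matrix(rnorm(3000), ncol = 1), labels)
  sp <- train_test_split(d, 0.8, seed = 7)
  expect_equal(nrow(sp$train$features), 2400L)
  expect_equal(nrow(sp$test$features), 600L)
  # stratified proportions within one sample of 0.8 per class
  for (cl in letters[1:4]) {
    n_tr <- sum(sp$train$labels == cl)
    expect_lte(abs(n_tr - 0.8 * counts[match(cl, letters)]), 1)
  }
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(3000))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)

  sp2 <- train_test_split(d, 0.8, seed = 7)
  expect_identical(sp$train_idx, sp2$train_idx)

  tiny <- gs_dataset(matrix(1:4, ncol = 1), c("a", "a", "b", "b"))
  half <- train_test_split(tiny, 0.5, seed = 1)
  expect_setequal(unique(half$train$labels), c("a", "b"))
  expect_setequal(unique(half$test$labels), c("a", "b"))

  solo <- gs_dataset(matrix(1:3, ncol = 1), c("a", "a", "b"))
  expect_error(train_test_split(solo, 0.5, seed = 1), "single sample")
})

test_that("splits at f and 1-f with one seed partition complementarily", {
  d <- small_generated(per_class = 30L)$dataset
  a <- train_test_split(d, 0.8, seed = 11)
  b <- train_test_split(d, 0.2, seed = 11)
  expect_identical(a$train_idx, sort(b$test_idx))
  expect_identical(a$test_idx, sort(b$train_idx))
})
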