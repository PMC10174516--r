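test_that("confusion tallies true x predicted counts", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 1L, 1L), 2,
                      dimnames = list(true = c("a", "b"),
                                      predicted = c("a", "b"))))
  perfect <- confusion(letters[1:4], letters[1:4])
  expect_equal(unname(diag(unclass(perfect))), rep(1L, 4))
  expect_equal(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion("a", "z", class_names = c("a", "b")), "outside")
  expect_error(confusion(c("a", "b"), "a"), "lengths differ")
})

test_that("binary metrics match the printed formulas", {
  m <- binary_metrics(5, 1, 2, 12)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$recall, 0.714286, tolerance = 1e-6)
  expect_equal(m$precision, 0.833333, tolerance = 1e-6)
  expect_equal(m$f_measure, 0.769231, tolerance = 1e-6)
  expect_equal(m$sensitivity, m$recall)
  expect_false(m$degenerate)

  perfect <- binary_metrics(3, 0, 0, 9)
  expect_equal(unlist(perfect[c("accuracy", "recall", "precision",
                                "f_measure")]),
               c(accuracy = 1, recall = 1, precision = 1, f_measure = 1))

  zero_tp <- binary_metrics(0, 0, 4, 6)
  expect_equal(zero_tp$recall, 0)
  expect_true(zero_tp$degenerate) # precision had a zero denominator
  expect_error(binary_metrics(0, 0, 0, 0), "zero")
  expect_error(binary_metrics(-1, 0, 0, 2), "negative")
})

test_that("binary metrics agree with a brute-force recount from labels", {
  set.seed(3)
  for (rep in 1:20) {
    truth <- sample(c("pos", "neg"), 40, replace = TRUE)
    pred <- sample(c("pos", "neg"), 40, replace = TRUE)
    tp <- sum(truth == "pos" & pred == "pos")
    fp <- sum(truth == "neg" & pred == "pos")
    fn <- sum(truth == "pos" & pred == "neg")
    tn <- sum(truth == "neg" & pred == "neg")
    m <- binary_metrics(tp, fp, fn, tn)
    expect_equal(m$accuracy, mean(truth == pred), tolerance = 1e-12)
    if (tp + fn > 0) {
      expect_equal(m$recall, tp / (tp + fn), tolerance = 1e-12)
    }
    expect_true(m$f_measure >= min(m$precision, m$recall) - 1e-12)
    expect_true(m$f_measure <= max(m$precision, m$recall) + 1e-12)
  }
})

test_that("macro metrics: diagonal, 2-class reduction, chance level", {
  cm <- confusion(rep(letters[1:4], each = 5), rep(letters[1:4], each = 5))
  mm <- macro_metrics(cm)
  expect_equal(unlist(mm[c("accuracy", "recall", "precision",
                           "f_measure", "sensitivity")]),
               c(accuracy = 1, recall = 1, precision = 1, f_measure = 1,
                 sensitivity = 1))

  # C = 2: macro equals the average of the two one-vs-rest binary records
  set.seed(11)
  for (rep in 1:10) {
    truth <- sample(c("a", "b"), 60, replace = TRUE)
    pred <- sample(c("a", "b"), 60, replace = TRUE)
    cm2 <- confusion(truth, pred, c("a", "b"))
    mm2 <- macro_metrics(cm2)
    cmat <- unclass(cm2)
    pos <- binary_metrics(cmat[1, 1], cmat[2, 1], cmat[1, 2], cmat[2, 2])
    neg <- binary_metrics(cmat[2, 2], cmat[1, 2], cmat[2, 1], cmat[1, 1])
    expect_equal(mm2$recall, (pos$recall + neg$recall) / 2,
                 tolerance = 1e-12)
    expect_equal(mm2$precision, (pos$precision + neg$precision) / 2,
                 tolerance = 1e-12)
    expect_equal(mm2$f_measure, (pos$f_measure + neg$f_measure) / 2,
                 tolerance = 1e-12)
  }

  # uniform random predictions over 4 balanced classes: accuracy ~ 0.25
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    truth <- rep(letters[1:4], each = 1000)
    pred <- sample(letters[1:4], 4000, replace = TRUE)
    macro_metrics(confusion(truth, pred))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.02)
})

test_that("signed-rank test matches brute-force enumeration", {
  # frozen example: differences 1, -2, 3, 4
  w <- suppressWarnings(wilcoxon_signed_rank(c(2, 1, 5, 7), c(1, 3, 2, 3)))
  expect_equal(w$statistic, 2)
  expect_equal(w$w_plus, 8)
  expect_equal(w$p_value, 6 / 16)
  expect_equal(w$n_effective, 4L)
  expect_equal(w$method, "exact")

  # independent oracle: enumerate all sign patterns explicitly
  enum_p <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d))
    stat <- min(sum(r[d > 0]), sum(r[d < 0]))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    wplus <- signs %*% r
    min(1, 2 * mean(wplus <= stat))
  }
  expect_equal(w$p_value, enum_p(c(1, -2, 3, 4)))

  # all positive, n = 3, distinct magnitudes
  w3 <- suppressWarnings(wilcoxon_signed_rank(c(4, 6, 9), c(3, 4, 5)))
  expect_equal(w3$statistic, 0)
  expect_equal(w3$p_value, 2 / 8)

  # ties in |d| are handled with midranks, still matching the oracle
  set.seed(7)
  for (rep in 1:5) {
    d <- sample(c(-3:-1, 1:3), 8, replace = TRUE)
    got <- suppressWarnings(wilcoxon_signed_rank(d, rep(0, 8)))
    expect_equal(got$p_value, enum_p(d), tolerance = 1e-12)
  }

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
})

test_that("exact p agrees with stats::wilcox.test on untied data", {
  set.seed(21)
  for (rep in 1:5) {
    a <- rnorm(12)
    b <- rnorm(12)
    mine <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and normal approximations agree at moderate n", {
  set.seed(15)
  a <- rnorm(15)
  b <- rnorm(15)
  ex <- wilcoxon_signed_rank(a, b)
  ap <- wilcoxon_signed_rank(a, b, exact_limit = 0L)
  expect_equal(ap$method, "normal")
  expect_lt(abs(ex$p_value - ap$p_value), 0.05)
  expect_lte(ex$statistic, ex$n_effective * (ex$n_effective + 1) / 4)
})
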