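# Shared fixtures: all built in code, no files.

# tiny 4-class dataset with a planted signal, cheap enough for any test
small_generated <- function(per_class = 40L, n_informative = 4L,
                            n_noise = 8L, effect_size = 2, seed = 1L) {
  generate_dataset(generator_spec(
    class_counts = rep(per_class, 4L), n_informative = n_informative,
    n_noise = n_noise, effect_size = effect_size, seed = seed
  ))
}

# dataset with given labels and an uninformative single feature
label_only_dataset <- function(labels) {
  gs_dataset(matrix(seq_along(labels), ncol = 1), labels)
}

# 2-class, 1-feature, perfectly separable toy set
separable_toy <- function(n_per_class = 20L) {
  x <- c(seq(-2, -1, length.out = n_per_class),
         seq(1, 2, length.out = n_per_class))
  gs_dataset(cbind(f1 = x, f2 = 0), rep(c("neg", "pos"), each = n_per_class))
}

# split whose k=1 nearest-neighbour test error is exactly `n_wrong/n_test`,
# padded with constant columns up to `d` features
exact_error_split <- function(n_train = 20L, n_test = 40L, n_wrong = 4L,
                              d = 37L) {
  stopifnot(n_test %% n_train == 0L)
  train_x <- matrix(0, n_train, d)
  train_x[, 1] <- seq_len(n_train)
  train_lab <- rep(c("a", "b"), each = n_train / 2)
  reps <- n_test / n_train
  test_x <- matrix(0, n_test, d)
  test_x[, 1] <- rep(seq_len(n_train), reps)
  test_lab <- rep(train_lab, reps)
  flip <- seq_len(n_wrong) # mislabel the first n_wrong test rows
  test_lab[flip] <- ifelse(test_lab[flip] == "a", "b", "a")
  feature_names <- paste0("f", seq_len(d))
  structure(
    list(train = gs_dataset(train_x, train_lab, feature_names, c("a", "b")),
         test = gs_dataset(test_x, test_lab, feature_names, c("a", "b")),
         fraction = n_train / (n_train + n_test), seed = 0L,
         train_idx = seq_len(n_train),
         test_idx = n_train + seq_len(n_test)),
    class = "gs_split"
  )
}

sphere <- function(x) sum(x^2)

jaccard <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (!any(a | b)) return(NA_real_)
  sum(a & b) / sum(a | b)
}
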