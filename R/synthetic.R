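#' Specification for the synthetic neurosurgical-style data generator
#'
#' Describes a tabular classification problem shaped like an encoded
#' neurosurgical patient extract: four outcome states (mortality, morbidity,
#' the same, improved), a mix of informative and pure-noise features, and
#' feature names tagged by clinical domain group (history / clinical / lab /
#' radiology). Defaults follow the published cohort structure: class counts
#' 800/700/850/650 (3000 records) and 37 encoded features.
#'
#' Informative features carry a planted class signal: for each informative
#' column the four classes sit at centred, equally spaced levels whose
#' consecutive gap is `effect_size` (in units of the within-class SD, which
#' is 1), and the class-to-level assignment is a fresh random permutation per
#' column. Noise features are class-independent Gaussians with SD
#' `noise_scale`. A fraction of the noise columns is dichotomized at its
#' latent median to emulate binary radiology-style flags. All columns are
#' finally min-max mapped into `domain_range`.
#'
#' @param class_counts integer vector of 4 per-class sample counts.
#' @param n_informative number of informative features (default 12).
#' @param n_noise number of pure-noise features (default 25; the defaults sum
#'   to the 37-attribute schema).
#' @param effect_size consecutive-level class separation on informative
#'   features, in within-class SD units (default 2).
#' @param noise_scale SD of the noise features (default 1).
#' @param binary_noise_frac fraction of noise columns dichotomized into 0/1
#'   flags (default 0.25).
#' @param domain_range target range of the encoded features (default
#'   `c(-1, 1)`).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `gs_generator_spec`.
#' @export
generator_spec <- function(class_counts = c(800L, 700L, 850L, 650L),
                           n_informative = 12L, n_noise = 25L,
                           effect_size = 2, noise_scale = 1,
                           binary_noise_frac = 0.25,
                           domain_range = c(-1, 1), seed = 1L) {
  stopifnot(length(class_counts) == 4L, all(class_counts >= 1L),
            n_informative >= 1L, n_noise >= 0L,
            effect_size >= 0, noise_scale > 0,
            binary_noise_frac >= 0, binary_noise_frac <= 1,
            length(domain_range) == 2L, domain_range[1] < domain_range[2])
  if (sum(class_counts) < 1L) stop("zero total samples", call. = FALSE)
  structure(
    list(class_counts = as.integer(class_counts),
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise),
         effect_size = effect_size, noise_scale = noise_scale,
         binary_noise_frac = binary_noise_frac,
         domain_range = domain_range, seed = as.integer(seed)),
    class = "gs_generator_spec"
  )
}

# outcome states of the clinical schema, in fixed order
outcome_classes <- c("mortality", "morbidity", "the_same", "improved")

# clinical domain groups used to tag generated feature names
domain_groups <- c("hist", "clin", "lab", "rad")

#' Generate a synthetic dataset with planted informative features
#'
#' Draws a dataset according to a [generator_spec()] together with its ground
#' truth (which columns are informative and the class centroids), so feature
#' recovery by a wrapper selector is measurable. This is a statistical
#' stand-in for a private clinical extract, not a clinical simulator: it
#' reproduces the cohort's shape (class counts, feature count, mixed
#' informative/noise structure, binary flags), not physiological
#' correlations.
#'
#' @param spec a [generator_spec()].
#' @return list with elements `dataset` (a [gs_dataset()]) and `truth`
#'   (class `gs_ground_truth`: `informative_mask` logical vector,
#'   `class_centroids` 4 x n_informative matrix of latent class means).
#' @examples
#' g <- generate_dataset(generator_spec(class_counts = c(30, 30, 30, 30),
#'                                      n_informative = 3, n_noise = 5))
#' dim(g$dataset$features)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "gs_generator_spec"))
  n <- sum(spec$class_counts)
  d <- spec$n_informative + spec$n_noise
  labels <- rep(outcome_classes, times = spec$class_counts)
  cls_idx <- rep(seq_len(4L), times = spec$class_counts)

  out <- with_rng_seed(spec$seed, {
    # centred equally spaced class levels, consecutive gap = effect_size
    levels4 <- spec$effect_size * (seq_len(4L) - 2.5)
    centroids <- matrix(0, 4L, spec$n_informative)
    X <- matrix(0, n, d)
    for (j in seq_len(spec$n_informative)) {
      perm <- sample.int(4L)
      centroids[, j] <- levels4[perm]
      X[, j] <- centroids[cls_idx, j] + rnorm(n)
    }
    if (spec$n_noise > 0L) {
      X[, spec$n_informative + seq_len(spec$n_noise)] <-
        matrix(rnorm(n * spec$n_noise, sd = spec$noise_scale), n, spec$n_noise)
    }
    # dichotomize a leading block of noise columns at the latent median:
    # binary radiology-style flags with a well-defined (class-free) truth
    n_bin <- floor(spec$n_noise * spec$binary_noise_frac)
    bin_cols <- if (n_bin > 0L) spec$n_informative + seq_len(n_bin) else integer(0)
    for (j in bin_cols) X[, j] <- as.numeric(X[, j] > median(X[, j]))
    list(X = X, centroids = centroids, bin_cols = bin_cols)
  })

  groups <- rep_len(domain_groups, d)
  feature_names <- sprintf("%s_f%02d", groups, seq_len(d))
  X <- minmax_normalize(out$X, spec$domain_range)
  colnames(X) <- feature_names
  dataset <- gs_dataset(X, labels, feature_names, outcome_classes)
  truth <- structure(
    list(informative_mask = seq_len(d) <= spec$n_informative,
         class_centroids = out$centroids),
    class = "gs_ground_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' Summarize a dataset
#'
#' @param dataset a [gs_dataset()].
#' @return list with `n_samples`, `n_features`, `class_counts` (named),
#'   `balance_ratio` (max/min class count), and a data.frame
#'   `feature_stats` of per-feature mean and SD.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "gs_dataset"))
  if (nrow(dataset$features) == 0L) stop("empty dataset", call. = FALSE)
  counts <- table(factor(dataset$labels, levels = dataset$class_names))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(
    n_samples = nrow(dataset$features),
    n_features = ncol(dataset$features),
    class_counts = counts,
    balance_ratio = max(counts) / min(counts[counts > 0]),
    feature_stats = data.frame(
      feature = dataset$feature_names,
      mean = colMeans(dataset$features),
      sd = apply(dataset$features, 2, sd),
      row.names = NULL
    )
  )
}

#' Write a generated dataset and its ground truth to disk
#'
#' CSV for the dataset (via [write_csv()]) and a JSON sidecar for the ground
#' truth, both plain text.
#'
#' @param generated list from [generate_dataset()].
#' @param csv_path,truth_path output paths.
#' @return invisible list of the two paths.
#' @export
write_generated <- function(generated, csv_path, truth_path) {
  write_csv(generated$dataset, csv_path)
  jsonlite::write_json(
    list(informative_mask = as.integer(generated$truth$informative_mask),
         class_centroids = generated$truth$class_centroids),
    truth_path, digits = NA, auto_unbox = FALSE
  )
  invisible(list(csv = csv_path, truth = truth_path))
}
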