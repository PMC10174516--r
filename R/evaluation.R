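#' Confusion matrix from label vectors
#'
#' @param true_labels,predicted equal-length vectors of class labels.
#' @param class_names class set fixing row/column order; defaults to the
#'   sorted union of observed labels.
#' @return Object of class `gs_confusion`: integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(true_labels, predicted, class_names = NULL) {
  if (length(true_labels) == 0L) stop("empty inputs", call. = FALSE)
  if (length(true_labels) != length(predicted)) {
    stop("true and predicted lengths differ", call. = FALSE)
  }
  true_labels <- as.character(true_labels)
  predicted <- as.character(predicted)
  if (is.null(class_names)) {
    class_names <- sort(unique(c(true_labels, predicted)))
  }
  unknown <- setdiff(unique(c(true_labels, predicted)), class_names)
  if (length(unknown)) {
    stop("labels outside class_names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- table(factor(true_labels, levels = class_names),
             factor(predicted, levels = class_names))
  m <- matrix(as.integer(m), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("gs_confusion", class(m)))
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Recall = TP/(TP+FN),
#' Precision = TP/(TP+FP), F = 2PR/(P+R). A zero denominator yields 0 with
#' `degenerate = TRUE` rather than an error, so batch evaluation stays total.
#' Sensitivity is recall reported under its clinical name.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return Object of class `gs_metrics`: list with `accuracy`, `recall`,
#'   `precision`, `f_measure`, `sensitivity`, `degenerate`.
#' @export
binary_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (sum(counts) == 0) stop("all counts zero", call. = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else {
      num / den
    }
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  rec <- safe_div(tp, tp + fn)
  prec <- safe_div(tp, tp + fp)
  f <- if (prec + rec == 0) {
    degenerate <- TRUE
    0
  } else {
    2 * prec * rec / (prec + rec)
  }
  structure(
    list(accuracy = acc, recall = rec, precision = prec, f_measure = f,
         sensitivity = rec, degenerate = degenerate),
    class = "gs_metrics"
  )
}

#' Macro-averaged multi-class metrics
#'
#' Extends the binary formulas to C classes by one-vs-rest reduction:
#' per-class TP/FP/FN/TN are read off the confusion matrix, recall /
#' precision / F are averaged unweighted over classes (macro averaging, apt
#' for a roughly balanced outcome), accuracy is trace/total, and sensitivity
#' equals macro recall.
#'
#' @param cm a [confusion()] matrix.
#' @return A `gs_metrics` record (see [binary_metrics()]) plus a `per_class`
#'   data.frame.
#' @export
macro_metrics <- function(cm) {
  stopifnot(inherits(cm, "gs_confusion"))
  cmat <- unclass(cm)
  C <- nrow(cmat)
  if (C < 2) stop("need at least 2 classes", call. = FALSE)
  total <- sum(cmat)
  per <- data.frame(class = rownames(cmat), recall = NA_real_,
                    precision = NA_real_, f_measure = NA_real_)
  degenerate <- FALSE
  for (k in seq_len(C)) {
    tp <- cmat[k, k]
    fn <- sum(cmat[k, ]) - tp
    fp <- sum(cmat[, k]) - tp
    tn <- total - tp - fn - fp
    b <- binary_metrics(tp, fp, fn, tn)
    per$recall[k] <- b$recall
    per$precision[k] <- b$precision
    per$f_measure[k] <- b$f_measure
    degenerate <- degenerate || b$degenerate
  }
  rec <- mean(per$recall)
  prec <- mean(per$precision)
  structure(
    list(accuracy = sum(diag(cmat)) / total,
         recall = rec, precision = prec,
         f_measure = mean(per$f_measure),
         sensitivity = rec, degenerate = degenerate, per_class = per),
    class = "gs_metrics"
  )
}

#' @export
print.gs_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | recall %.4f | precision %.4f | F %.4f | sensitivity %.4f%s\n",
    x$accuracy, x$recall, x$precision, x$f_measure, x$sensitivity,
    if (isTRUE(x$degenerate)) " [degenerate ratios -> 0]" else ""))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Paired comparison of two models' per-run scores: zero differences are
#' dropped, absolute differences are ranked with midrank ties, and the
#' statistic is the smaller of the positive and negative rank sums. The
#' two-sided p-value is exact for n <= `exact_limit` effective pairs —
#' computed by enumerating the null distribution of the signed rank sum over
#' all 2^n sign patterns (via a subset-sum convolution, so ties are handled
#' exactly) — and a normal approximation with continuity and tie correction
#' otherwise.
#'
#' @param a,b equal-length numeric vectors of paired scores.
#' @param exact_limit largest n for exact enumeration (default 20).
#' @return Object of class `gs_wilcoxon`: list with `statistic` (min rank
#'   sum), `p_value`, `n_effective`, `method` ("exact" or "normal"), and the
#'   signed rank sums `w_plus`, `w_minus`.
#' @examples
#' wilcoxon_signed_rank(c(2, 1, 5, 7), c(1, 3, 2, 3))
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 20L) {
  if (length(a) != length(b)) stop("paired vectors differ in length",
                                   call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate test: all differences are zero",
                    call. = FALSE)
  if (n < 5L) {
    warning("fewer than 5 non-zero differences; test has little power")
  }
  r <- rank(abs(d)) # midranks on ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  stat <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    p <- exact_signed_rank_p(r, stat)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (stat - mu + 0.5) / sqrt(sigma2) # continuity correction
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  structure(
    list(statistic = stat, p_value = p, n_effective = n, method = method,
         w_plus = w_plus, w_minus = w_minus),
    class = "gs_wilcoxon"
  )
}

# Exact two-sided p for the signed-rank statistic: distribution of W+ under
# random signs, by dynamic-programming convolution over doubled (integer)
# midranks. p = min(1, 2 * P(W <= stat)) by the symmetry of W+ about its mean.
exact_signed_rank_p <- function(ranks, stat) {
  r2 <- as.integer(round(2 * ranks)) # doubled midranks are integers
  total <- sum(r2)
  counts <- numeric(total + 1L) # counts[w + 1] = #patterns with 2*W+ == w
  counts[1L] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), counts[seq_len(total + 1L - v)])
    counts <- counts + shifted
  }
  cdf_le <- sum(counts[seq_len(min(total, floor(2 * stat)) + 1L)])
  min(1, 2 * cdf_le / 2^length(r2))
}

#' @export
print.gs_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: W = %g (W+ = %g, W- = %g), n = %d, p = %.6g (%s)\n",
    x$statistic, x$w_plus, x$w_minus, x$n_effective, x$p_value, x$method))
  invisible(x)
}
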