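#' Mean pairwise similarity of learner confidence vectors
#'
#' For each sample the similarity of a set of \eqn{n} learners is the mean
#' pairwise dot product of their confidence vectors,
#' \deqn{S_s = \frac{2}{n(n-1)} \sum_{i<j} \vec c_i(s) \cdot \vec c_j(s),}
#' which for three learners is
#' \eqn{S = \frac13(\vec c_0\cdot\vec c_1 + \vec c_0\cdot\vec c_2 +
#' \vec c_1\cdot\vec c_2)}. The reported value is the average over the test
#' set. \eqn{S} ranges from 0 (learners concentrate on disjoint classes) to 1
#' (all learners emit the same one-hot vector); identical uniform vectors
#' over K classes give \eqn{S = 1/K}. High \eqn{S} means the learners make
#' near-identical predictions and ensembling has little room to help.
#'
#' The quoted uncertainty is the standard error of the per-sample mean
#' (sample standard deviation of \eqn{S_s} divided by \eqn{\sqrt N}).
#'
#' @param cube A [confidence_cube()] with at least two learners.
#' @return A one-row tibble: `similarity_mean`, `similarity_se`, `n_samples`,
#'   `n_learners`. The per-sample values are attached as attribute
#'   `"per_sample"`.
#' @examples
#' cube <- confidence_cube(array(rep(c(1, 0), each = 3), dim = c(3, 1, 2)))
#' pairwise_similarity(cube) # identical one-hots: S = 1
#' @export
pairwise_similarity <- function(cube) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  n <- n_learners(cube)
  if (n < 2) abort("similarity needs at least two learners.")
  s <- similarity_per_sample(cube)
  out <- tibble::tibble(
    similarity_mean = mean(s),
    similarity_se = if (length(s) > 1) sd(s) / sqrt(length(s)) else 0,
    n_samples = length(s),
    n_learners = n
  )
  attr(out, "per_sample") <- s
  out
}

similarity_per_sample <- function(cube) {
  n <- n_learners(cube)
  npairs <- n * (n - 1) / 2
  acc <- numeric(n_samples(cube))
  mats <- lapply(seq_len(n), function(i) learner_matrix(cube, i))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      acc <- acc + rowSums(mats[[i]] * mats[[j]])
    }
  }
  unname(acc / npairs)
}

#' Right/wrong agreement patterns across learners
#'
#' For every sample, counts how many learners predict the wrong class and
#' histograms the result over `m = 0..n` wrong learners. For three learners
#' the bins carry the conventional labels RRR (all right), RRW (one wrong),
#' RWW (two wrong) and WWW (all wrong); for other `n` the labels are built
#' the same way (e.g. RR/RW/WW for two learners).
#'
#' `conditional_patterns()` computes the same histogram restricted to the
#' samples that the ensemble (under the given combination rule) classifies
#' correctly. Comparing the two shows where the ensemble earns its advantage:
#' a conditional RWW count > 0 means samples were *rescued* — predicted
#' correctly although two of three learners were individually wrong.
#'
#' @param cube A [confidence_cube()].
#' @param labels True class indices (1-based), or a data frame with a
#'   `true_class` column.
#' @param rule Combination rule for the conditioning ensemble.
#' @return A tibble with one row per pattern: `pattern` (label), `n_wrong`,
#'   `count`. Conditional tables additionally carry the `rule` and the number
#'   of ensemble-correct samples as columns `rule`, `n_conditioned`.
#' @examples
#' cube <- confidence_cube(array(rep(c(0.8, 0.2), each = 3), dim = c(3, 1, 2)))
#' agreement_patterns(cube, labels = 1)
#' @export
agreement_patterns <- function(cube, labels) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  truth <- check_labels(labels, cube)
  pattern_table(wrong_counts(cube, truth), n_learners(cube))
}

#' @rdname agreement_patterns
#' @export
conditional_patterns <- function(cube, labels,
                                 rule = c("arithmetic", "geometric")) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  rule <- match.arg(rule)
  truth <- check_labels(labels, cube)
  keep <- ensemble_predict(cube, rule)$prediction == truth
  out <- pattern_table(wrong_counts(cube, truth)[keep], n_learners(cube))
  out$rule <- rule
  out$n_conditioned <- sum(keep)
  out
}

wrong_counts <- function(cube, truth) {
  preds <- learner_predictions(cube)
  rowSums(preds != truth)
}

pattern_table <- function(m_wrong, n) {
  counts <- tabulate(m_wrong + 1L, nbins = n + 1L)
  tibble::tibble(
    pattern = pattern_labels(n),
    n_wrong = 0:n,
    count = counts
  )
}

pattern_labels <- function(n) {
  vapply(0:n, function(m) {
    paste0(strrep("R", n - m), strrep("W", m))
  }, character(1))
}

check_labels <- function(labels, cube) {
  truth <- label_vector(labels)
  if (length(truth) != n_samples(cube)) {
    abort(sprintf(
      "got %d labels for %d samples.", length(truth), n_samples(cube)
    ))
  }
  if (any(truth < 1L | truth > n_classes(cube))) {
    abort("labels contain class indices outside 1..K.")
  }
  truth
}

#' Top-1 confidence profile per learner
#'
#' Summarizes, per learner, the distribution of the largest component of the
#' confidence vector (the top-1 probability). Peaked learners (top-1 near 1)
#' leave an ensemble little to average over; flatter profiles carry ranking
#' information beyond the argmax and tend to benefit more from averaging.
#'
#' @param cube A [confidence_cube()].
#' @return A tibble with one row per learner: `learner`, `top1_mean`,
#'   `top1_median`, and deciles `d10` ... `d90`.
#' @export
top1_profile <- function(cube) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  purrr::map_dfr(seq_len(n_learners(cube)), function(i) {
    m <- learner_matrix(cube, i)
    top1 <- apply(m, 1, max)
    dec <- quantile(top1, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
    dplyr::bind_cols(
      tibble::tibble(
        learner = learner_names(cube)[i],
        top1_mean = mean(top1),
        top1_median = median(top1)
      ),
      tibble::as_tibble(setNames(as.list(dec), paste0("d", seq(10, 90, 10))))
    )
  })
}

#' Full agreement report for a learner cohort
#'
#' Bundles the agreement diagnostics into one object: unconditional pattern
#' counts, mean pairwise similarity with its standard error, and the
#' per-learner top-1 profile.
#'
#' @param cube A [confidence_cube()] with >= 2 learners.
#' @param labels True class indices.
#' @return An object of class `agreement_report` with elements `patterns`,
#'   `similarity`, `top1`, `n_learners`, `n_samples`. [tidy()] returns the
#'   pattern table; [glance()] the similarity/top-1 summary.
#' @export
agreement_report <- function(cube, labels) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  truth <- check_labels(labels, cube)
  structure(
    list(
      patterns = agreement_patterns(cube, truth),
      similarity = pairwise_similarity(cube),
      top1 = top1_profile(cube),
      n_learners = n_learners(cube),
      n_samples = n_samples(cube)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %d learners, %d samples\n", x$n_learners, x$n_samples
  ))
  cat(sprintf(
    "similarity S = %.4f +- %.4f\n",
    x$similarity$similarity_mean, x$similarity$similarity_se
  ))
  cat("patterns:", paste(sprintf("%s=%d", x$patterns$pattern, x$patterns$count),
    collapse = "  "), "\n")
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) x$patterns

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n_learners = x$n_learners,
    n_samples = x$n_samples,
    similarity_mean = x$similarity$similarity_mean,
    similarity_se = x$similarity$similarity_se,
    top1_mean = mean(x$top1$top1_mean)
  )
}

#' Side-by-side comparison of two agreement reports
#'
#' Tabulates pattern counts of two cohorts next to each other with the
#' count ratio b/a per pattern — the comparison used to contrast a
#' high-similarity ensemble with a low-similarity one (e.g. "correct RWW
#' cases are 2.0x more common"). A zero denominator yields an `NA` ratio
#' rather than an error. Similarity and mean top-1 are appended as extra
#' rows with `pattern = "S"` and `"top1_mean"` (their `count` columns hold
#' the real-valued statistics).
#'
#' @param report_a,report_b Two [agreement_report()]s built with the same
#'   number of learners.
#' @return A tibble with columns `pattern`, `count_a`, `count_b`, `ratio`.
#' @export
compare_reports <- function(report_a, report_b) {
  if (!inherits(report_a, "agreement_report") ||
      !inherits(report_b, "agreement_report")) {
    abort("both arguments must be agreement_report objects.")
  }
  if (report_a$n_learners != report_b$n_learners) {
    abort("reports were built with different numbers of learners.")
  }
  counts <- tibble::tibble(
    pattern = report_a$patterns$pattern,
    count_a = as.numeric(report_a$patterns$count),
    count_b = as.numeric(report_b$patterns$count)
  )
  extras <- tibble::tibble(
    pattern = c("S", "S_se", "top1_mean"),
    count_a = c(
      report_a$similarity$similarity_mean,
      report_a$similarity$similarity_se,
      mean(report_a$top1$top1_mean)
    ),
    count_b = c(
      report_b$similarity$similarity_mean,
      report_b$similarity$similarity_se,
      mean(report_b$top1$top1_mean)
    )
  )
  out <- dplyr::bind_rows(counts, extras)
  out$ratio <- ifelse(out$count_a == 0, NA_real_, out$count_b / out$count_a)
  out
}
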