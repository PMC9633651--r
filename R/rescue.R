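#' Rescue analysis of samples with a single correct learner
#'
#' Among three learners, an RWW sample is one where exactly one learner
#' predicts the true class. Whether the ensemble nevertheless gets such a
#' sample right ("rescues" it) depends on the shape of the combined
#' confidence vector: the closer the second-largest component is to the
#' third-largest, the more evenly the two wrong learners spread their
#' confidence over *different* wrong classes, and the better the chance that
#' the single correct learner tips the argmax. The analysis therefore
#' records, per RWW sample, the ratio of the second- to the third-largest
#' component of the combined vector and whether the sample was rescued, then
#' reports the rescue frequency per ratio quantile bin.
#'
#' The ratio is scale-invariant, so it is identical for the raw
#' (unnormalized) and renormalized combined vector; both component values
#' are stored anyway for inspection. A zero third component yields an
#' infinite ratio, which lands in the top bin.
#'
#' The RWW label is only defined for three learners; other learner counts
#' are an error rather than a silent redefinition.
#'
#' @param cube A [confidence_cube()] with exactly 3 learners.
#' @param labels True class indices.
#' @param rule Combination rule used both for the combined vector and the
#'   rescue outcome.
#' @param n_bins Number of quantile bins (default 5). Bins are equal-count
#'   by rank, so sparse RWW sets still populate every bin.
#' @return An object of class `rescue_table`: `samples` — one row per RWW
#'   sample (`sample_id`, `ratio`, `ratio_infinite`, `second_raw`,
#'   `third_raw`, `second_norm`, `third_norm`, `rescued`, `bin`); `bins` —
#'   one row per bin (`bin`, `n`, `ratio_min`, `ratio_max`,
#'   `rescue_frequency`); plus `rule` and `n_rww`. Empty when no RWW sample
#'   exists. [tidy()] returns `samples`; [glance()] summarizes.
#' @export
rww_rescue <- function(cube, labels, rule = c("arithmetic", "geometric"),
                       n_bins = 5) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  rule <- match.arg(rule)
  if (n_learners(cube) != 3L) {
    abort("RWW rescue analysis is defined for exactly 3 learners.")
  }
  if (n_classes(cube) < 3L) {
    abort("the second/third-component ratio needs at least 3 classes.")
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1) {
    abort("`n_bins` must be a single integer >= 1.")
  }
  truth <- check_labels(labels, cube)
  ens <- ensemble_predict(cube, rule)
  rww <- which(wrong_counts(cube, truth) == 2L)

  if (length(rww) == 0L) {
    samples <- tibble::tibble(
      sample_id = character(0), ratio = numeric(0), ratio_infinite = logical(0),
      second_raw = numeric(0), third_raw = numeric(0),
      second_norm = numeric(0), third_norm = numeric(0),
      rescued = logical(0), bin = integer(0)
    )
    bins <- tibble::tibble(
      bin = integer(0), n = integer(0), ratio_min = numeric(0),
      ratio_max = numeric(0), rescue_frequency = numeric(0)
    )
    return(new_rescue_table(samples, bins, rule))
  }

  comb <- ens$combined[rww, , drop = FALSE]
  sorted <- t(apply(comb, 1, sort, decreasing = TRUE))
  second <- sorted[, 2]
  third <- sorted[, 3]
  row_sums <- rowSums(comb)
  ratio <- ifelse(third > 0, second / third, Inf)

  samples <- tibble::tibble(
    sample_id = (sample_ids(cube) %||% as.character(seq_len(n_samples(cube))))[rww],
    ratio = ratio,
    ratio_infinite = !is.finite(ratio),
    second_raw = second,
    third_raw = third,
    second_norm = ifelse(row_sums > 0, second / row_sums, NA_real_),
    third_norm = ifelse(row_sums > 0, third / row_sums, NA_real_),
    rescued = ens$prediction[rww] == truth[rww]
  )
  samples$bin <- dplyr::ntile(samples$ratio, n_bins)
  bins <- samples |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      ratio_min = min(.data$ratio),
      ratio_max = max(.data$ratio),
      rescue_frequency = mean(.data$rescued),
      .groups = "drop"
    )
  new_rescue_table(samples, bins, rule)
}

new_rescue_table <- function(samples, bins, rule) {
  structure(
    list(samples = samples, bins = bins, rule = rule, n_rww = nrow(samples)),
    class = "rescue_table"
  )
}

#' @export
print.rescue_table <- function(x, ...) {
  cat(sprintf(
    "<rescue_table> rule = %s, %d RWW sample(s), %d rescued\n",
    x$rule, x$n_rww, sum(x$samples$rescued)
  ))
  if (nrow(x$bins) > 0) print(x$bins)
  invisible(x)
}

#' @export
tidy.rescue_table <- function(x, ...) x$samples

#' @export
glance.rescue_table <- function(x, ...) {
  tibble::tibble(
    rule = x$rule,
    n_rww = x$n_rww,
    n_rescued = sum(x$samples$rescued),
    rescue_frequency = if (x$n_rww > 0) mean(x$samples$rescued) else NA_real_
  )
}
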