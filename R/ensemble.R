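#' Combine learner confidence vectors into an ensemble prediction
#'
#' Given the confidence vectors \eqn{c_i} of \eqn{n} learners, the arithmetic
#' ensemble averages them component-wise,
#' \deqn{c_{AA,\alpha} = \frac{1}{n}\sum_{i=1}^n c_{i,\alpha},}
#' while the geometric ensemble takes the component-wise geometric mean,
#' \deqn{c_{GA,\alpha} = \Big(\prod_{i=1}^n c_{i,\alpha}\Big)^{1/n}.}
#' Both predict the class with the largest combined component. The geometric
#' vector is reported unnormalized: normalization (and the n-th root itself)
#' rescales all components equally and cannot change the argmax, which is why
#' the bare product rule ([product_rule_predict()]) yields the same
#' predictions.
#'
#' The geometric mean inherits a *veto* property: one learner assigning zero
#' confidence to a class forces the combined confidence of that class to
#' exactly zero. Zeros short-circuit to zero; everything else is computed in
#' the log domain for numerical stability. If every class of a sample is
#' vetoed the combined row is all-zero and carries no argmax information; the
#' prediction for that sample falls back to the arithmetic rule, with a
#' warning, rather than aborting the run.
#'
#' For two learners and two classes the two rules always pick the same class
#' on strictly positive confidences; from three learners or three classes on
#' they can genuinely disagree.
#'
#' @param cube A [confidence_cube()].
#' @param rule `"arithmetic"` or `"geometric"`.
#' @return An object of class `ensemble_result` with elements `rule`,
#'   `combined` (samples x classes matrix; rows on the simplex for the
#'   arithmetic rule, unnormalized for the geometric rule), `prediction`
#'   (1-based class index per sample) and `fallback` (logical per sample,
#'   `TRUE` where the all-vetoed arithmetic fallback was used). Use [tidy()]
#'   for a per-sample tibble and [glance()] for a one-row summary.
#' @examples
#' cube <- confidence_cube(array(
#'   c(0.9, 0.4, 0.1, 0.6), dim = c(2, 1, 2)
#' ))
#' ensemble_predict(cube, "arithmetic")$combined
#' ensemble_predict(cube, "geometric")$combined
#' @export
ensemble_predict <- function(cube, rule = c("arithmetic", "geometric")) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  rule <- match.arg(rule)
  switch(rule,
    arithmetic = arithmetic_ensemble(cube),
    geometric = geometric_ensemble(cube)
  )
}

#' @rdname ensemble_predict
#' @export
arithmetic_ensemble <- function(cube) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  combined <- apply(unclass(cube), c(2, 3), mean)
  combined <- matrix(combined, n_samples(cube), n_classes(cube),
    dimnames = dimnames(cube)[2:3]
  )
  new_ensemble_result("arithmetic", combined, predicted_class(combined),
    fallback = rep(FALSE, nrow(combined))
  )
}

#' @rdname ensemble_predict
#' @export
geometric_ensemble <- function(cube) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  gm <- geometric_combined(cube)
  pred <- predicted_class(gm)
  vetoed <- rowSums(gm) == 0
  if (any(vetoed)) {
    warn(sprintf(
      "%d sample(s) had every class vetoed (zero geometric confidence everywhere); falling back to the arithmetic prediction for them.",
      sum(vetoed)
    ))
    pred[vetoed] <- arithmetic_ensemble(cube)$prediction[vetoed]
  }
  new_ensemble_result("geometric", gm, pred, fallback = vetoed)
}

# component-wise geometric mean in log space; exact zeros propagate as zeros
geometric_combined <- function(cube) {
  d <- dim(cube)
  arr <- unclass(cube)
  any_zero <- apply(arr == 0, c(2, 3), any)
  logs <- log(ifelse(arr == 0, 1, arr)) # placeholder under the zero mask
  mean_log <- apply(logs, c(2, 3), mean)
  gm <- exp(mean_log)
  gm[any_zero] <- 0
  matrix(gm, d[2], d[3], dimnames = dimnames(cube)[2:3])
}

#' Product-rule predictions
#'
#' Predicts, per sample, the class maximizing the raw product
#' \eqn{\prod_i c_{i,\alpha}}. The product is a monotone transform of the
#' geometric mean, so the predictions equal those of [geometric_ensemble()]
#' sample by sample, including the arithmetic fallback on all-vetoed samples.
#'
#' @param cube A [confidence_cube()].
#' @return Integer class index per sample.
#' @export
product_rule_predict <- function(cube) {
  if (!inherits(cube, "confidence_cube")) cube <- confidence_cube(cube)
  geometric_ensemble(cube)$prediction
}

new_ensemble_result <- function(rule, combined, prediction, fallback) {
  structure(
    list(rule = rule, combined = combined, prediction = prediction,
         fallback = fallback),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> rule = %s, %d samples x %d classes%s\n",
    x$rule, nrow(x$combined), ncol(x$combined),
    if (any(x$fallback)) sprintf(" (%d veto fallback)", sum(x$fallback)) else ""
  ))
  invisible(x)
}

#' Tidy an ensemble result into a per-sample tibble
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return A tibble with one row per sample: `sample_id`, `prediction`
#'   (1-based index), `predicted_class` (class name), `confidence` (the
#'   winning combined component), `fallback`.
#' @export
tidy.ensemble_result <- function(x, ...) {
  cls <- colnames(x$combined)
  tibble::tibble(
    sample_id = rownames(x$combined) %||% as.character(seq_len(nrow(x$combined))),
    prediction = x$prediction,
    predicted_class = cls[x$prediction],
    confidence = x$combined[cbind(seq_len(nrow(x$combined)), x$prediction)],
    fallback = x$fallback
  )
}

#' One-row summary of an ensemble result
#'
#' @param x An `ensemble_result`.
#' @param labels Optional true class indices (or data frame with
#'   `true_class`); when supplied, accuracy and macro-F1 are included.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ensemble_result <- function(x, labels = NULL, ...) {
  out <- tibble::tibble(
    rule = x$rule,
    n_samples = nrow(x$combined),
    n_classes = ncol(x$combined),
    n_fallback = sum(x$fallback)
  )
  if (!is.null(labels)) {
    out <- dplyr::bind_cols(
      out,
      classification_metrics(labels, x$prediction, n_classes = ncol(x$combined))[, c("accuracy", "macro_f1")]
    )
  }
  out
}
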