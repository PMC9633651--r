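#' Predicted class of a confidence vector or matrix
#'
#' The prediction of a classifier (or ensemble) is the class with the largest
#' confidence. Ties are broken deterministically towards the smallest class
#' index, so repeated runs on the same input always agree.
#'
#' Because the argmax is invariant under multiplication by a positive scalar,
#' the same function serves normalized confidence vectors, unnormalized
#' geometric means, and raw products.
#'
#' @param x A numeric vector of length K >= 2, or a samples x classes matrix.
#' @return An integer class index (1-based), or a vector of them for a
#'   matrix input.
#' @examples
#' predicted_class(c(0.1, 0.7, 0.2)) # 2
#' predicted_class(c(0.5, 0.5)) # 1: tie-break to the smallest index
#' @export
predicted_class <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2L) abort("need at least two classes.")
    if (nrow(x) == 0L) return(integer(0))
    return(max.col(x, ties.method = "first"))
  }
  if (length(x) < 2L) abort("confidence vector must have length >= 2.")
  which.max(x)
}

#' Per-learner predictions of a confidence cube
#'
#' @param cube A [confidence_cube()].
#' @return Integer matrix, samples x learners, of 1-based class indices.
#' @export
learner_predictions <- function(cube) {
  n <- n_learners(cube)
  out <- matrix(NA_integer_, n_samples(cube), n,
    dimnames = list(sample_ids(cube), learner_names(cube))
  )
  for (i in seq_len(n)) out[, i] <- predicted_class(learner_matrix(cube, i))
  out
}

#' Balanced inverse-frequency class weights
#'
#' Computes the class-reweighting factors used to compensate class imbalance
#' during training: `w_a = N / (K_present * N_a)`, where `N_a` is the number
#' of samples of class `a` and `K_present` counts the classes actually
#' observed. Weighting every sample by its class weight then gives every
#' present class the same total influence, and the weights average to 1 over
#' the dataset. Classes with no samples receive weight 0 with a warning, so
#' that label files covering only a subset of the classes still load.
#'
#' @param labels Data frame with a `true_class` column of 1-based class
#'   indices, or a bare integer vector.
#' @param n_classes Total number of classes K (>= 2).
#' @return A tibble with columns `class` (index), `n` (count), `weight`.
#' @examples
#' class_weights(c(1, 1, 1, 1, 2, 2), n_classes = 2) # weights 0.75, 1.5
#' @export
class_weights <- function(labels, n_classes) {
  truth <- label_vector(labels)
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2) {
    abort("`n_classes` must be a single integer >= 2.")
  }
  n_classes <- as.integer(n_classes)
  if (any(truth < 1L | truth > n_classes)) {
    abort("labels contain class indices outside 1..n_classes.")
  }
  counts <- tabulate(truth, nbins = n_classes)
  k_present <- sum(counts > 0)
  w <- ifelse(counts > 0, length(truth) / (k_present * counts), 0)
  if (any(counts == 0)) {
    warn(sprintf(
      "%d class(es) have zero count and receive weight 0: %s",
      sum(counts == 0), paste(which(counts == 0), collapse = ", ")
    ))
  }
  tibble::tibble(class = seq_len(n_classes), n = counts, weight = w)
}

label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (!"true_class" %in% names(labels)) {
      abort("label data frame needs a `true_class` column.")
    }
    labels <- labels$true_class
  }
  if (!is.numeric(labels) || length(labels) < 1L) {
    abort("labels must be a non-empty numeric vector of class indices.")
  }
  if (any(labels != as.integer(labels))) abort("labels must be integer class indices.")
  as.integer(labels)
}

#' Accuracy, macro-F1 and per-class precision/recall/F1
#'
#' `classification_metrics()` returns the one-row summary used throughout the
#' package: overall accuracy and macro-averaged F1.
#' `per_class_metrics()` returns the underlying per-class table.
#'
#' Macro-F1 is the unweighted mean of per-class F1 scores. Classes that occur
#' in neither the truth nor the predictions are excluded from the macro
#' average; a class whose precision and recall are both zero contributes
#' F1 = 0.
#'
#' @param truth Integer class indices (or a data frame with `true_class`).
#' @param estimate Integer predicted class indices, same length.
#' @param n_classes Number of classes; defaults to the largest index seen.
#' @return `classification_metrics()`: a one-row tibble with `accuracy`,
#'   `macro_f1`, `n_samples`, `n_classes_scored`. `per_class_metrics()`: a
#'   tibble with one row per class and columns `class`, `support`,
#'   `precision`, `recall`, `f1`, `scored`.
#' @examples
#' classification_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
classification_metrics <- function(truth, estimate, n_classes = NULL) {
  per <- per_class_metrics(truth, estimate, n_classes)
  truth <- label_vector(truth)
  scored <- per[per$scored, ]
  tibble::tibble(
    accuracy = mean(truth == as.integer(estimate)),
    macro_f1 = mean(scored$f1),
    n_samples = length(truth),
    n_classes_scored = nrow(scored)
  )
}

#' @rdname classification_metrics
#' @export
per_class_metrics <- function(truth, estimate, n_classes = NULL) {
  truth <- label_vector(truth)
  estimate <- label_vector(estimate)
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length.")
  }
  n_classes <- as.integer(n_classes %||% max(truth, estimate))
  tp <- tabulate(truth[truth == estimate], nbins = n_classes)
  support <- tabulate(truth, nbins = n_classes)
  predicted <- tabulate(estimate, nbins = n_classes)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  tibble::tibble(
    class = seq_len(n_classes),
    support = support,
    precision = precision,
    recall = recall,
    f1 = f1,
    scored = support > 0 | predicted > 0
  )
}
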