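#' Confidence cubes: stacked per-learner class-probability tables
#'
#' A confidence cube holds the softmax outputs of `n` learners over the same
#' `N` test samples and `K` classes: a 3-way array indexed by
#' (learner, sample, class) in which every (learner, sample) slice lies on the
#' probability simplex. It is the common input of the combination rules
#' ([ensemble_predict()]) and the agreement diagnostics
#' ([pairwise_similarity()], [agreement_patterns()]).
#'
#' `confidence_cube()` accepts either a 3-way numeric array
#' (learner x sample x class), a long data frame with columns
#' `learner`, `sample_id`, `class`, `confidence`, or a named list of wide
#' per-learner data frames (`sample_id` column plus one column per class,
#' as written by [write_cohort()]). Wide tables are aligned by `sample_id`,
#' never by row order, and learners with mismatched sample-id sets are an
#' error.
#'
#' Rows whose probabilities sum to 1 within `tolerance` are silently
#' renormalized (softmax outputs round-trip through text at 1e-8 or better);
#' larger deviations and negative entries are validation errors naming the
#' offending learner and sample.
#'
#' @param x Array, long data frame, or named list of wide data frames (see
#'   Details).
#' @param tolerance Maximum tolerated absolute deviation of a row sum from 1
#'   before the row is rejected rather than renormalized. Default `1e-6`.
#' @param learner_names,class_names Optional identifier vectors; taken from
#'   dimnames/columns when available.
#'
#' @return An object of class `confidence_cube`: the validated array with
#'   `learner_names` and `class_names` attached as dimnames.
#' @examples
#' cube <- confidence_cube(array(
#'   c(0.9, 0.4, 0.1, 0.6,   # class-1 confidences, learner x sample
#'     0.1, 0.6, 0.9, 0.4),  # class-2 confidences
#'   dim = c(2, 2, 2)
#' ))
#' n_learners(cube)
#' as_tibble(cube)
#' @export
confidence_cube <- function(x, tolerance = 1e-6,
                            learner_names = NULL, class_names = NULL) {
  if (is.data.frame(x)) {
    x <- long_to_cube_array(x)
  } else if (is.list(x) && !is.array(x)) {
    x <- wide_list_to_cube_array(x)
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("`x` must be a 3-way array (learner x sample x class), a long data frame, or a list of per-learner tables.")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    abort("`tolerance` must be a single non-negative number.")
  }
  storage.mode(x) <- "double"
  d <- dim(x)
  if (d[1] < 1L || d[2] < 1L) abort("need at least one learner and one sample.")
  if (d[3] < 2L) abort("need at least two classes.")
  if (anyNA(x)) abort("confidence values must not be missing.")

  learner_names <- learner_names %||% dimnames(x)[[1]] %||% paste0("learner_", seq_len(d[1]))
  class_names <- class_names %||% dimnames(x)[[3]] %||% paste0("class_", seq_len(d[3]))
  sample_ids <- dimnames(x)[[2]] %||% as.character(seq_len(d[2]))

  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative confidence for learner '%s', sample '%s'.",
      learner_names[bad[1]], sample_ids[bad[2]]
    ))
  }
  sums <- apply(x, c(1, 2), sum)
  dev <- abs(sums - 1)
  if (any(dev >= tolerance & dev > 0)) {
    bad <- which(dev >= tolerance, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf(
        "confidence row for learner '%s', sample '%s' sums to %.8f (deviation %.2e >= tolerance %.2e).",
        learner_names[bad[1, 1]], sample_ids[bad[1, 2]],
        sums[bad[1, 1], bad[1, 2]], dev[bad[1, 1], bad[1, 2]], tolerance
      ))
    }
  }
  # renormalize rows that are off by less than the tolerance
  if (any(dev > 0)) {
    for (i in seq_len(d[1])) x[i, , ] <- x[i, , ] / sums[i, ]
  }
  dimnames(x) <- list(learner_names, sample_ids, class_names)
  structure(x, class = c("confidence_cube", "array"))
}

long_to_cube_array <- function(df) {
  needed <- c("learner", "sample_id", "class", "confidence")
  if (!all(needed %in% names(df))) {
    abort("long-format input needs columns `learner`, `sample_id`, `class`, `confidence`.")
  }
  learners <- unique(df$learner)
  classes <- unique(df$class)
  ids <- unique(df$sample_id)
  arr <- array(NA_real_,
    dim = c(length(learners), length(ids), length(classes)),
    dimnames = list(as.character(learners), as.character(ids), as.character(classes))
  )
  arr[cbind(
    match(df$learner, learners),
    match(df$sample_id, ids),
    match(df$class, classes)
  )] <- df$confidence
  if (anyNA(arr)) abort("long-format input is not a complete learner x sample x class grid.")
  arr
}

wide_list_to_cube_array <- function(tables) {
  if (length(tables) < 1L) abort("need at least one per-learner table.")
  if (!all(vapply(tables, is.data.frame, logical(1)))) {
    abort("every element of the list must be a data frame.")
  }
  nm <- names(tables) %||% paste0("learner_", seq_along(tables))
  nm[nm == ""] <- paste0("learner_", which(nm == ""))
  ref <- tables[[1]]
  if (!"sample_id" %in% names(ref)) abort("per-learner tables need a `sample_id` column.")
  ids <- as.character(ref$sample_id)
  classes <- setdiff(names(ref), "sample_id")
  arr <- array(NA_real_,
    dim = c(length(tables), length(ids), length(classes)),
    dimnames = list(nm, ids, classes)
  )
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    if (!"sample_id" %in% names(tab)) abort(sprintf("table '%s' lacks a `sample_id` column.", nm[i]))
    if (!setequal(as.character(tab$sample_id), ids)) {
      abort(sprintf("sample ids of learner '%s' do not match those of '%s'.", nm[i], nm[1]))
    }
    if (anyDuplicated(tab$sample_id)) abort(sprintf("duplicated sample ids for learner '%s'.", nm[i]))
    if (!setequal(setdiff(names(tab), "sample_id"), classes)) {
      abort(sprintf("class columns of learner '%s' do not match those of '%s'.", nm[i], nm[1]))
    }
    m <- as.matrix(tab[match(ids, as.character(tab$sample_id)), classes, drop = FALSE])
    arr[i, , ] <- m
  }
  arr
}

#' @export
print.confidence_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<confidence_cube> %d learner%s x %d sample%s x %d classes\n",
    d[1], if (d[1] == 1) "" else "s", d[2], if (d[2] == 1) "" else "s", d[3]
  ))
  cat("learners:", paste(head(dimnames(x)[[1]], 5), collapse = ", "),
    if (d[1] > 5) "..." else "", "\n")
  cat("classes: ", paste(head(dimnames(x)[[3]], 8), collapse = ", "),
    if (d[3] > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname confidence_cube
#' @param cube A `confidence_cube`.
#' @export
n_learners <- function(cube) dim(cube)[1]

#' @rdname confidence_cube
#' @export
n_samples <- function(cube) dim(cube)[2]

#' @rdname confidence_cube
#' @export
n_classes <- function(cube) dim(cube)[3]

#' @rdname confidence_cube
#' @export
learner_names <- function(cube) dimnames(cube)[[1]]

#' @rdname confidence_cube
#' @export
class_names <- function(cube) dimnames(cube)[[3]]

#' @rdname confidence_cube
#' @export
sample_ids <- function(cube) dimnames(cube)[[2]]

#' Confidence matrix of one learner
#'
#' @param cube A [confidence_cube()].
#' @param learner Learner index or name.
#' @return Numeric matrix, samples x classes.
#' @export
learner_matrix <- function(cube, learner) {
  m <- cube[learner, , , drop = FALSE]
  dim(m) <- dim(cube)[2:3]
  dimnames(m) <- dimnames(cube)[2:3]
  m
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long tibble view of a confidence cube
#'
#' @param x A `confidence_cube`.
#' @param ... Unused.
#' @return A tibble with columns `learner`, `sample_id`, `class`,
#'   `confidence`.
#' @export
as_tibble.confidence_cube <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    learner = rep(dimnames(x)[[1]], times = d[2] * d[3]),
    sample_id = rep(rep(dimnames(x)[[2]], each = d[1]), times = d[3]),
    class = rep(dimnames(x)[[3]], each = d[1] * d[2]),
    confidence = as.vector(unclass(x))
  )
}
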