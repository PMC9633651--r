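#' Read per-learner confidence files and a label file
#'
#' Confidence files are delimited text (comma or tab, sniffed from the
#' header line) with a header `sample_id,<class_1>,...,<class_K>` and one
#' row per test sample. The labels file has columns `sample_id,true_class`,
#' where `true_class` is either a class name matching the confidence
#' headers or a 1-based class index. Samples are aligned by `sample_id`
#' across all files — never by row order — and mismatched id sets are an
#' error.
#'
#' @param paths Character vector of per-learner confidence file paths.
#' @param tolerance Row-sum tolerance passed to [confidence_cube()].
#' @param learner_names Learner identifiers; defaults to `names(paths)` or
#'   the file base names.
#' @return [read_confidence_files()]: a [confidence_cube()].
#'   [read_labels()]: a tibble `sample_id`, `true_class` (as read).
#' @export
read_confidence_files <- function(paths, tolerance = 1e-6,
                                  learner_names = NULL) {
  if (length(paths) < 1L) abort("need at least one confidence file.")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("confidence file(s) not found: ", paste(missing, collapse = ", ")))
  }
  learner_names <- learner_names %||% names(paths) %||%
    tools::file_path_sans_ext(basename(paths))
  tables <- lapply(paths, read_delim_sniffed)
  names(tables) <- learner_names
  confidence_cube(tables, tolerance = tolerance)
}

#' @rdname read_confidence_files
#' @param path Labels file path.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("labels file not found: ", path))
  tab <- read_delim_sniffed(path)
  if (!all(c("sample_id", "true_class") %in% names(tab))) {
    abort(sprintf("labels file '%s' needs columns `sample_id` and `true_class`.", path))
  }
  tab[, c("sample_id", "true_class")]
}

read_delim_sniffed <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Align a labels table to a cube's sample order
#'
#' Reorders the labels by the cube's sample ids and converts class names to
#' 1-based class indices.
#'
#' @param labels Tibble with `sample_id`, `true_class`.
#' @param cube A [confidence_cube()].
#' @return Integer vector of true class indices in cube sample order.
#' @export
align_labels <- function(labels, cube) {
  ids <- sample_ids(cube)
  if (!setequal(as.character(labels$sample_id), ids)) {
    abort("sample ids of the labels file do not match those of the confidence files.")
  }
  if (anyDuplicated(labels$sample_id)) abort("duplicated sample ids in labels file.")
  truth <- labels$true_class[match(ids, as.character(labels$sample_id))]
  if (is.character(truth) || is.factor(truth)) {
    idx <- match(as.character(truth), class_names(cube))
    if (anyNA(idx)) {
      abort(sprintf(
        "unknown class name(s) in labels: %s",
        paste(unique(truth[is.na(idx)]), collapse = ", ")
      ))
    }
    return(idx)
  }
  check_labels(truth, cube)
}

#' Write a cohort to per-learner confidence files plus a labels file
#'
#' Writes one CSV per learner in the format read by
#' [read_confidence_files()] and a `labels.csv`, rounding nothing (full
#' double precision via [readr::write_csv()]).
#'
#' @param cohort A `synthetic_cohort` (or a list with `cube` and `labels`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!all(c("cube", "labels") %in% names(cohort))) {
    abort("`cohort` must have elements `cube` and `labels`.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cube <- cohort$cube
  paths <- character(0)
  for (i in seq_len(n_learners(cube))) {
    m <- learner_matrix(cube, i)
    tab <- dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(m)),
      tibble::as_tibble(m)
    )
    p <- file.path(dir, paste0(learner_names(cube)[i], ".csv"))
    readr::write_csv(tab, p)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.csv")
  readr::write_csv(cohort$labels, lp)
  invisible(c(paths, lp))
}
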