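#' Run the full ensembling-and-diagnostics pipeline on confidence files
#'
#' Reads per-learner confidence files and a labels file, combines the
#' learners under the requested rules, computes all agreement diagnostics,
#' and writes to `out_dir`:
#'
#' * `combined_<rule>.csv` — the combined confidence matrix with a
#'   `predicted_class` column, per rule;
#' * `report.json` — a machine-readable report: tool version, input echo,
#'   per-learner and per-rule accuracy and macro-F1, similarity S with its
#'   standard error, unconditional and per-rule conditional pattern counts,
#'   top-1 profiles, the RWW rescue table (three-learner cohorts only), and
#'   any warnings raised (renormalization, veto fallbacks);
#' * `summary.txt` — a plain-text pattern table ([render_pattern_table()]).
#'
#' Outputs are deterministic: rerunning on the same inputs produces
#' byte-identical files (no timestamps are written).
#'
#' @param inputs Character vector of >= 2 per-learner confidence file paths.
#' @param labels Path to the labels file.
#' @param rules Combination rules to run (default both).
#' @param out_dir Output directory, created if needed. `NULL` skips writing.
#' @param normalize_geometric If `TRUE`, the *written* geometric combined
#'   matrix is renormalized row-wise for display; predictions and the JSON
#'   report always use the raw vectors.
#' @param n_bins Quantile bins for the rescue table.
#' @return The report, invisibly, as a nested list mirroring `report.json`.
#' @export
run_pipeline <- function(inputs, labels,
                         rules = c("arithmetic", "geometric"),
                         out_dir = NULL, normalize_geometric = FALSE,
                         n_bins = 5) {
  if (length(inputs) < 2L) abort("the pipeline needs at least two learners.")
  rules <- match.arg(rules, several.ok = TRUE)
  warnings_seen <- character(0)
  cube <- withCallingHandlers(
    read_confidence_files(inputs),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  truth <- align_labels(read_labels(labels), cube)

  ens <- list()
  for (rule in rules) {
    ens[[rule]] <- withCallingHandlers(
      ensemble_predict(cube, rule),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  report <- build_report(cube, truth, ens, n_bins = n_bins)
  report$inputs <- list(
    confidence_files = basename(inputs), labels_file = basename(labels),
    rules = rules
  )
  report$warnings <- warnings_seen

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rule in rules) {
      comb <- ens[[rule]]$combined
      if (rule == "geometric" && normalize_geometric) {
        rs <- rowSums(comb)
        comb[rs > 0, ] <- comb[rs > 0, ] / rs[rs > 0]
      }
      tab <- dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(comb)),
        tibble::as_tibble(comb),
        tibble::tibble(predicted_class = colnames(comb)[ens[[rule]]$prediction])
      )
      readr::write_csv(tab, file.path(out_dir, paste0("combined_", rule, ".csv")))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    writeLines(
      render_pattern_table(c(
        list(unconditional = report$patterns$unconditional),
        setNames(
          lapply(rules, function(r) report$patterns$conditional[[r]]),
          paste0("correct_", rules)
        )
      )),
      file.path(out_dir, "summary.txt")
    )
  }
  invisible(report)
}

build_report <- function(cube, truth, ens, n_bins = 5) {
  pattern_to_list <- function(tab) as.list(setNames(tab$count, tab$pattern))
  per_learner <- purrr::map_dfr(seq_len(n_learners(cube)), function(i) {
    pred <- predicted_class(learner_matrix(cube, i))
    dplyr::bind_cols(
      tibble::tibble(learner = learner_names(cube)[i]),
      classification_metrics(truth, pred, n_classes = n_classes(cube))
    )
  })
  sim <- pairwise_similarity(cube)
  report <- list(
    tool = list(name = "softvote", version = as.character(utils::packageVersion("softvote"))),
    shape = list(
      n_learners = n_learners(cube), n_samples = n_samples(cube),
      n_classes = n_classes(cube)
    ),
    similarity = list(
      mean = sim$similarity_mean, se = sim$similarity_se
    ),
    learners = per_learner,
    ensembles = purrr::map(ens, function(e) {
      m <- classification_metrics(truth, e$prediction, n_classes = n_classes(cube))
      list(
        rule = e$rule, accuracy = m$accuracy, macro_f1 = m$macro_f1,
        n_veto_fallback = sum(e$fallback)
      )
    }),
    patterns = list(
      unconditional = agreement_patterns(cube, truth),
      conditional = purrr::map(ens, function(e) {
        conditional_patterns(cube, truth, e$rule)
      })
    ),
    top1 = top1_profile(cube)
  )
  if (n_learners(cube) == 3L && n_classes(cube) >= 3L) {
    report$rescue <- purrr::map(ens, function(e) {
      rt <- rww_rescue(cube, truth, e$rule, n_bins = n_bins)
      list(rule = rt$rule, n_rww = rt$n_rww, bins = rt$bins)
    })
  }
  report
}

#' Render pattern tables as an aligned text table
#'
#' Lays out one row per pattern table (e.g. the unconditional histogram and
#' the per-rule conditional ones) with one column per agreement pattern,
#' mirroring a bar-plot-with-printed-counts figure in text. When exactly two
#' tables are given, a `ratio` row (second/first, `NA` on zero denominators)
#' is appended.
#'
#' @param tables Named list of pattern tibbles (as returned by
#'   [agreement_patterns()] / [conditional_patterns()]), all with the same
#'   patterns.
#' @return Character vector of text lines.
#' @export
render_pattern_table <- function(tables) {
  if (length(tables) < 1L) abort("need at least one pattern table.")
  pats <- tables[[1]]$pattern
  for (tab in tables) {
    if (!identical(tab$pattern, pats)) {
      abort("pattern tables have mismatched pattern labels.")
    }
  }
  rows <- names(tables) %||% paste0("table_", seq_along(tables))
  cells <- lapply(tables, function(tab) format(tab$count))
  body <- do.call(rbind, cells)
  if (length(tables) == 2L) {
    a <- tables[[1]]$count
    b <- tables[[2]]$count
    ratio <- ifelse(a == 0, NA_real_, b / a)
    body <- rbind(body, format(round(ratio, 3)))
    rows <- c(rows, "ratio")
  }
  widths <- pmax(nchar(pats), apply(nchar(body), 2, max))
  name_w <- max(nchar(c("", rows)))
  pad <- function(x, w) formatC(x, width = w)
  header <- paste(c(pad("", name_w), mapply(pad, pats, widths)), collapse = "  ")
  lines <- vapply(seq_along(rows), function(r) {
    paste(c(pad(rows[r], name_w), mapply(pad, body[r, ], widths)), collapse = "  ")
  }, character(1))
  c(header, lines)
}
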