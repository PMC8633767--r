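#' Read and write the package's delimited-text tables
#'
#' Trial logs, model traces, learning curves, and session summaries are
#' plain comma-separated text with a header row, one record per line,
#' so they interoperate with any downstream tooling (e.g. mixed-model
#' fitting outside this package). `write_ratcat_table()` writes any of
#' these tibbles; `read_trial_log()` and `read_learning_curves()` read
#' them back with the column types the pipeline expects.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_ratcat_table()` returns `x` invisibly; readers return
#'   a tibble.
#' @export
write_ratcat_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(x)
}

#' @rdname write_ratcat_table
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "session", "trial", "is_correction",
            "x_norm", "y_norm", "category", "response", "correct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("trial log missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$category <- factor(df$category, levels = c("A", "B"))
  tibble::as_tibble(df)
}

#' @rdname write_ratcat_table
#' @export
read_learning_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "task_class", "session", "accuracy", "n_subjects",
            "trials_per_session")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("curves file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}
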