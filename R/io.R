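#' Read / write tidy concentration profiles
#'
#' The interchange format is a plain CSV with columns `subject_id`,
#' `sequence`, `period`, `formulation`, `time_min`, `conc` — the same
#' layout [simulate_crossover()] produces — so stored or user-supplied
#' datasets can be fed straight into [nca_table()].
#'
#' @param dataset Data frame of profiles.
#' @param path File path.
#' @return `read_profiles()` returns the data frame; `write_profiles()`
#'   returns `path` invisibly.
#' @export
write_profiles <- function(dataset, path) {
  need <- c("subject_id", "sequence", "period", "formulation",
            "time_min", "conc")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(format_numeric(dataset[, need]), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sequence", "period", "formulation",
            "time_min", "conc")
  miss <- setdiff(need, names(ds))
  if (length(miss))
    stop("profile CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ds
}

# all floats at 10 significant digits for stable, diffable CSVs
format_numeric <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  df
}

#' Write a tabular result to CSV
#'
#' Works for [nca_table()], [run_trial()], [run_sweep()] and
#' [scenario_matrix()] outputs; floats are written with 10 significant
#' digits.
#'
#' @param x Data frame result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(format_numeric(as.data.frame(x)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

utils::globalVariables(c("ratio", "mean_gmr", "pct_acceptance", "metric",
                         "PC1", "PC2"))

#' Quick plots of sweep and PCA results
#'
#' Minimal diagnostic figures (requires \pkg{ggplot2}): `plot_sweep()`
#' draws the mean GMR or percent-acceptance curves per metric against the
#' KaT/KaR ratio; `plot_biplot()` draws the loading vectors of the first
#' two components.
#'
#' @param sweep A [run_sweep()] result.
#' @param what `"gmr"` or `"acceptance"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, what = c("gmr", "acceptance")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  what <- match.arg(what)
  df <- as.data.frame(sweep)
  if (what == "gmr") {
    ggplot2::ggplot(df, ggplot2::aes(ratio, mean_gmr,
                                     colour = metric)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "KaT/KaR", y = "mean GMR")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(ratio, pct_acceptance,
                                     colour = metric)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "KaT/KaR", y = "% BE acceptance")
  }
}

#' @rdname plot_sweep
#' @param fit A [pca_metrics()] result.
#' @export
plot_biplot <- function(fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  L <- as.data.frame(fit$loadings[, 1:2])
  L$metric <- rownames(fit$loadings)
  ggplot2::ggplot(L) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = PC1,
                                       yend = PC2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(ggplot2::aes(PC1, PC2,
                                    label = metric),
                       hjust = -0.1) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * fit$explained[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * fit$explained[2]))
}
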