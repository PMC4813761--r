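#' Load the transcribed published behavioral summary table
#'
#' The package ships a transcription of the published per-session behavioral
#' table (30 sessions across 8 analysed subjects, 4 task variants) as a
#' plain-text fixture: trial counts, change and fail fractions, median RTs
#' and SOAs, the two SSRT estimates and the inhibition-function deviance,
#' plus the rejected flag marking the sessions the original analysis
#' excluded. Missing cells (no RT on successful stop trials; no
#' psychometric fit for sessions discarded on earlier grounds) are `NA`.
#'
#' @param path Path to the TSV; defaults to the installed fixture.
#' @return A data frame, one row per subject/condition session.
#' @export
load_table2 <- function(path = system.file("extdata", "table2.tsv",
                                           package = "stopmeg")) {
  if (!nzchar(path) || !file.exists(path)) stop_invalid("table file not found")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", na.strings = "",
                      stringsAsFactors = FALSE),
    error = function(e) stop_invalid("malformed table: %s", conditionMessage(e))
  )
  need <- c("subject", "condition", "presented", "unclassified", "classified",
            "change_fraction", "fail_fraction", "go_rt", "fail_rt",
            "success_rt", "fail_soa", "success_soa", "ssrt_av", "ssrt_mcmc",
            "deviance", "rejected")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_invalid("table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  bad <- which(df$classified + df$unclassified != df$presented)
  if (length(bad)) {
    stop_invalid("row %d: classified + unclassified != presented", bad[1])
  }
  df$rejected <- as.logical(df$rejected)
  df
}

#' Summary statistics over the retained sessions
#'
#' Mean and SD of every numeric column over the rows not flagged as
#' rejected, plus the mean difference between the two SSRT estimates.
#'
#' @param rows A data frame from [load_table2()].
#' @return A list with `n_retained`, `mean` and `sd` (named numeric
#'   vectors), and `mean_ssrt_diff` (mean of `ssrt_av - ssrt_mcmc`).
#' @export
summarize_retained <- function(rows) {
  kept <- rows[!rows$rejected, , drop = FALSE]
  if (nrow(kept) == 0L) stop_invalid("no retained sessions")
  num <- kept[vapply(kept, is.numeric, logical(1))]
  list(
    n_retained = nrow(kept),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(x) stats::sd(x, na.rm = TRUE), numeric(1)),
    mean_ssrt_diff = mean(kept$ssrt_av - kept$ssrt_mcmc, na.rm = TRUE)
  )
}
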