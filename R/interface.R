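# High-level entry points tying the procedures together: run a set of
# methods on one dataset, serialize results, and back the command-line
# script shipped under inst/cli/.

#' Run multiple contrast test procedures on one dataset
#'
#' Applies the requested procedures to a grouped survival dataset with a
#' common contrast set and weight set.
#'
#' @param data a [survival_dataset()] (at least two groups).
#' @param methods character subset of `"adjusted_logrank"`,
#'   `"adjusted_mdir"`, `"multiweightedlr"`, `"multicasanova_rademacher"`,
#'   `"multicasanova_poisson"`.
#' @param contrasts `"tukey"`, `"dunnett"`, or a [make_contrasts()] object.
#' @param weights weight specification for [parse_weights()] (the adjusted
#'   log-rank uses only the first weight).
#' @param alpha global significance level.
#' @param B resampling iterations for permutation/bootstrap methods.
#' @param seed master seed.
#' @return Named list of `mctp_result` objects.
#' @examples
#' d <- sample_scenario(scenario("Prop", n = 30), seed = 7)
#' mctp_test(d, methods = "adjusted_logrank")
#' @export
mctp_test <- function(data, methods = c("adjusted_logrank", "adjusted_mdir",
                                        "multiweightedlr",
                                        "multicasanova_rademacher"),
                      contrasts = "tukey", weights = c("lr", "crossing"),
                      alpha = 0.05, B = 1000L, seed = 1L) {
  stopifnot(inherits(data, "survival_dataset"))
  if (data$k < 2L)
    stop("at least two groups are required", call. = FALSE)
  methods <- match.arg(methods, mc_methods, several.ok = TRUE)
  if (is.character(contrasts))
    contrasts <- make_contrasts(contrasts, data$k)
  ws <- parse_weights(weights)
  out <- lapply(seq_along(methods), function(mi) {
    m <- methods[mi]
    mseed <- derive_seed(seed, mi)
    switch(m,
      adjusted_logrank = adjusted_logrank_test(data, contrasts,
                                               w = ws[[1L]], alpha = alpha),
      adjusted_mdir = adjusted_mdir_test(data, contrasts, ws, B = B,
                                         alpha = alpha, seed = mseed),
      multiweightedlr = multiweightedlr_test(data, contrasts, ws,
                                             alpha = alpha),
      multicasanova_rademacher = multicasanova_test(
        data, contrasts, ws, "rademacher", B = B, alpha = alpha,
        seed = mseed),
      multicasanova_poisson = multicasanova_test(
        data, contrasts, ws, "poisson", B = B, alpha = alpha, seed = mseed))
  })
  stats::setNames(out, methods)
}

#' Serialize results to a tidy table and a summary document
#'
#' Writes one delimited table with a row per method and contrast (full
#' precision) and, optionally, a human-readable text summary (4 significant
#' digits).
#'
#' @param results named list of `mctp_result`s (as from [mctp_test()]).
#' @param table_path output path for the delimited table.
#' @param summary_path optional path for the text summary.
#' @param delim field delimiter.
#' @return `table_path`, invisibly.
#' @export
write_mctp_results <- function(results, table_path, summary_path = NULL,
                               delim = ",") {
  rows <- do.call(rbind, lapply(names(results), function(m) {
    tab <- results[[m]]$table
    pcol <- if ("p_value" %in% names(tab)) tab$p_value else tab$p_adj
    data.frame(method = m, contrast = tab$contrast,
               statistic = tab$statistic, p = pcol, reject = tab$reject,
               global_reject = results[[m]]$global_reject)
  }))
  utils::write.table(rows, table_path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(summary_path)) {
    con <- file(summary_path, "w")
    on.exit(close(con))
    for (m in names(results)) {
      sink(con)
      print(results[[m]])
      cat("\n")
      sink()
    }
  }
  invisible(table_path)
}
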