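# Bonferroni-adjusted reference procedures: adjusted (weighted) log-rank and
# adjusted mdir, both with local and global decisions, plus the shared result
# container used by all four procedures in the package.

#' Bonferroni-adjusted significance level
#'
#' @param alpha global significance level in (0, 1).
#' @param q number of comparisons (>= 1).
#' @return `alpha / q`.
#' @examples
#' bonferroni_level(0.05, 21)  # 21 Tukey tests for k = 7 groups
#' @export
bonferroni_level <- function(alpha, q) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q < 1)
    stop("'q' must be a positive integer", call. = FALSE)
  alpha / q
}

# Shared constructor for the result container.
mctp_result <- function(method, data, contrasts, table, global_reject, alpha,
                        adjustment, B = NA_integer_, seed = NA_integer_) {
  structure(
    list(method = method, contrasts = contrasts, table = table,
         global_reject = global_reject, alpha = alpha,
         adjustment = adjustment, B = B, seed = seed,
         labels = data$labels),
    class = "mctp_result")
}

pair_names <- function(data, pairs) {
  paste(data$labels[pairs[, 1L]], data$labels[pairs[, 2L]], sep = " vs ")
}

#' @export
print.mctp_result <- function(x, digits = 4, ...) {
  cat(x$method, "\n")
  cat(sprintf("Global decision: %s at alpha = %g\n",
              if (x$global_reject) "reject" else "do not reject", x$alpha))
  for (nm in names(x$adjustment))
    cat(sprintf("  %s: %s\n", nm, format(signif(x$adjustment[[nm]], digits))))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tidy per-contrast result table
#'
#' @param x an `mctp_result`.
#' @param ... unused.
#' @return the per-contrast `data.frame` (one row per contrast).
#' @export
as.data.frame.mctp_result <- function(x, ...) x$table

#' Bonferroni-adjusted weighted log-rank procedure
#'
#' For every pairwise contrast, computes the weighted log-rank statistic and
#' its variance, forms the chi-square statistic `T^2 / sigma`, and derives the
#' local p-value from the upper tail of the chi-square distribution with one
#' degree of freedom.  A local hypothesis is rejected when its p-value falls
#' below `alpha / q`; the global hypothesis is rejected when the smallest
#' local p-value does.  The default weight is the classical log-rank weight.
#'
#' @param data a [survival_dataset()].
#' @param contrasts a [make_contrasts()] set (pairwise rows only).
#' @param w a single [weight_function()].
#' @param alpha global significance level.
#' @return An `mctp_result`.
#' @export
adjusted_logrank_test <- function(data, contrasts, w = fleming_harrington(0, 0),
                                  alpha = 0.05) {
  assert_pairwise(contrasts)
  a_bonf <- bonferroni_level(alpha, contrasts$q)
  rows <- lapply(seq_len(contrasts$q), function(i) {
    v <- wlr_vector(data, contrasts$pairs[i, ], list(w))
    chisq <- if (v$sigma[1L] > 0) v$stats[1L]^2 / v$sigma[1L] else 0
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    c(stat = v$stats[1L], chisq = chisq, p = p)
  })
  rows <- do.call(rbind, rows)
  tab <- data.frame(contrast = pair_names(data, contrasts$pairs),
                    statistic = rows[, "chisq"], p_value = rows[, "p"],
                    reject = rows[, "p"] < a_bonf)
  mctp_result("Bonferroni-adjusted weighted log-rank test", data, contrasts,
              tab, global_reject = any(tab$reject), alpha = alpha,
              adjustment = list(alpha_bonferroni = a_bonf))
}

#' Bonferroni-adjusted mdir permutation procedure
#'
#' For every pairwise contrast, combines several weighted log-rank statistics
#' into the studentized quadratic form of [mdir_statistic()] and calibrates it
#' by permutation within the pair ([mdir_permutation_pvalue()]); asymptotic
#' chi-square calibration is available for reference but the permutation path
#' is the default.  Local and global decisions use the Bonferroni level
#' `alpha / q`.  When `1/(B+1) >= alpha/q` no permutation p-value can fall
#' below the adjusted level, so a warning is emitted (the descriptive
#' p-values are still returned).
#'
#' @param data a [survival_dataset()].
#' @param contrasts a [make_contrasts()] set (pairwise rows only).
#' @param ws list of linearly independent weight functions.
#' @param B permutations per contrast.
#' @param alpha global significance level.
#' @param seed master seed; each contrast draws from a deterministically
#'   derived sub-seed so runs are reproducible and order-independent.
#' @param calibrate `"permutation"` (default) or `"chisq"` for the asymptotic
#'   chi-square reference with `m` degrees of freedom.
#' @return An `mctp_result`.
#' @export
adjusted_mdir_test <- function(data, contrasts, ws = default_weights(),
                               B = 1000L, alpha = 0.05, seed = NULL,
                               calibrate = c("permutation", "chisq")) {
  assert_pairwise(contrasts)
  calibrate <- match.arg(calibrate)
  a_bonf <- bonferroni_level(alpha, contrasts$q)
  if (calibrate == "permutation" && 1 / (B + 1) >= a_bonf)
    warning(sprintf(paste0("smallest achievable permutation p-value 1/(B+1) ",
                           "= %.4g is not below the Bonferroni level %.4g; ",
                           "no local rejection is possible"),
                    1 / (B + 1), a_bonf), call. = FALSE)
  rows <- lapply(seq_len(contrasts$q), function(i) {
    pair <- contrasts$pairs[i, ]
    if (calibrate == "permutation") {
      pr <- mdir_permutation_pvalue(data, pair, ws, B = B,
                                    seed = derive_seed(seed, i))
      c(z = pr$z_obs, p = pr$p)
    } else {
      z <- mdir_statistic(wlr_vector(data, pair, ws))
      c(z = z, p = stats::pchisq(z, df = length(ws), lower.tail = FALSE))
    }
  })
  rows <- do.call(rbind, rows)
  tab <- data.frame(contrast = pair_names(data, contrasts$pairs),
                    statistic = rows[, "z"], p_value = rows[, "p"],
                    reject = rows[, "p"] < a_bonf)
  mctp_result(sprintf("Bonferroni-adjusted mdir test (%s calibration)",
                      calibrate),
              data, contrasts, tab, global_reject = any(tab$reject),
              alpha = alpha,
              adjustment = list(alpha_bonferroni = a_bonf),
              B = if (calibrate == "permutation") B else NA_integer_,
              seed = if (is.null(seed)) NA_integer_ else seed)
}
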