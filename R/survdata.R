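#' Construct a grouped right-censored survival dataset
#'
#' The universal input object of the package: one record per subject with an
#' observed time `X = min(T, C)`, an event indicator `status` (1 = event,
#' 0 = right-censored) and a group label.  Group labels of any atomic type are
#' accepted; internally they are mapped to integers `1..k` in order of first
#' appearance and reported back in the original labels.
#'
#' @param times numeric vector of positive observed times.
#' @param status integer/logical vector of event indicators (1 event,
#'   0 censored).
#' @param group vector of group labels (at least one record per group).
#' @return An object of class `survival_dataset`: a list with components
#'   `times`, `status`, `group` (integer codes `1..k`), `labels` (original
#'   labels in code order), `n_j` (per-group sizes) and `k`.
#' @examples
#' d <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 0, 1), c("a", "a", "b", "b"))
#' d$n_j
#' @export
survival_dataset <- function(times, status, group) {
  times <- as.numeric(times)
  status <- as.integer(status)
  if (length(times) == 0L)
    stop("empty dataset: no records", call. = FALSE)
  if (length(status) != length(times) || length(group) != length(times))
    stop("'times', 'status' and 'group' must have equal length", call. = FALSE)
  if (anyNA(times) || anyNA(status) || anyNA(group))
    stop("missing values are not allowed", call. = FALSE)
  if (any(times <= 0))
    stop("all observed times must be strictly positive", call. = FALSE)
  if (!all(status %in% c(0L, 1L)))
    stop("'status' must contain only 0 (censored) and 1 (event)", call. = FALSE)
  labels <- unique(group)
  code <- match(group, labels)
  structure(
    list(times = times, status = status, group = code,
         labels = labels, n_j = tabulate(code, length(labels)),
         k = length(labels)),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("Right-censored survival dataset:", length(x$times), "records in",
      x$k, "groups\n")
  tab <- data.frame(group = as.character(x$labels), n = x$n_j,
                    events = vapply(seq_len(x$k), function(j)
                      sum(x$status[x$group == j]), integer(1)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Read a survival dataset from delimited text
#'
#' Expects a header with columns `time`, `status` and `group` (any order,
#' extra columns ignored).  `status` is coded 1 = event, 0 = censored unless
#' `flip_status = TRUE`.
#'
#' @param path path to a delimited text file.
#' @param delim field delimiter (default comma).
#' @param flip_status set `TRUE` when the file codes 0 = event, 1 = censored.
#' @return A [survival_dataset()].
#' @export
read_survival_data <- function(path, delim = ",", flip_status = FALSE) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  need <- c("time", "status", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!(df$status %in% c(0, 1)) | !is.finite(df$time) | df$time <= 0)
  if (length(bad))
    stop("malformed rows (non-positive time or status not in {0,1}) at line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  status <- if (flip_status) 1L - as.integer(df$status) else as.integer(df$status)
  survival_dataset(df$time, status, df$group)
}

#' Counting processes of a (sub)sample
#'
#' Builds, on the sorted unique observed times of the selected subsample, the
#' group-wise event increments `dN_j(t)` and at-risk counts
#' `Y_j(t) = #\{i : X_ji >= t\}`.  At a tied time, events are counted before
#' censored records leave the risk set (both are still at risk at `t`), the
#' standard convention for the Nelson-Aalen and Kaplan-Meier estimators.
#'
#' @param data a [survival_dataset()].
#' @param groups group labels (original labels or integer codes) to include;
#'   default all groups.
#' @return An object of class `counting_processes`: list with `grid` (sorted
#'   unique times), matrices `Y` and `dN` (rows = grid, one column per selected
#'   group), `Y_total`, `dN_total`, `groups` (integer codes) and `n_j`.
#' @export
counting_processes <- function(data, groups = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  codes <- resolve_groups(data, groups)
  keep <- data$group %in% codes
  times <- data$times[keep]
  status <- data$status[keep]
  grp <- match(data$group[keep], codes)
  grid <- sort(unique(times))
  idx <- match(times, grid)
  ng <- length(grid)
  k <- length(codes)
  Y <- matrix(0L, ng, k)
  dN <- matrix(0L, ng, k)
  for (j in seq_len(k)) {
    sel <- grp == j
    cnt <- tabulate(idx[sel], ng)
    Y[, j] <- rev(cumsum(rev(cnt)))            # at risk just before t
    dN[, j] <- tabulate(idx[sel & status == 1L], ng)
  }
  structure(
    list(grid = grid, Y = Y, dN = dN,
         Y_total = rowSums(Y), dN_total = rowSums(dN),
         groups = codes, n_j = data$n_j[codes]),
    class = "counting_processes")
}

resolve_groups <- function(data, groups) {
  if (is.null(groups)) return(seq_len(data$k))
  codes <- match(groups, data$labels)
  if (anyNA(codes)) {
    # allow integer codes directly
    if (is.numeric(groups) && all(groups %in% seq_len(data$k)))
      codes <- as.integer(groups)
    else
      stop("unknown group label(s): ",
           paste(groups[is.na(codes)], collapse = ", "), call. = FALSE)
  }
  if (length(codes) == 0L) stop("empty group selection", call. = FALSE)
  codes
}

#' Right-continuous step-function estimate
#'
#' Container for step estimators over a grid of event times (Nelson-Aalen,
#' Kaplan-Meier, pooled CDF).  `init` is the value before the first grid
#' point (0 for cumulative hazards and CDFs, 1 for survival functions).
#'
#' @param grid sorted numeric grid.
#' @param values estimate at each grid point (right-continuous convention).
#' @param init value on `[0, grid[1])`.
#' @param kind descriptive label.
#' @return Object of class `step_estimate`.
#' @export
step_estimate <- function(grid, values, init, kind = "step") {
  stopifnot(length(grid) == length(values), !is.unsorted(grid))
  structure(list(grid = grid, values = values, init = init, kind = kind),
            class = "step_estimate")
}

#' Evaluate a step estimate
#'
#' `step_value()` returns the right-continuous value at `t`;
#' `step_left()` the left limit, i.e. the value at the largest grid point
#' strictly below `t` (`init` before the first grid point).
#'
#' @param est a [step_estimate()].
#' @param t numeric vector of evaluation times.
#' @return numeric vector.
#' @export
step_value <- function(est, t) {
  pos <- findInterval(t, est$grid)
  c(est$init, est$values)[pos + 1L]
}

#' @rdname step_value
#' @export
step_left <- function(est, t) {
  pos <- findInterval(t, est$grid, left.open = TRUE)
  c(est$init, est$values)[pos + 1L]
}

#' @export
print.step_estimate <- function(x, ...) {
  cat("Step estimate (", x$kind, ") on ", length(x$grid), " grid points\n",
      sep = "")
  print(utils::head(data.frame(time = x$grid, value = x$values), 10L))
  invisible(x)
}

#' Nelson-Aalen estimator of the cumulative hazard
#'
#' `A_hat_j(t) = sum_{s <= t, Y_j(s) > 0} dN_j(s) / Y_j(s)`; an empty risk
#' set contributes 0.
#'
#' @param cp a [counting_processes()] object.
#' @param group the group (position within `cp$groups`, or original code if
#'   `cp` spans all groups); default 1 for single-group processes.
#' @return A non-decreasing [step_estimate()] starting at 0.
#' @export
nelson_aalen <- function(cp, group = 1L) {
  stopifnot(inherits(cp, "counting_processes"))
  j <- if (group %in% cp$groups) match(group, cp$groups) else as.integer(group)
  if (is.na(j) || j < 1L || j > ncol(cp$Y))
    stop("group not present in counting processes", call. = FALSE)
  inc <- ifelse(cp$Y[, j] > 0, cp$dN[, j] / cp$Y[, j], 0)
  step_estimate(cp$grid, cumsum(inc), init = 0, kind = "nelson-aalen")
}

#' Kaplan-Meier estimator of the pooled survival function
#'
#' Product-limit estimator over all groups contained in `cp`:
#' `S_hat(t) = prod_{s <= t} (1 - dN(s)/Y(s))`.  Use `one_minus = TRUE` for
#' the CDF `F_hat = 1 - S_hat` (whose left limit feeds the weight functions).
#'
#' @param cp a [counting_processes()] object (pooled over its groups).
#' @param one_minus return the CDF instead of the survival function.
#' @return A [step_estimate()]; non-increasing in `[0, 1]` for the survival
#'   function.
#' @export
kaplan_meier <- function(cp, one_minus = FALSE) {
  stopifnot(inherits(cp, "counting_processes"))
  fac <- ifelse(cp$Y_total > 0, 1 - cp$dN_total / cp$Y_total, 1)
  S <- cumprod(fac)
  if (one_minus)
    step_estimate(cp$grid, 1 - S, init = 0, kind = "kaplan-meier CDF")
  else
    step_estimate(cp$grid, S, init = 1, kind = "kaplan-meier")
}

#' Write a step estimate as a delimited table
#'
#' @param est a [step_estimate()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_step_estimate <- function(est, path, delim = ",") {
  utils::write.table(data.frame(time = est$grid, value = est$values),
                     path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
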