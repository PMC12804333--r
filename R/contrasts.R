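#' Pairwise contrast matrices
#'
#' Builds the contrast matrix `H` (q x k, rows summing to zero) together with
#' the ordered index set `I` of `(j1, j2)` pairs.  Dunnett-type contrasts
#' compare group 1 to every other group (`q = k - 1`); Tukey-type contrasts
#' enumerate all pairs in lexicographic order (`q = k (k - 1) / 2`).  Each row
#' carries `-1` at position `j1` and `+1` at position `j2`.
#'
#' @param kind `"dunnett"`, `"tukey"`, or `"custom"` with `pairs` supplied.
#' @param k number of groups (>= 2).
#' @param pairs for `kind = "custom"`: a 2-column matrix or list of `(j1, j2)`
#'   index pairs.
#' @return Object of class `contrast_set`: list with `H`, `pairs` (q x 2
#'   integer matrix), `q`, `k`, `kind`.
#' @examples
#' make_contrasts("tukey", 4)$q    # 6 pairwise comparisons
#' make_contrasts("dunnett", 4)$q  # 3 comparisons against group 1
#' @export
make_contrasts <- function(kind = c("tukey", "dunnett", "custom"), k,
                           pairs = NULL) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (is.na(k) || k < 2L)
    stop("contrasts require at least k = 2 groups", call. = FALSE)
  if (kind == "dunnett") {
    pairs <- cbind(1L, 2:k)
  } else if (kind == "tukey") {
    pairs <- do.call(rbind, lapply(seq_len(k - 1L), function(j1)
      cbind(j1, seq.int(j1 + 1L, k))))
  } else {
    if (is.null(pairs)) stop("custom contrasts need 'pairs'", call. = FALSE)
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (anyNA(pairs) || any(pairs < 1L) || any(pairs > k) ||
        any(pairs[, 1L] == pairs[, 2L]))
      stop("invalid contrast pairs", call. = FALSE)
  }
  q <- nrow(pairs)
  H <- matrix(0, q, k)
  H[cbind(seq_len(q), pairs[, 1L])] <- -1
  H[cbind(seq_len(q), pairs[, 2L])] <- 1
  structure(list(H = H, pairs = pairs, q = q, k = k, kind = kind),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("%s-type contrast set: %d pairwise comparisons of %d groups\n",
              x$kind, x$q, x$k))
  invisible(x)
}

# Checks that every row of H is a +/-1 pairwise contrast; the test statistics
# of this release support only those.
assert_pairwise <- function(contrasts) {
  stopifnot(inherits(contrasts, "contrast_set"))
  H <- contrasts$H
  ok <- apply(H, 1L, function(r)
    sum(r == 1) == 1 && sum(r == -1) == 1 && sum(r != 0) == 2)
  if (!all(ok))
    stop("only pairwise (+1/-1) contrast rows are supported by the test ",
         "procedures", call. = FALSE)
  invisible(contrasts)
}

#' Weight functions for weighted log-rank statistics
#'
#' A weight function maps the left limit of the pooled Kaplan-Meier CDF,
#' a value in `[0, 1]`, to a real weight.  `fleming_harrington(r, g)` gives
#' the classical family `w(x) = x^r (1 - x)^g` (`r = g = 0` is the log-rank
#' weight); `crossing_weight()` gives `w(x) = 1 - 2x`, which changes sign at
#' the pooled median and targets crossing-hazard alternatives.  Both built-ins
#' are continuous and of bounded variation on `[0, 1]`; custom weights passed
#' to the procedures should satisfy the same (the caller's responsibility).
#'
#' @param r,g non-negative exponents.
#' @return Object of class `weight_function`: the evaluator with a `label`
#'   attribute.
#' @examples
#' fleming_harrington(0, 0)(0.3)  # log-rank weight, constant 1
#' crossing_weight()(0.5)         # sign change at the median
#' @export
fleming_harrington <- function(r, g) {
  if (r < 0 || g < 0)
    stop("Fleming-Harrington exponents must be non-negative", call. = FALSE)
  force(r); force(g)
  f <- function(x) x^r * (1 - x)^g
  weight_function(f, if (r == 0 && g == 0) "log-rank"
                  else sprintf("FH(%g,%g)", r, g))
}

#' @rdname fleming_harrington
#' @export
crossing_weight <- function() {
  weight_function(function(x) 1 - 2 * x, "crossing")
}

#' @rdname fleming_harrington
#' @param f an evaluator on `[0, 1]`.
#' @param label display label.
#' @export
weight_function <- function(f, label = "custom") {
  stopifnot(is.function(f))
  structure(f, label = label, class = c("weight_function", "function"))
}

#' @export
print.weight_function <- function(x, ...) {
  cat("Weight function:", attr(x, "label"), "\n")
  invisible(x)
}

#' Default weight set
#'
#' The default combination used by all multi-weight procedures: the log-rank
#' weight `w == 1` together with the crossing weight `1 - 2x`, a pairing that
#' is robust against both stochastic-ordering and crossing-hazard
#' alternatives.
#'
#' @return list of two [weight_function()]s.
#' @export
default_weights <- function() {
  list(fleming_harrington(0, 0), crossing_weight())
}

#' Parse a weight specification
#'
#' Accepts character shorthands: `"lr"` (log-rank), `"fh:r,g"`
#' (Fleming-Harrington with exponents r, g) and `"crossing"`, or
#' ready-made [weight_function()] objects.
#'
#' @param spec character vector of shorthands and/or a list of weight
#'   functions.
#' @return list of [weight_function()]s.
#' @examples
#' parse_weights(c("lr", "fh:1,1", "crossing"))
#' @export
parse_weights <- function(spec) {
  if (inherits(spec, "weight_function")) return(list(spec))
  lapply(spec, function(s) {
    if (inherits(s, "weight_function")) return(s)
    if (!is.character(s)) stop("unknown weight specification", call. = FALSE)
    if (s == "lr") return(fleming_harrington(0, 0))
    if (s == "crossing") return(crossing_weight())
    if (grepl("^fh:", s)) {
      rg <- as.numeric(strsplit(sub("^fh:", "", s), ",")[[1L]])
      if (length(rg) != 2L || anyNA(rg))
        stop("Fleming-Harrington spec must be 'fh:r,g'", call. = FALSE)
      return(fleming_harrington(rg[1L], rg[2L]))
    }
    stop("unknown weight specification: ", s, call. = FALSE)
  })
}

#' Check linear independence of a weight set
#'
#' The multi-directional statistics require linearly independent weights;
#' this evaluates each weight on a grid in `[0, 1]` and checks that the
#' evaluation matrix has full row rank (numeric tolerance via [qr()]).
#'
#' @param ws list of weight functions.
#' @param grid evaluation points in `[0, 1]` (at least `length(ws)` distinct
#'   values).
#' @return `TRUE` iff the weights are linearly independent on the grid.
#' @export
check_linear_independence <- function(ws, grid = seq(0, 1, by = 0.05)) {
  m <- length(ws)
  if (length(unique(grid)) < m)
    stop("grid must contain at least m distinct points", call. = FALSE)
  M <- vapply(ws, function(w) w(grid), numeric(length(grid)))
  qr(M)$rank == m
}
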