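# Two-sample weighted log-rank statistics, their covariance estimator, the
# multi-directional quadratic form and its permutation calibration.  This is
# the computational core shared by the Bonferroni-adjusted procedures and the
# maximum test.

# Moore-Penrose pseudo-inverse via SVD.  Singular values below
# max(dim) * sqrt(machine eps) * s_max are treated as zero so that quadratic
# forms on (numerically) singular covariance matrices are reproducible.
mp_inverse <- function(S) {
  if (length(S) == 1L) {
    s <- as.numeric(S)
    return(matrix(if (abs(s) > sqrt(.Machine$double.eps)) 1 / s else 0, 1L, 1L))
  }
  sv <- svd(S)
  tol <- max(dim(S)) * sqrt(.Machine$double.eps) * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, nrow(S), ncol(S)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# Pair-pooled quantities on the pooled grid of the two groups.  `grp` is a
# 1/2 vector aligned with `times`/`status`.  Everything downstream
# (statistics, covariance, permutation) is built from this.
pair_quantities <- function(times, status, grp) {
  grid <- sort(unique(times))
  gi <- match(times, grid)
  ng <- length(grid)
  cnt1 <- tabulate(gi[grp == 1L], ng)
  cnt2 <- tabulate(gi[grp == 2L], ng)
  Y1 <- rev(cumsum(rev(cnt1)))
  Y2 <- rev(cumsum(rev(cnt2)))
  dN1 <- tabulate(gi[grp == 1L & status == 1L], ng)
  dN2 <- tabulate(gi[grp == 2L & status == 1L], ng)
  Yp <- Y1 + Y2
  dNp <- dN1 + dN2
  S <- cumprod(ifelse(Yp > 0, 1 - dNp / Yp, 1))
  Fminus <- c(0, 1 - S[-ng])
  list(grid = grid, gi = gi, Y1 = Y1, Y2 = Y2, dN1 = dN1, dN2 = dN2,
       Yp = Yp, dNp = dNp, Fminus = Fminus,
       dApool = ifelse(Yp > 0, dNp / Yp, 0))
}

# Statistic vector and covariance given pair quantities and the weight matrix
# evaluated at Fminus (ng x m).  scale = n / (n1 * n2).
wlr_core <- function(pq, wmat, scale) {
  K <- ifelse(pq$Yp > 0, pq$Y1 * pq$Y2 / pq$Yp, 0)
  dA1 <- ifelse(pq$Y1 > 0, pq$dN1 / pq$Y1, 0)
  dA2 <- ifelse(pq$Y2 > 0, pq$dN2 / pq$Y2, 0)
  stats <- sqrt(scale) * colSums(wmat * (K * (dA2 - dA1)))
  Sigma <- scale * crossprod(wmat, wmat * (K * pq$dApool))
  Sigma <- (Sigma + t(Sigma)) / 2
  list(stats = stats, Sigma = Sigma)
}

# Resolve a (j1, j2) pair given in original labels or integer codes.
resolve_pair <- function(data, pair) {
  if (length(pair) != 2L) stop("'pair' must have length 2", call. = FALSE)
  codes <- resolve_groups(data, pair)
  if (codes[1L] == codes[2L])
    stop("'pair' must name two distinct groups", call. = FALSE)
  if (any(data$n_j[codes] == 0L))
    stop("both groups of the pair must be non-empty", call. = FALSE)
  codes
}

pair_subset <- function(data, codes) {
  keep <- data$group %in% codes
  list(times = data$times[keep], status = data$status[keep],
       grp = ifelse(data$group[keep] == codes[1L], 1L, 2L),
       n1 = data$n_j[codes[1L]], n2 = data$n_j[codes[2L]])
}

#' Two-sample weighted log-rank statistic
#'
#' The statistic for the local hypothesis of equal cumulative hazards in
#' groups `j1` and `j2`:
#' \deqn{T = \sqrt{n/(n_1 n_2)} \sum_t w\{\hat F(t-)\}
#'   \frac{Y_1(t) Y_2(t)}{Y_1(t) + Y_2(t)}\,\{d\hat A_2(t) - d\hat A_1(t)\},}
#' summed over the pooled pair's event grid, where \eqn{\hat F} is the
#' pair-pooled Kaplan-Meier CDF and \eqn{\hat A_j} the group-wise
#' Nelson-Aalen estimators.  `w == 1` recovers the classical log-rank
#' statistic (up to the chosen standardization).
#'
#' @param data a [survival_dataset()].
#' @param pair two group labels `(j1, j2)`.
#' @param w a [weight_function()].
#' @return numeric scalar; antisymmetric under pair reversal.
#' @export
wlr_statistic <- function(data, pair, w = fleming_harrington(0, 0)) {
  wlr_vector(data, pair, list(w))$stats
}

#' Weighted log-rank vector with estimated covariance
#'
#' Evaluates `m` weighted log-rank statistics for one pair together with the
#' plug-in covariance estimate whose entries integrate the weight products
#' against the pair-pooled Nelson-Aalen increments.
#'
#' @param data a [survival_dataset()].
#' @param pair two group labels.
#' @param ws list of [weight_function()]s.
#' @return Object of class `wlr_vector`: list with `stats` (length m),
#'   `sigma` (m x m), `pair` (integer codes), `n` (pooled pair size).
#' @export
wlr_vector <- function(data, pair, ws = default_weights()) {
  codes <- resolve_pair(data, pair)
  ps <- pair_subset(data, codes)
  pq <- pair_quantities(ps$times, ps$status, ps$grp)
  wmat <- vapply(ws, function(w) w(pq$Fminus), numeric(length(pq$grid)))
  wmat <- matrix(wmat, nrow = length(pq$grid))
  core <- wlr_core(pq, wmat, (ps$n1 + ps$n2) / (ps$n1 * ps$n2))
  structure(list(stats = core$stats, sigma = core$Sigma, pair = codes,
                 n = ps$n1 + ps$n2),
            class = "wlr_vector")
}

#' @rdname wlr_vector
#' @return `wlr_sigma()` returns the m x m covariance matrix alone.
#' @export
wlr_sigma <- function(data, pair, ws = default_weights()) {
  wlr_vector(data, pair, ws)$sigma
}

#' Multi-directional (mdir) quadratic form
#'
#' Studentizes the weighted log-rank vector through the Moore-Penrose inverse
#' of its estimated covariance: `Z = t(stats) %*% sigma^- %*% stats`.
#' Rank-deficient covariance matrices (e.g. proportional weights on sparse
#' data) are handled by the pseudo-inverse; `Z >= 0` always.
#'
#' @param v a [wlr_vector()].
#' @return numeric scalar.
#' @export
mdir_statistic <- function(v) {
  stopifnot(inherits(v, "wlr_vector"))
  max(0, drop(crossprod(v$stats, mp_inverse(v$sigma) %*% v$stats)))
}

# Z recomputed for one assignment of pooled subjects to groups; reuses the
# fixed pooled quantities (grid, Fminus, dApool, weight matrix).
perm_mdir_z <- function(fix, z1) {
  ng <- length(fix$grid)
  cnt1 <- tabulate(fix$gi[z1], ng)
  Y1 <- rev(cumsum(rev(cnt1)))
  Y2 <- fix$Yp - Y1
  dN1 <- tabulate(fix$gi_events[z1[fix$events]], ng)
  dN2 <- fix$dNp - dN1
  K <- ifelse(fix$Yp > 0, Y1 * Y2 / fix$Yp, 0)
  dA1 <- ifelse(Y1 > 0, dN1 / Y1, 0)
  dA2 <- ifelse(Y2 > 0, dN2 / Y2, 0)
  stats <- fix$sqscale * colSums(fix$wmat * (K * (dA2 - dA1)))
  Sigma <- fix$scale * crossprod(fix$wmat, fix$wmat * (K * fix$dApool))
  max(0, drop(crossprod(stats, mp_inverse((Sigma + t(Sigma)) / 2) %*% stats)))
}

#' Permutation p-value for the mdir statistic
#'
#' Randomly reassigns the pooled pair's group labels (preserving the group
#' sizes) `B` times, recomputes the quadratic form each time, and returns the
#' add-one p-value `(1 + #\{Z* >= Z_obs\}) / (B + 1)`, which lies in
#' `(0, 1]` by construction.  Permutation acts only within the two groups
#' being compared (pairwise exchangeability under the local null).
#'
#' @param data a [survival_dataset()].
#' @param pair two group labels.
#' @param ws list of weight functions.
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return list with `p`, `z_obs`, `B`.
#' @export
mdir_permutation_pvalue <- function(data, pair, ws = default_weights(),
                                    B = 1000L, seed = NULL) {
  stopifnot(B >= 1L)
  codes <- resolve_pair(data, pair)
  ps <- pair_subset(data, codes)
  pq <- pair_quantities(ps$times, ps$status, ps$grp)
  n <- ps$n1 + ps$n2
  wmat <- matrix(vapply(ws, function(w) w(pq$Fminus),
                        numeric(length(pq$grid))), nrow = length(pq$grid))
  scale <- n / (ps$n1 * ps$n2)
  fix <- list(grid = pq$grid, gi = pq$gi, Yp = pq$Yp, dNp = pq$dNp,
              dApool = pq$dApool, wmat = wmat, scale = scale,
              sqscale = sqrt(scale),
              events = ps$status == 1L,
              gi_events = pq$gi[ps$status == 1L])
  z_obs <- perm_mdir_z(fix, ps$grp == 1L)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(B)) {
    z1 <- logical(n)
    z1[sample.int(n, ps$n1)] <- TRUE
    if (perm_mdir_z(fix, z1) >= z_obs - 1e-12) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (B + 1), z_obs = z_obs, B = B)
}

# Deterministic per-pair seed derived from a master seed and the contrast
# index, kept below 2^31 so multi-contrast runs are reproducible and
# order-independent.
derive_seed <- function(master, index) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) * 1000003 + 9973 * index) %% 2147483629)
}
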