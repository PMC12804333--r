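# MultiWeightedLR maximum test: joint covariance of all m*q weighted
# log-rank statistics, equicoordinate Gaussian critical value, and
# simultaneous local/global decisions.

# Joint statistic vector (contrast-major, weight-minor ordering) and the
# (m*q) x (m*q) plug-in covariance.  Diagonal m x m blocks are the pairwise
# covariance estimates of wlr_vector(); off-diagonal blocks between contrasts
# sharing a group use the martingale plug-in: each two-sample statistic
# decomposes into per-group integrals of H_{a,p}(t) against the group's
# counting-process martingale, whose (co)variation is estimated by
# dN_j / Y_j^2.  Blocks of disjoint contrasts are zero (independent samples).
joint_wlr <- function(data, contrasts, ws) {
  assert_pairwise(contrasts)
  m <- length(ws)
  q <- contrasts$q
  cp <- counting_processes(data)
  ng <- length(cp$grid)
  # per-contrast pair-grid statistics (bit-identical to the pairwise module)
  pairres <- lapply(seq_len(q), function(i)
    wlr_vector(data, contrasts$pairs[i, ], ws))
  stats <- unlist(lapply(pairres, `[[`, "stats"))
  # per-contrast integrand H_{a,p}(t) on the shared global grid
  Hmats <- vector("list", q)
  for (i in seq_len(q)) {
    j1 <- contrasts$pairs[i, 1L]; j2 <- contrasts$pairs[i, 2L]
    Y1 <- cp$Y[, j1]; Y2 <- cp$Y[, j2]
    Yp <- Y1 + Y2
    dNp <- cp$dN[, j1] + cp$dN[, j2]
    S <- cumprod(ifelse(Yp > 0, 1 - dNp / Yp, 1))
    Fminus <- c(0, 1 - S[-ng])
    K <- ifelse(Yp > 0, Y1 * Y2 / Yp, 0)
    sc <- sqrt((data$n_j[j1] + data$n_j[j2]) / (data$n_j[j1] * data$n_j[j2]))
    Hmats[[i]] <- sc * vapply(ws, function(w) w(Fminus) * K, numeric(ng))
  }
  Sigma <- matrix(0, m * q, m * q)
  for (a in seq_len(q)) {
    ia <- (a - 1L) * m + seq_len(m)
    Sigma[ia, ia] <- pairres[[a]]$sigma
    if (a == q) break
    for (b in seq.int(a + 1L, q)) {
      shared <- intersect(contrasts$pairs[a, ], contrasts$pairs[b, ])
      if (length(shared) == 0L) next
      block <- matrix(0, m, m)
      for (j in shared) {
        eps <- (if (j == contrasts$pairs[a, 2L]) 1 else -1) *
               (if (j == contrasts$pairs[b, 2L]) 1 else -1)
        r <- ifelse(cp$Y[, j] > 0, cp$dN[, j] / cp$Y[, j]^2, 0)
        block <- block + eps * crossprod(Hmats[[a]], Hmats[[b]] * r)
      }
      ib <- (b - 1L) * m + seq_len(m)
      Sigma[ia, ib] <- block
      Sigma[ib, ia] <- t(block)
    }
  }
  coord <- data.frame(
    contrast = rep(seq_len(q), each = m),
    weight = rep(seq_len(m), q))
  list(stats = stats, Sigma = (Sigma + t(Sigma)) / 2, coord = coord,
       m = m, q = q, Hmats = Hmats)
}

#' Joint covariance of all contrast-by-weight log-rank statistics
#'
#' Plug-in estimate of the `(m*q) x (m*q)` covariance of the vector of
#' weighted log-rank statistics over all contrasts and weights (ordering:
#' contrast-major, weight-minor).  Diagonal blocks equal the pairwise
#' covariance of [wlr_sigma()]; off-diagonal blocks between contrasts sharing
#' a group are estimated from the shared group's optional-variation process
#' `dN_j / Y_j^2`; blocks of disjoint contrasts are zero.
#'
#' As a cross-check, `method = "wild"` estimates the same matrix by wild
#' bootstrap: every subject's counting-process increment is multiplied by a
#' Rademacher variable, the statistic vector is recomputed `B` times, and the
#' Monte-Carlo covariance of the draws is returned.  On null data both
#' estimates agree up to Monte-Carlo and finite-sample error.
#'
#' @param data a [survival_dataset()].
#' @param contrasts a pairwise [make_contrasts()] set.
#' @param ws list of weight functions.
#' @param method `"plugin"` (default) or `"wild"`.
#' @param B wild-bootstrap draws (`method = "wild"` only).
#' @param seed seed for the multiplier stream (`method = "wild"` only).
#' @return `(m*q) x (m*q)` symmetric matrix.
#' @export
joint_covariance <- function(data, contrasts, ws = default_weights(),
                             method = c("plugin", "wild"), B = 2000L,
                             seed = NULL) {
  method <- match.arg(method)
  joint <- joint_wlr(data, contrasts, ws)
  if (method == "plugin") return(joint$Sigma)
  m <- length(ws); q <- contrasts$q
  cp <- counting_processes(data)
  if (!is.null(seed)) set.seed(seed)
  Tstar <- matrix(0, m * q, B)
  for (j in seq_len(data$k)) {
    sel <- data$group == j
    G <- matrix(sample(c(-1, 1), sum(sel) * B, replace = TRUE), ncol = B)
    ev <- data$status[sel] == 1L
    if (!any(ev)) next
    gi <- match(data$times[sel][ev], cp$grid)
    Yj <- cp$Y[gi, j]
    V <- matrix(0, m * q, length(gi))
    for (a in seq_len(q)) {
      pr <- contrasts$pairs[a, ]
      if (!(j %in% pr)) next
      eps <- if (j == pr[2L]) 1 else -1
      V[(a - 1L) * m + seq_len(m), ] <-
        eps * t(joint$Hmats[[a]][gi, , drop = FALSE] / Yj)
    }
    Tstar <- Tstar + V %*% G[ev, , drop = FALSE]
  }
  tcrossprod(Tstar) / B
}

# Clip negative eigenvalues at zero and rescale back to unit diagonal;
# finite-sample plug-in blocks need not be jointly positive semidefinite.
psd_repair_corr <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values >= 0)) return(R)
  V <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  d <- sqrt(pmax(diag(V), .Machine$double.eps))
  R2 <- V / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

# Central multivariate-normal rectangle probability P(all |Z_i| <= c) with a
# fixed integration seed (randomized-lattice algorithm of pmvnorm), leaving
# the caller's RNG state untouched.
mvn_rect_prob <- function(c, R, seed) {
  if (nrow(R) == 1L) return(2 * stats::pnorm(c) - 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  as.numeric(mvtnorm::pmvnorm(
    lower = rep(-c, nrow(R)), upper = rep(c, nrow(R)), corr = R,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 50000L)))
}

#' Equicoordinate quantile of a centered multivariate normal
#'
#' The smallest `c` with `P(max_i |Z_i| <= c) >= 1 - alpha` for a centered
#' Gaussian vector with correlation matrix `R` — the simultaneous critical
#' value of the maximum test.  Rectangle probabilities are computed by the
#' deterministic randomized-lattice rule at a fixed integration seed and `c`
#' is located by bisection (bracket `[1, 6]`, expanded when needed).
#'
#' @param R correlation matrix (unit diagonal; repaired to positive
#'   semidefinite internally if needed).
#' @param alpha significance level in (0, 1).
#' @param tol absolute tolerance on `c`.
#' @param seed integration seed (fixed so critical values are reproducible).
#' @return numeric critical value.
#' @examples
#' equicoordinate_quantile(diag(1), 0.05)          # 1.96
#' equicoordinate_quantile(diag(2), 0.05)          # about 2.2365
#' @export
equicoordinate_quantile <- function(R, alpha = 0.05, tol = 1e-3, seed = 20260101L) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || any(abs(diag(R) - 1) > 1e-8))
    stop("'R' must be a square correlation matrix with unit diagonal",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (nrow(R) == 1L) return(stats::qnorm(1 - alpha / 2))
  R <- psd_repair_corr(R)
  target <- 1 - alpha
  lo <- 1; hi <- 6
  while (mvn_rect_prob(lo, R, seed) >= target && lo > 1e-3) lo <- lo / 2
  while (mvn_rect_prob(hi, R, seed) < target && hi < 50) hi <- hi * 1.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mvn_rect_prob(mid, R, seed) >= target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' MultiWeightedLR maximum test
#'
#' Simultaneous test over all contrasts and weight functions: each weighted
#' log-rank statistic is studentized by its own estimated standard deviation,
#' the global statistic is `T_max`, the maximum of the absolute standardized
#' entries, and the per-contrast statistic is the maximum over that
#' contrast's weights.  Both are compared against the equicoordinate
#' `(1 - alpha)`-quantile of a centered multivariate normal with the
#' estimated correlation matrix, so the correlation between the statistics is
#' exploited instead of a Bonferroni bound.  Adjusted p-values are
#' `1 - P(max <= observed)` under the fitted Gaussian.
#'
#' Coordinates whose estimated variance is zero (no events in the pair) are
#' dropped with a warning.
#'
#' @param data a [survival_dataset()].
#' @param contrasts a pairwise [make_contrasts()] set.
#' @param ws list of weight functions.
#' @param alpha global significance level.
#' @param seed integration seed for the Gaussian quantile.
#' @return An `mctp_result`; component `coordinates` holds the standardized
#'   statistics with simultaneous `+/- c` intervals.
#' @export
multiweightedlr_test <- function(data, contrasts, ws = default_weights(),
                                 alpha = 0.05, seed = 20260101L) {
  joint <- joint_wlr(data, contrasts, ws)
  sdv <- sqrt(pmax(diag(joint$Sigma), 0))
  keep <- sdv > 0
  if (!any(keep))
    stop("no events in any contrast: maximum test undefined", call. = FALSE)
  if (!all(keep))
    warning(sum(!keep), " coordinate(s) with zero estimated variance ",
            "(no events in the pair) dropped", call. = FALSE)
  Tstd <- joint$stats[keep] / sdv[keep]
  R <- psd_repair_corr(stats::cov2cor(joint$Sigma[keep, keep, drop = FALSE]))
  cval <- equicoordinate_quantile(R, alpha, seed = seed)
  coord <- joint$coord[keep, , drop = FALSE]
  t_local <- vapply(seq_len(joint$q), function(a) {
    v <- abs(Tstd[coord$contrast == a])
    if (length(v)) max(v) else 0
  }, numeric(1))
  p_adj <- vapply(t_local, function(t0)
    if (t0 <= 0) 1 else max(0, 1 - mvn_rect_prob(t0, R, seed = 20260101L)),
    numeric(1))
  tab <- data.frame(contrast = pair_names(data, contrasts$pairs),
                    statistic = t_local, critical = cval, p_adj = p_adj,
                    reject = t_local > cval)
  res <- mctp_result("MultiWeightedLR maximum test", data, contrasts, tab,
                     global_reject = any(tab$reject), alpha = alpha,
                     adjustment = list(critical_value = cval),
                     seed = seed)
  res$coordinates <- data.frame(
    contrast = pair_names(data, contrasts$pairs)[coord$contrast],
    weight = vapply(ws, function(w) attr(w, "label"), character(1))[coord$weight],
    stat_std = Tstd, lower = Tstd - cval, upper = Tstd + cval)
  res$t_max <- if (length(Tstd)) max(abs(Tstd)) else 0
  res
}
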