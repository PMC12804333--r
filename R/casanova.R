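# multiCASANOVA: pooled-weight contrast statistics, per-contrast Wald
# quadratic forms, and wild-bootstrap calibration of the maximum statistic.
# Unlike the pairwise module, weights and at-risk denominators here use
# quantities pooled over ALL groups, so at k = 2 the two constructions
# coincide exactly.

# Observed statistics, covariance pseudo-inverses and the bootstrap
# coefficient vectors for every contrast, all on the global event grid.
casanova_core <- function(data, contrasts, ws) {
  assert_pairwise(contrasts)
  m <- length(ws)
  cp <- counting_processes(data)
  ng <- length(cp$grid)
  S <- cumprod(ifelse(cp$Y_total > 0, 1 - cp$dN_total / cp$Y_total, 1))
  Fminus <- c(0, 1 - S[-ng])
  dA <- ifelse(cp$Y_total > 0, cp$dN_total / cp$Y_total, 0)
  wFm <- matrix(vapply(ws, function(w) w(Fminus), numeric(ng)), nrow = ng)
  dAg <- ifelse(cp$Y > 0, cp$dN / cp$Y, 0)          # group NA increments
  per <- lapply(seq_len(contrasts$q), function(i) {
    j1 <- contrasts$pairs[i, 1L]; j2 <- contrasts$pairs[i, 2L]
    scale <- (data$n_j[j1] + data$n_j[j2]) / (data$n_j[j1] * data$n_j[j2])
    K <- ifelse(cp$Y_total > 0, cp$Y[, j1] * cp$Y[, j2] / cp$Y_total, 0)
    tvec <- sqrt(scale) * colSums(wFm * (K * (dAg[, j2] - dAg[, j1])))
    cov <- scale * crossprod(wFm, wFm * (K * dA))
    cov <- (cov + t(cov)) / 2
    pinv <- mp_inverse(cov)
    list(pair = c(j1, j2), tvec = tvec, cov = cov, pinv = pinv,
         C = max(0, drop(crossprod(tvec, pinv %*% tvec))),
         coef = sqrt(scale) * (wFm * K))          # ng x m bootstrap coefs
  })
  list(cp = cp, per = per, m = m, q = contrasts$q)
}

#' Pooled-weight contrast statistic (multiCASANOVA)
#'
#' The local statistic for contrast `(j1, j2)` built from quantities pooled
#' over all `k` groups: the weight is evaluated at the left limit of the
#' all-group Kaplan-Meier CDF, the denominator is the all-group at-risk count
#' `Y(t)`, and the covariance integrates against the all-group pooled
#' Nelson-Aalen increments.  The Wald-type value is
#' `C = t(T) %*% Cov^- %*% T` with the Moore-Penrose inverse.  At `k = 2`
#' this reduces exactly to the pairwise mdir construction.
#'
#' @param data a [survival_dataset()] containing all `k` groups.
#' @param pair two group labels `(j1, j2)`.
#' @param ws list of weight functions.
#' @return Object of class `casanova_stat`: list with `pair`, `t_vector`,
#'   `cov`, `C`.
#' @export
casanova_statistic <- function(data, pair, ws = default_weights()) {
  codes <- resolve_pair(data, pair)
  core <- casanova_core(data, make_contrasts("custom", data$k,
                                             pairs = rbind(codes)), ws)
  p <- core$per[[1L]]
  structure(list(pair = codes, t_vector = p$tvec, cov = p$cov, C = p$C),
            class = "casanova_stat")
}

#' Wild-bootstrap Nelson-Aalen estimator
#'
#' Replaces the unobservable counting-process martingales by
#' `G_ji * N_ji` with i.i.d. mean-zero unit-variance multipliers `G_ji`:
#' `A*_j(t) = sum_{s <= t} (sum_{i: X_ji = s, event} G_ji) / Y_j(s)`.
#' Censored subjects contribute nothing; with all multipliers equal to 1 the
#' ordinary Nelson-Aalen estimate is recovered, with all 0 the zero function.
#'
#' @param data a [survival_dataset()].
#' @param group one group label.
#' @param multipliers numeric vector, one multiplier per subject of the
#'   group, in the subjects' order of appearance in `data`.
#' @return A [step_estimate()] on the group's own time grid.
#' @export
wild_bootstrap_na <- function(data, group, multipliers) {
  code <- resolve_groups(data, group)
  if (length(code) != 1L) stop("'group' must be a single label", call. = FALSE)
  sel <- data$group == code
  if (length(multipliers) != sum(sel))
    stop("need exactly one multiplier per subject of the group (",
         sum(sel), " subjects, ", length(multipliers), " multipliers)",
         call. = FALSE)
  times <- data$times[sel]; status <- data$status[sel]
  grid <- sort(unique(times))
  gi <- match(times, grid)
  ng <- length(grid)
  cnt <- tabulate(gi, ng)
  Y <- rev(cumsum(rev(cnt)))
  num <- numeric(ng)
  ev <- status == 1L
  if (any(ev)) {
    agg <- rowsum(multipliers[ev], gi[ev])
    num[as.integer(rownames(agg))] <- agg
  }
  step_estimate(grid, cumsum(ifelse(Y > 0, num / Y, 0)), init = 0,
                kind = "wild-bootstrap nelson-aalen")
}

draw_multipliers <- function(multiplier, n) {
  switch(multiplier,
         rademacher = sample(c(-1, 1), n, replace = TRUE),
         poisson = stats::rpois(n, 1) - 1,
         stop("unknown multiplier law: ", multiplier, call. = FALSE))
}

#' multiCASANOVA wild-bootstrap test
#'
#' Computes the pooled Wald statistic `C` of [casanova_statistic()] for every
#' contrast, takes `C_max` over contrasts as the global statistic (the
#' weights are already combined inside each quadratic form), and calibrates
#' against the wild bootstrap: per draw, fresh mean-zero unit-variance
#' multipliers are attached to every subject (shared across all contrasts so
#' their joint dependence is preserved), the group-wise Nelson-Aalen
#' increments are replaced by their bootstrap versions while the data-based
#' covariance stays fixed, and `C*_max` is recorded.  The critical value
#' `q*` is the empirical `(1 - alpha)`-quantile of the bootstrap sample,
#' taken with the add-one convention (order statistic at
#' `ceiling((1 - alpha) (B + 1))`), which keeps the rejection probability at
#' or below `alpha` under exchangeability; a hypothesis is rejected when its
#' statistic exceeds `q*`.
#'
#' @param data a [survival_dataset()].
#' @param contrasts a pairwise [make_contrasts()] set.
#' @param ws list of weight functions.
#' @param multiplier `"rademacher"` (default) or `"poisson"` (centered
#'   Poisson(1)).
#' @param B bootstrap draws.
#' @param alpha global significance level.
#' @param seed master seed for the multiplier stream.
#' @return An `mctp_result`; `p_adj` is the add-one proportion of bootstrap
#'   `C*_max` values at or above each local statistic.
#' @export
multicasanova_test <- function(data, contrasts, ws = default_weights(),
                               multiplier = c("rademacher", "poisson"),
                               B = 1000L, alpha = 0.05, seed = NULL) {
  multiplier <- match.arg(multiplier)
  stopifnot(B >= 1L)
  core <- casanova_core(data, contrasts, ws)
  C_obs <- vapply(core$per, `[[`, numeric(1), "C")
  C_max <- max(C_obs)
  cp <- core$cp
  m <- core$m; q <- core$q
  # Per-group map from event subjects to global grid rows and the matrix V_j
  # with V_j[(a,p), i] = eps_a(j) * coef_{a,p}(t_i) / Y_j(t_i): the bootstrap
  # statistic vector is then sum_j V_j %*% G_j (events only).
  if (!is.null(seed)) set.seed(seed)
  Tstar <- matrix(0, m * q, B)
  grid <- cp$grid
  for (j in seq_len(data$k)) {
    sel <- data$group == j
    G <- matrix(draw_multipliers(multiplier, sum(sel) * B), ncol = B)
    ev <- data$status[sel] == 1L
    if (!any(ev)) next
    gi <- match(data$times[sel][ev], grid)
    Yj <- cp$Y[gi, j]
    V <- matrix(0, m * q, length(gi))
    for (a in seq_len(q)) {
      pr <- core$per[[a]]$pair
      if (!(j %in% pr)) next
      eps <- if (j == pr[2L]) 1 else -1
      V[(a - 1L) * m + seq_len(m), ] <-
        eps * t(core$per[[a]]$coef[gi, , drop = FALSE] / Yj)
    }
    Tstar <- Tstar + V %*% G[ev, , drop = FALSE]
  }
  Cstar <- matrix(0, q, B)
  for (a in seq_len(q)) {
    Tm <- Tstar[(a - 1L) * m + seq_len(m), , drop = FALSE]
    Cstar[a, ] <- pmax(0, colSums((core$per[[a]]$pinv %*% Tm) * Tm))
  }
  Cmax_star <- apply(Cstar, 2L, max)
  # add-one quantile convention: under exchangeability of the observed
  # statistic with the bootstrap draws, P(C > q*) = 25/501 <= alpha at
  # B = 500, whereas the index ceiling((1-alpha)*B) gives 26/501 > alpha
  qstar <- sort(Cmax_star)[min(B, ceiling((1 - alpha) * (B + 1)))]
  p_adj <- vapply(C_obs, function(c0) (1 + sum(Cmax_star >= c0)) / (B + 1),
                  numeric(1))
  tab <- data.frame(contrast = pair_names(data, contrasts$pairs),
                    statistic = C_obs, critical = qstar, p_adj = p_adj,
                    reject = C_obs > qstar)
  res <- mctp_result(
    sprintf("multiCASANOVA wild-bootstrap test (%s multipliers)", multiplier),
    data, contrasts, tab, global_reject = any(tab$reject), alpha = alpha,
    adjustment = list(bootstrap_quantile = qstar), B = B,
    seed = if (is.null(seed)) NA_integer_ else seed)
  res$C_max <- C_max
  res$bootstrap_Cmax <- Cmax_star
  res
}
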