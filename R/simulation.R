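# Scenario generator and Monte-Carlo harness for family-wise error rate and
# power studies: four named hazard-shape scenarios (proportional,
# non-proportional, crossing, mixed), uniform censoring calibrated to a
# target rate per group, and a per-run counter-seeded simulation loop.

#' Survival law specification
#'
#' Parameter conventions follow the standard R distributions:
#' `exponential(rate)`, `lognormal(meanlog, sdlog)` (mean and sd of
#' log-time), `weibull(shape, scale)`.
#'
#' @param family `"exponential"`, `"lognormal"` or `"weibull"`.
#' @param ... distribution parameters (see Details).
#' @return Object of class `survival_law`.
#' @examples
#' survival_law("exponential", rate = 1.2)
#' survival_law("weibull", shape = 1.5, scale = 5)
#' @export
survival_law <- function(family, ...) {
  pars <- list(...)
  need <- switch(family,
                 exponential = "rate",
                 lognormal = c("meanlog", "sdlog"),
                 weibull = c("shape", "scale"),
                 stop("unknown distribution family: ", family, call. = FALSE))
  if (length(pars) == length(need) && is.null(names(pars)))
    names(pars) <- need
  if (!setequal(names(pars), need))
    stop(family, " law needs parameter(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(family = family, pars = pars[need]), class = "survival_law")
}

law_sample <- function(law, n) {
  p <- law$pars
  switch(law$family,
         exponential = stats::rexp(n, rate = p$rate),
         lognormal = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
         weibull = stats::rweibull(n, shape = p$shape, scale = p$scale))
}

law_survival <- function(law, t) {
  p <- law$pars
  switch(law$family,
         exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
         lognormal = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                   lower.tail = FALSE),
         weibull = stats::pweibull(t, shape = p$shape, scale = p$scale,
                                   lower.tail = FALSE))
}

law_hazard <- function(law, t) {
  p <- law$pars
  dens <- switch(law$family,
                 exponential = stats::dexp(t, rate = p$rate),
                 lognormal = stats::dlnorm(t, p$meanlog, p$sdlog),
                 weibull = stats::dweibull(t, p$shape, p$scale))
  dens / law_survival(law, t)
}

law_equal <- function(a, b) {
  a$family == b$family && isTRUE(all.equal(unlist(a$pars), unlist(b$pars)))
}

#' @export
print.survival_law <- function(x, ...) {
  cat(x$family, "(", paste(sprintf("%s=%g", names(x$pars), unlist(x$pars)),
                           collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# The four named scenarios: k = 4 groups with the hazard relationships
# (i) proportional, (ii) non-proportional non-crossing, (iii) crossing,
# (iv) mixed.
scenario_presets <- function(name) {
  switch(name,
    Prop = list(survival_law("exponential", rate = 1.2),
                survival_law("exponential", rate = 1.8),
                survival_law("exponential", rate = 2.3),
                survival_law("exponential", rate = 2.9)),
    NProp = list(survival_law("lognormal", meanlog = 2.2, sdlog = 1.7),
                 survival_law("lognormal", meanlog = 2.6, sdlog = 1.6),
                 survival_law("lognormal", meanlog = 3.5, sdlog = 1.7),
                 survival_law("lognormal", meanlog = 4.5, sdlog = 1.6)),
    Cross = list(survival_law("weibull", shape = 1.5, scale = 5),
                 survival_law("weibull", shape = 2.5, scale = 5),
                 survival_law("weibull", shape = 3.5, scale = 5),
                 survival_law("weibull", shape = 4.5, scale = 5)),
    Mix = list(survival_law("lognormal", meanlog = 2.3, sdlog = 1.7),
               survival_law("exponential", rate = 0.05),
               survival_law("weibull", shape = 2.4, scale = 11.7),
               survival_law("lognormal", meanlog = 3, sdlog = 1.6)),
    stop("unknown scenario name: ", name, call. = FALSE))
}

#' Simulation scenario
#'
#' Bundles per-group survival laws, group sizes, a censoring target and the
#' contrast type.  Named presets `Prop`, `NProp`, `Cross` and `Mix` set the
#' four standard hazard configurations for `k = 4` groups; `custom` takes
#' explicit `laws`.  Censoring times are Uniform(0, u) with `u` calibrated
#' per group so that `P(C < T)` equals the target (see
#' [calibrate_censoring()]); a target of 0 disables censoring.
#'
#' @param name preset name or `"custom"`.
#' @param laws list of [survival_law()]s (overrides the preset).
#' @param n group sizes: scalar or length-k vector.
#' @param censoring censoring target in `[0, 1)` (defaults to 0).
#' @param contrasts `"tukey"` or `"dunnett"`.
#' @param alpha global significance level.
#' @return Object of class `mc_scenario`.
#' @examples
#' scenario("Prop", n = 100, censoring = 0.2)
#' @export
scenario <- function(name = c("Prop", "NProp", "Cross", "Mix", "custom"),
                     laws = NULL, n = 100, censoring = 0,
                     contrasts = c("tukey", "dunnett"), alpha = 0.05) {
  name <- match.arg(name)
  contrasts <- match.arg(contrasts)
  if (is.null(laws)) {
    if (name == "custom") stop("custom scenarios need 'laws'", call. = FALSE)
    laws <- scenario_presets(name)
  }
  k <- length(laws)
  if (k < 2L) stop("a scenario needs at least two groups", call. = FALSE)
  n <- rep_len(as.integer(n), k)
  if (any(n < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  if (censoring < 0 || censoring >= 1)
    stop("'censoring' target must lie in [0, 1)", call. = FALSE)
  structure(list(name = name, laws = laws, n = n, censoring = censoring,
                 contrasts = contrasts, alpha = alpha, k = k,
                 cens_upper = NULL),
            class = "mc_scenario")
}

#' @export
print.mc_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': k = %d groups, n = (%s), censoring target %g%%, %s contrasts\n",
              x$name, x$k, paste(x$n, collapse = ", "), 100 * x$censoring,
              x$contrasts))
  for (l in x$laws) print(l)
  invisible(x)
}

#' Calibrate the uniform censoring bound
#'
#' Finds `u` such that `P(C < T) = target` for `C ~ Uniform(0, u)` and
#' `T` following `law`: `P(C < T) = (1/u) * integral_0^u S_T(c) dc`, which is
#' strictly decreasing in `u`, so the root is unique.  Solved by
#' [stats::uniroot()] with bracket expansion; `target = 0` returns `Inf`
#' (no censoring).
#'
#' @param law a [survival_law()].
#' @param target censoring proportion in `[0, 1)`.
#' @return the upper bound `u` (`Inf` when `target` is 0).
#' @examples
#' calibrate_censoring(survival_law("exponential", rate = 1.2), 0.3)
#' @export
calibrate_censoring <- function(law, target) {
  if (target < 0 || target >= 1)
    stop("'target' must lie in [0, 1)", call. = FALSE)
  if (target == 0) return(Inf)
  pcens <- function(u)
    stats::integrate(function(s) law_survival(law, s), 0, u,
                     rel.tol = 1e-9)$value / u
  lo <- 1e-6; hi <- 1
  while (pcens(hi) > target && hi < 1e8) hi <- hi * 2
  if (pcens(hi) > target)
    stop("censoring root not bracketed after expansion", call. = FALSE)
  stats::uniroot(function(u) pcens(u) - target, c(lo, hi),
                 tol = 1e-8)$root
}

calibrate_scenario <- function(sc) {
  if (!is.null(sc$cens_upper)) return(sc)
  sc$cens_upper <- if (sc$censoring == 0) rep(Inf, sc$k) else
    vapply(sc$laws, calibrate_censoring, numeric(1), target = sc$censoring)
  sc
}

#' Draw one dataset from a scenario
#'
#' Event times come from each group's survival law; censoring times are
#' Uniform(0, u_j) with the group-specific calibrated bound; the observed
#' time is the minimum and the status indicates an event.
#'
#' @param sc an [scenario()] object.
#' @param seed optional integer seed.
#' @return A [survival_dataset()] with groups labelled `1..k`.
#' @export
sample_scenario <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "mc_scenario"))
  sc <- calibrate_scenario(sc)
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0); status <- integer(0); group <- integer(0)
  for (j in seq_len(sc$k)) {
    tt <- law_sample(sc$laws[[j]], sc$n[j])
    if (is.finite(sc$cens_upper[j])) {
      cc <- stats::runif(sc$n[j], 0, sc$cens_upper[j])
      x <- pmin(tt, cc)
      d <- as.integer(tt <= cc)
    } else {
      x <- tt; d <- rep(1L, sc$n[j])
    }
    times <- c(times, x); status <- c(status, d)
    group <- c(group, rep(j, sc$n[j]))
  }
  survival_dataset(times, status, group)
}

# Which contrasts are true nulls: a pair is null iff both groups follow an
# identical law.
scenario_null_contrasts <- function(sc, contrasts) {
  vapply(seq_len(contrasts$q), function(i)
    law_equal(sc$laws[[contrasts$pairs[i, 1L]]],
              sc$laws[[contrasts$pairs[i, 2L]]]), logical(1))
}

#' Binomial precision band around a nominal rate
#'
#' @param nominal nominal rate (e.g. 0.05).
#' @param runs Monte-Carlo runs.
#' @param level band coverage (default 95%).
#' @return length-2 vector `c(lower, upper)` on the probability scale.
#' @examples
#' round(100 * precision_band(0.05, 10000), 2)  # 4.57 5.43
#' @export
precision_band <- function(nominal, runs, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(nominal * (1 - nominal) / runs)
  c(lower = nominal - half, upper = nominal + half)
}

mc_methods <- c("adjusted_logrank", "adjusted_mdir", "multiweightedlr",
                "multicasanova_rademacher", "multicasanova_poisson")

apply_method <- function(method, data, contrasts, ws, alpha, B, seed) {
  res <- switch(method,
    adjusted_logrank = adjusted_logrank_test(data, contrasts, alpha = alpha),
    adjusted_mdir = suppressWarnings(
      adjusted_mdir_test(data, contrasts, ws, B = B, alpha = alpha,
                         seed = seed)),
    multiweightedlr = multiweightedlr_test(data, contrasts, ws,
                                           alpha = alpha),
    multicasanova_rademacher = multicasanova_test(
      data, contrasts, ws, multiplier = "rademacher", B = B, alpha = alpha,
      seed = seed),
    multicasanova_poisson = multicasanova_test(
      data, contrasts, ws, multiplier = "poisson", B = B, alpha = alpha,
      seed = seed),
    stop("unknown method: ", method, call. = FALSE))
  res$table$reject
}

#' Monte-Carlo study of FWER and local power
#'
#' Repeatedly simulates a scenario and applies the requested procedures.
#' The family-wise error rate is the fraction of runs with at least one
#' rejection among true-null contrasts (pairs of identically distributed
#' groups); local power is the per-contrast rejection fraction among
#' false-null contrasts.  Runs are independently seeded by a counter derived
#' from the master seed, so results do not depend on execution order.
#'
#' @param sc an [scenario()].
#' @param methods character vector from `"adjusted_logrank"`,
#'   `"adjusted_mdir"`, `"multiweightedlr"`, `"multicasanova_rademacher"`,
#'   `"multicasanova_poisson"`.
#' @param runs number of simulated datasets.
#' @param B resampling iterations for permutation/bootstrap methods.
#' @param master_seed integer master seed.
#' @param ws weight set for the multi-weight procedures.
#' @return Object of class `mc_report`: per-method FWER, per-contrast
#'   rejection rates, the null/false partition of contrasts, run counts and
#'   the binomial precision band of the nominal level.
#' @export
run_study <- function(sc, methods = "adjusted_logrank", runs = 1000L,
                      B = 1000L, master_seed = 1L, ws = default_weights()) {
  stopifnot(inherits(sc, "mc_scenario"), runs >= 1L)
  methods <- match.arg(methods, mc_methods, several.ok = TRUE)
  sc <- calibrate_scenario(sc)
  contrasts <- make_contrasts(sc$contrasts, sc$k)
  is_null <- scenario_null_contrasts(sc, contrasts)
  rej <- array(FALSE, c(length(methods), contrasts$q, runs),
               dimnames = list(methods, NULL, NULL))
  for (r in seq_len(runs)) {
    run_seed <- derive_seed(master_seed, r)
    data <- sample_scenario(sc, seed = run_seed)
    for (mi in seq_along(methods))
      rej[mi, , r] <- apply_method(methods[mi], data, contrasts, ws,
                                   sc$alpha, B,
                                   seed = derive_seed(run_seed, 1000L + mi))
  }
  local_rate <- apply(rej, c(1L, 2L), mean)
  fwer <- if (any(is_null))
    vapply(seq_along(methods), function(mi)
      mean(apply(rej[mi, is_null, , drop = FALSE], 3L, any)), numeric(1))
  else rep(NA_real_, length(methods))
  structure(
    list(scenario = sc$name, methods = methods, runs = runs, B = B,
         master_seed = master_seed, alpha = sc$alpha,
         contrast_pairs = contrasts$pairs, is_null = is_null,
         fwer = stats::setNames(fwer, methods),
         local_rates = local_rate,
         band = precision_band(sc$alpha, runs)),
    class = "mc_report")
}

#' @export
print.mc_report <- function(x, digits = 4, ...) {
  cat(sprintf("Monte-Carlo report: scenario '%s', %d runs, alpha = %g\n",
              x$scenario, x$runs, x$alpha))
  cat(sprintf("Binomial precision band: [%.2f%%, %.2f%%]\n",
              100 * x$band[1L], 100 * x$band[2L]))
  cat("\nFWER over true-null contrasts:\n")
  print(round(100 * x$fwer, 2))
  if (any(!x$is_null)) {
    cat("\nLocal power (false-null contrasts):\n")
    pw <- x$local_rates[, !x$is_null, drop = FALSE]
    colnames(pw) <- apply(x$contrast_pairs[!x$is_null, , drop = FALSE], 1L,
                          paste, collapse = " vs ")
    print(round(100 * pw, 2))
  }
  invisible(x)
}

#' Tidy Monte-Carlo report table
#'
#' @param x an `mc_report`.
#' @param ... unused.
#' @return data.frame with one row per method and contrast plus the FWER
#'   rows.
#' @export
as.data.frame.mc_report <- function(x, ...) {
  q <- ncol(x$local_rates)
  local <- data.frame(
    method = rep(x$methods, each = q),
    quantity = rep(paste0("local_", apply(x$contrast_pairs, 1L, paste,
                                          collapse = "_vs_")), length(x$methods)),
    null_contrast = rep(x$is_null, length(x$methods)),
    rate = as.vector(t(x$local_rates)))
  global <- data.frame(method = x$methods, quantity = "fwer",
                       null_contrast = NA, rate = unname(x$fwer))
  rbind(global, local)
}
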