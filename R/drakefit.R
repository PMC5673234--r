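#' Solve Drake's implicit mutation-rate equation
#'
#' Drake's median estimator relates the mutation rate per cell division
#' \eqn{\mu} to the median mutant frequency \eqn{f} and the population size
#' \eqn{N} through the implicit equation \eqn{\mu \, \ln(N\mu) = f}. The
#' left-hand side is strictly increasing in \eqn{\mu} on \eqn{(e/N, \infty)},
#' so for \eqn{f > e/N} there is a unique root on \eqn{(e/N, f]}, found here
#' by bisection to a relative tolerance of `tol`.
#'
#' @param f median mutant frequency (dimensionless), must exceed `e/N`.
#' @param N population size (cells per culture).
#' @param tol relative bisection tolerance on \eqn{\mu}.
#' @return the mutation rate per cell division.
#' @examples
#' drake_rate(1e-7 * log(1e8 * 1e-7), 1e8)  # recovers 1e-7
#' @export
drake_rate <- function(f, N, tol = 1e-10) {
  if (length(f) > 1L || length(N) > 1L)
    return(mapply(drake_rate, f, N, MoreArgs = list(tol = tol)))
  if (!is.finite(f) || !is.finite(N) || N <= 0)
    stop("f and N must be finite, N > 0", call. = FALSE)
  if (f <= 0)
    stop("median mutant frequency is 0: the rate is undefined; ",
         "report an upper bound from one hypothetical mutant instead",
         call. = FALSE)
  g <- function(mu) mu * log(N * mu) - f
  lo <- exp(1) / N * (1 + 1e-12)
  hi <- f
  if (g(hi) < 0 || lo >= hi)
    stop("no root with N*mu > e: need N > e/f (f = ", format(f),
         ", N = ", format(N), ")", call. = FALSE)
  repeat {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * mid) break
  }
  (lo + hi) / 2
}

# Root of mu*ln(N*mu) = f on the full monotone branch mu > 1/(e*N).
# Used for bounds below the e/N bracket of the published formula (the
# one-hypothetical-mutant convention f = 1/N, and small CI bounds), where
# the implicit equation still has a unique solution with N*mu < e.
drake_rate_extended <- function(f, N, tol = 1e-10) {
  if (f <= 0) stop("f must be positive", call. = FALSE)
  if (f > exp(1) / N) return(drake_rate(f, N, tol))
  g <- function(mu) mu * log(N * mu) - f
  lo <- 1 / N                # g(1/N) = 0 - f < 0 for f > 0
  hi <- exp(1) / N
  repeat {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * mid) break
  }
  (lo + hi) / 2
}

#' Fit a mutation rate to a fluctuation assay by Drake's median estimator
#'
#' The fitting routine (i) corrects each culture's selective count by
#' excluding verification-positive colonies and scales by the selective
#' dilution, (ii) measures each culture's population census from the
#' permissive plate, (iii) takes the median mutant frequency \eqn{f} and a
#' population-size summary \eqn{N} (median across cultures by default), and
#' (iv) solves \eqn{\mu \ln(N\mu) = f} for the mutation rate per cell
#' division.
#'
#' The confidence interval is a distribution-free order-statistic interval
#' for the median mutant frequency (binomial argument on the ranks),
#' transformed through the monotone Drake relation at the same \eqn{N}.
#' With fewer than about six cultures no pair of order statistics reaches
#' 95% coverage; the widest available interval is then used and flagged
#' (`ci_flagged`). A frequency bound of zero yields a lower rate bound of
#' 0; a positive bound below e/N is transformed on the lower branch of the
#' implicit equation (N mu < e), where the relation is still monotone.
#'
#' If every corrected count is zero the rate itself is undefined; the fit
#' then reports the upper bound obtained from one hypothetical mutant
#' (\eqn{f_{\min} = 1/N}) and sets `is_upper_bound`.
#'
#' @param cs a [culture_set()].
#' @param conf.level confidence level for the interval (default 0.95).
#' @param n_summary how to summarise per-culture population censuses into
#'   the single \eqn{N} of Drake's formula: `"median"` (default, robust) or
#'   `"mean"`.
#' @return an object of class `"drakefit"`: a list with components `mu`,
#'   `ci_low`, `ci_high`, `f_median`, `n_population`, `n_cultures`,
#'   `conf.level`, `is_upper_bound`, `ci_flagged`, `genotype`, `locus`.
#' @seealso [drake_rate()], [simulate_cultures()], [fold_change()],
#'   [synergy_index()]
#' @examples
#' cfg <- simulation_config(n_cultures = 12, seed = 42)
#' fit <- drakefit(simulate_cultures(cfg))
#' coef(fit)
#' confint(fit)
#' @export
drakefit <- function(cs, conf.level = 0.95, n_summary = c("median", "mean")) {
  n_summary <- match.arg(n_summary)
  mutants <- corrected_mutant_counts(cs)
  pops <- population_sizes(cs)
  n <- length(mutants)
  freqs <- mutants / pops
  if (any(pops <= 0))
    stop("population census must be positive for every culture", call. = FALSE)
  f_med <- median_mutant_frequency(mutants, pops)
  N <- if (n_summary == "median") stats::median(pops) else mean(pops)

  is_upper_bound <- f_med <= 0
  mu <- if (is_upper_bound) {
    # zero-mutant convention: bound from a single hypothetical mutant
    drake_rate_extended(1 / N, N)
  } else {
    drake_rate_extended(f_med, N)
  }

  ci <- median_orderstat_ci(sort(freqs), conf.level)
  ci_low <- if (ci$lower <= 0) 0 else drake_rate_extended(ci$lower, N)
  ci_high <- if (ci$upper <= 0) mu else drake_rate_extended(ci$upper, N)
  # monotone transform keeps the ordering; guard numerically anyway
  ci_low <- min(ci_low, mu)
  ci_high <- max(ci_high, mu)

  structure(list(
    mu = mu, ci_low = ci_low, ci_high = ci_high,
    f_median = f_med, n_population = N, n_cultures = n,
    conf.level = conf.level, is_upper_bound = is_upper_bound,
    ci_flagged = ci$flagged,
    genotype = attr(cs, "genotype"), locus = attr(cs, "locus")
  ), class = "drakefit")
}

# Distribution-free CI for a median from sorted values: pick the symmetric
# pair of order statistics (x_(k), x_(n+1-k)) with the largest k whose
# binomial coverage 1 - 2 P(Bin(n, 1/2) <= k-1) still reaches the level.
median_orderstat_ci <- function(x_sorted, level) {
  n <- length(x_sorted)
  alpha <- (1 - level) / 2
  k <- stats::qbinom(alpha, n, 0.5)           # P(X <= k) <= alpha or nearest
  while (k >= 1 && stats::pbinom(k - 1, n, 0.5) > alpha) k <- k - 1
  flagged <- FALSE
  if (k < 1) { k <- 1; flagged <- TRUE }      # widest available interval
  list(lower = x_sorted[k], upper = x_sorted[n + 1 - k], flagged = flagged)
}

#' @export
print.drakefit <- function(x, ...) {
  lab <- if (x$is_upper_bound) "< " else ""
  cat(sprintf("Drake median estimate of mutation rate (%s at %s)\n",
              x$genotype, x$locus))
  cat(sprintf("  mu = %s%s per cell division (%d%% CI %s - %s)\n",
              lab, fmt_rate(x$mu), round(100 * x$conf.level),
              fmt_rate(x$ci_low), fmt_rate(x$ci_high)))
  cat(sprintf("  f_median = %s, N = %s, cultures = %d\n",
              format(signif(x$f_median, 4)), format(signif(x$n_population, 4)),
              x$n_cultures))
  if (x$ci_flagged)
    cat("  note: too few cultures for the requested level;",
        "widest order-statistic interval reported\n")
  invisible(x)
}

#' @export
coef.drakefit <- function(object, ...) c(mu = object$mu)

#' @export
confint.drakefit <- function(object, parm = "mu", level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$conf.level)))
    warning("interval was computed at level ", object$conf.level,
            "; refit to change it")
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("mu", c("lower", "upper")))
  m
}

#' @export
summary.drakefit <- function(object, ...) {
  out <- unclass(object)
  class(out) <- "summary.drakefit"
  out
}

#' @export
print.summary.drakefit <- function(x, ...) {
  print.drakefit(structure(x, class = "drakefit"))
  cat(sprintf("  solver residual |mu ln(N mu) - f| = %.3g\n",
              abs(x$mu * log(x$n_population * x$mu) - x$f_median)))
  invisible(x)
}

#' Simulate new fluctuation assays from a fitted rate
#'
#' Draws `nsim` synthetic culture sets at the fitted mutation rate and the
#' observed population size, using the package's Luria-Delbrueck generator.
#'
#' @param object a [drakefit()] object.
#' @param nsim number of culture sets to simulate.
#' @param seed integer seed.
#' @param ... passed to [simulation_config()] (e.g. `n_cultures`).
#' @return a list of [culture_set()] objects (length `nsim`).
#' @export
simulate.drakefit <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i) {
    cfg <- simulation_config(mu = object$mu,
                             n_final = object$n_population,
                             n_cultures = object$n_cultures,
                             seed = substream(seed, i), ...)
    simulate_cultures(cfg)
  })
}

#' Fold change between two mutation rates
#'
#' @param mu_mutant,mu_reference rates per cell division; the reference must
#'   be positive.
#' @return the full-precision ratio, with the two-significant-figure value
#'   customarily reported attached as attribute `"reported"`.
#' @examples
#' fold_change(500e-8, 60e-8)   # reported 8.3
#' @export
fold_change <- function(mu_mutant, mu_reference) {
  if (any(mu_reference <= 0)) stop("reference rate must be > 0", call. = FALSE)
  r <- mu_mutant / mu_reference
  attr(r, "reported") <- signif2(r)
  r
}

#' Synergy (epistasis) index for a double mutant
#'
#' Rates are first expressed relative to the wild type; the index is the
#' relative double-mutant rate divided by the sum of the relative
#' single-mutant rates. An index of 1 is additivity; values well above 1
#' indicate a synergistic interaction (the two genes act in overlapping
#' pathways on the same replication errors).
#'
#' @param mu_wt,mu_a,mu_b,mu_ab positive rates per cell division for the
#'   wild type, each single mutant, and the double mutant.
#' @return an object of class `"synergy"` with components `rel_a`, `rel_b`,
#'   `rel_ab` and `index`.
#' @examples
#' synergy_index(1, 3, 5, 80)$index  # 10
#' @export
synergy_index <- function(mu_wt, mu_a, mu_b, mu_ab) {
  rates <- c(mu_wt, mu_a, mu_b, mu_ab)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all four rates must be positive", call. = FALSE)
  rel_a <- mu_a / mu_wt; rel_b <- mu_b / mu_wt; rel_ab <- mu_ab / mu_wt
  structure(list(rel_a = rel_a, rel_b = rel_b, rel_ab = rel_ab,
                 index = rel_ab / (rel_a + rel_b)),
            class = "synergy")
}

#' @export
print.synergy <- function(x, ...) {
  cat(sprintf("Synergy index: %.3g (relative rates a = %.3g, b = %.3g, ab = %.3g)\n",
              x$index, x$rel_a, x$rel_b, x$rel_ab))
  if (x$index > 1) cat("  index > 1: super-additive (synergistic) interaction\n")
  invisible(x)
}
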