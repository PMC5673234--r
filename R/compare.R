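#' Assemble a category-by-genotype contingency table
#'
#' @param ... [mutation_spectrum()] objects, a list of them, or a single
#'   numeric matrix (rows = categories, columns = genotypes).
#' @return integer matrix with category row names and genotype column names.
#' @export
as_contingency <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) &&
      !inherits(args[[1]], "mutation_spectrum") && !is.data.frame(args[[1]]))
    args <- args[[1]]
  if (length(args) == 1 && is.matrix(args[[1]])) {
    m <- args[[1]]
    storage.mode(m) <- "integer"
    return(m)
  }
  stopifnot(all(vapply(args, inherits, TRUE, "mutation_spectrum")))
  cats <- names(args[[1]]$counts)
  for (s in args)
    if (!identical(names(s$counts), cats))
      stop("spectra are over different category sets", call. = FALSE)
  m <- vapply(args, function(s) s$counts, integer(length(cats)))
  colnames(m) <- vapply(args, function(s) s$genotype, "")
  rownames(m) <- cats
  m
}

# Drop all-zero rows/columns; error if the table degenerates.
drop_zero_margins <- function(tab, require_cols = TRUE) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate table after dropping zero margins: need >= 2 rows and ",
         ">= 2 columns with positive totals", call. = FALSE)
  tab
}

# Pearson chi-square statistic, sum over cells of (O - E)^2 / E with
# E = row total x column total / grand total.
pearson_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' Asymptotic chi-square test of independence for mutation spectra
#'
#' Pearson chi-square without continuity correction on a category-by-
#' genotype table; all-zero rows and columns are dropped first, and the
#' degrees of freedom are (rows - 1)(columns - 1) of the reduced table.
#' The asymptotic chi-square p-value is used even when expected counts are
#' small (a warning notes this), which is the convention under which
#' published spectrum comparisons of this kind are computed.
#'
#' @param tab contingency matrix (see [as_contingency()]).
#' @return object of class `"spectra_chisq"`: list with `statistic`, `df`,
#'   `p` (full precision), `expected`, and `small_counts` (logical).
#' @examples
#' wt <- mutation_spectrum(c(7, 40, 1, 1, 1), "wild type")
#' ex <- mutation_spectrum(c(7, 40, 0, 3, 0), "exo1")
#' chisq_independence(as_contingency(wt, ex))   # p = 0.5578
#' @export
chisq_independence <- function(tab) {
  tab <- drop_zero_margins(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  small <- any(E < 5)
  if (small)
    warning("expected counts below 5; asymptotic p-value is approximate",
            call. = FALSE)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = E, small_counts = small),
            class = "spectra_chisq")
}

# Render a p-value the way comparison tables print it: 4 decimals,
# "< .0001" below 0.00005.
format_pvalue <- function(p) {
  ifelse(p < 5e-5, "< .0001", sprintf("%.4f", round(p, 4)))
}

#' @export
print.spectra_chisq <- function(x, ...) {
  cat(sprintf("Chi-square test of independence: X^2 = %.4g, df = %d, p = %s\n",
              x$statistic, x$df, format_pvalue(x$p)))
  if (x$small_counts)
    cat("  note: some expected counts < 5; asymptotic p is approximate\n")
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies a p-value by the number of comparisons, capping at 1. When
#' `digits` is given the p-value is first rounded to that many decimals,
#' matching the practice of adjusting the p-values as reported in a table.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of comparisons (>= 1).
#' @param digits optional rounding applied to `p` before adjustment.
#' @return adjusted p-value(s), never smaller than `p`.
#' @examples
#' bonferroni(0.0001, 7)   # 0.0007
#' @export
bonferroni <- function(p, m, digits = NULL) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (!is.null(digits)) p <- round(p, digits)
  pmin(1, m * p)
}

#' Monte-Carlo test of mutation-spectra homogeneity
#'
#' Computes the observed Pearson chi-square statistic on a category-by-
#' genotype table and assesses significance by simulation under the null of
#' homogeneous spectra: null tables are drawn with both margins fixed
#' (equivalent to randomly permuting the genotype label of each individual
#' mutation; the multivariate hypergeometric distribution conditioned on
#' the margins, generated by Patefield's algorithm). The p-value uses the
#' add-one estimator p = (1 + #\{simulated >= observed\}) / (1 + n_iter), so
#' it is never exactly zero and has resolution 1/n_iter; when no simulated
#' statistic reaches the observed one the result prints as "< 1/n_iter".
#' The empirical 95th percentile of the simulated statistics is reported as
#' the critical 5% value.
#'
#' @param tab contingency matrix; all column totals must be positive
#'   (all-zero rows are dropped).
#' @param n_iter number of Monte-Carlo iterations (>= 1000; default 1e5).
#' @param seed integer seed.
#' @return object of class `"mc_homogeneity"`: list with
#'   `statistic_observed`, `p_mc`, `n_exceed`, `critical_value_5pct`,
#'   `n_iter`, `seed`.
#' @export
mc_homogeneity <- function(tab, n_iter = 1e5, seed = 1L) {
  if (any(colSums(tab) == 0))
    stop("zero column total: every genotype needs at least one mutation",
         call. = FALSE)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate table: need >= 2 non-empty rows and 2 columns",
         call. = FALSE)
  as_count(n_iter, "n_iter", min = 1000)
  obs <- pearson_stat(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  E <- outer(rs, cs) / sum(tab)
  sims <- with_seed(seed, {
    nulls <- stats::r2dtable(n_iter, rs, cs)
    vapply(nulls, function(m) sum((m - E)^2 / E), 0)
  })
  n_exceed <- sum(sims >= obs - 1e-12)   # tolerance for ties at obs = 0
  structure(list(statistic_observed = obs,
                 p_mc = (1 + n_exceed) / (1 + n_iter),
                 n_exceed = n_exceed,
                 critical_value_5pct = unname(stats::quantile(sims, 0.95)),
                 n_iter = n_iter, seed = as.integer(seed)),
            class = "mc_homogeneity")
}

#' @export
print.mc_homogeneity <- function(x, ...) {
  p_txt <- if (x$n_exceed == 0) sprintf("< %g", 1 / x$n_iter)
           else format(signif(x$p_mc, 4))
  cat(sprintf("Monte-Carlo homogeneity test: X^2 = %.4g, P %s%s (n_iter = %g, seed = %d)\n",
              x$statistic_observed, if (x$n_exceed == 0) "" else "= ", p_txt,
              x$n_iter, x$seed))
  cat(sprintf("  critical 5%% value = %.3g\n", x$critical_value_5pct))
  invisible(x)
}

#' Pairwise comparison of mutation spectra
#'
#' Runs the chosen test on every unordered pair of spectra and, for the
#' asymptotic chi-square method, also on the full all-genotypes table
#' ("overall"). Bonferroni adjustment uses m = number of reported
#' comparisons — pairs plus the overall test when present (7 for four
#' genotypes under the chi-square method) — applied to the 4-decimal
#' reported p-values.
#'
#' @param spectra list of >= 2 [mutation_spectrum()] objects over the same
#'   categories.
#' @param method `"chisq"` (asymptotic, with overall test and Bonferroni)
#'   or `"mc"` (Monte-Carlo homogeneity on each pair).
#' @param m number of comparisons for the Bonferroni adjustment; default is
#'   the number of rows reported.
#' @param n_iter,seed Monte-Carlo settings (method `"mc"`).
#' @return data frame with one row per comparison: `comparison`,
#'   `statistic`, `df` (chisq only), `p`, `p_reported`, `p_adjusted`
#'   (chisq) or `p_mc`, `critical_5pct` (mc).
#' @examples
#' sp <- hmr_ura3_spectra()
#' pairwise_compare(sp, method = "chisq")
#' @export
pairwise_compare <- function(spectra, method = c("chisq", "mc"), m = NULL,
                             n_iter = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (length(spectra) < 2) stop("need at least two spectra", call. = FALSE)
  labs <- vapply(spectra, function(s) s$genotype, "")
  pairs <- utils::combn(length(spectra), 2)
  if (method == "chisq") {
    rows <- list()
    if (length(spectra) > 2) {
      overall <- suppressWarnings(chisq_independence(as_contingency(spectra)))
      rows[[1]] <- data.frame(comparison = "overall",
                              statistic = overall$statistic, df = overall$df,
                              p = overall$p, stringsAsFactors = FALSE)
    }
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      r <- suppressWarnings(
        chisq_independence(as_contingency(spectra[[a]], spectra[[b]])))
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste(labs[a], "vs", labs[b]),
        statistic = r$statistic, df = r$df, p = r$p, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(m)) m <- nrow(out)
    out$p_reported <- format_pvalue(out$p)
    out$p_adjusted <- bonferroni(out$p, m, digits = 4)
    out$m <- m
    out
  } else {
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      r <- mc_homogeneity(as_contingency(spectra[[a]], spectra[[b]]),
                          n_iter = n_iter, seed = substream(seed, j))
      data.frame(comparison = paste(labs[a], "vs", labs[b]),
                 statistic = r$statistic_observed, p_mc = r$p_mc,
                 critical_5pct = r$critical_value_5pct,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(m)) m <- nrow(out)
    out$p_adjusted <- bonferroni(out$p_mc, m)
    out$m <- m
    out
  }
}
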