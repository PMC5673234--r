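#' Partition a total mutation rate by spectrum category
#'
#' Splits a genotype's total mutation rate across mutation categories in
#' proportion to its spectrum counts: per-category rate = total rate x
#' count / n_total. A category with zero observed mutations gets the upper
#' bound obtained from one hypothetical mutation (total rate x 1 / n_total)
#' and is flagged as a bound; bounds are excluded when checking that the
#' partition conserves the total.
#'
#' Full precision is retained; printed output reports two significant
#' figures and renders bounds as "<value".
#'
#' @param total_rate total mutation rate per cell division (> 0).
#' @param spectrum a [mutation_spectrum()] with `n_total` > 0.
#' @return object of class `"rate_partition"`: list with `genotype`,
#'   `table` (data frame: category, count, rate, is_bound), `total_rate`,
#'   `n_total`.
#' @examples
#' sp <- mutation_spectrum(c(25, 17, 6, 1, 1), genotype = "msh2")
#' partition_rates(500e-8, sp)
#' @export
partition_rates <- function(total_rate, spectrum) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  if (!is.numeric(total_rate) || total_rate <= 0)
    stop("total_rate must be > 0", call. = FALSE)
  if (spectrum$n_total == 0)
    stop("spectrum has no mutations; cannot partition", call. = FALSE)
  counts <- spectrum$counts
  is_bound <- counts == 0
  eff_counts <- ifelse(is_bound, 1, counts)   # pseudo-count 1 for bounds
  rate <- total_rate * eff_counts / spectrum$n_total
  structure(list(
    genotype = spectrum$genotype,
    table = data.frame(category = names(counts),
                       count = as.integer(counts),
                       rate = rate, is_bound = is_bound,
                       row.names = NULL, stringsAsFactors = FALSE),
    total_rate = total_rate, n_total = spectrum$n_total
  ), class = "rate_partition")
}

#' @export
print.rate_partition <- function(x, ...) {
  cat(sprintf("Per-type mutation rates: %s (total %s, n = %d mutations)\n",
              x$genotype, fmt_rate(x$total_rate), x$n_total))
  shown <- x$table
  shown$rate <- mapply(fmt_rate, shown$rate, shown$is_bound)
  if (!is.null(shown$relative_rate))
    shown$relative_rate <- ifelse(is.na(shown$relative_rate), "NA",
                                  paste0(ifelse(shown$is_bound, "<", ""),
                                         signif2(shown$relative_rate)))
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Category-wise relative rates against a reference partition
#'
#' Divides each per-category rate by the matching category rate of a
#' reference genotype's partition (so the reference genotype has relative
#' rate 1 in every category). Ratios involving an upper-bound rate keep the
#' bound flag; a zero reference rate yields `NA` with a warning.
#'
#' @param partition,reference_partition [partition_rates()] objects over
#'   the same categories.
#' @return `partition` with a `relative_rate` column added to its table
#'   (full precision; printed at two significant figures).
#' @examples
#' wt <- partition_rates(60e-8, mutation_spectrum(c(7, 40, 1, 1, 1), "wt"))
#' m  <- partition_rates(500e-8, mutation_spectrum(c(25, 17, 6, 1, 1), "msh2"))
#' relative_rates(m, wt)
#' @export
relative_rates <- function(partition, reference_partition) {
  stopifnot(inherits(partition, "rate_partition"),
            inherits(reference_partition, "rate_partition"))
  if (!identical(partition$table$category, reference_partition$table$category))
    stop("partitions are over different category sets", call. = FALSE)
  ref <- reference_partition$table$rate
  rel <- partition$table$rate / ref
  if (any(ref <= 0)) {
    warning("zero reference rate: relative rate undefined for some categories")
    rel[ref <= 0] <- NA_real_
  }
  partition$table$relative_rate <- rel
  partition$total_relative <- partition$total_rate / reference_partition$total_rate
  partition
}

#' Mismatch-repair efficiency from rates in proficient and deficient strains
#'
#' Repair efficiency (%) = 100 - 100 x (rate in the repair-proficient
#' strain / rate in the repair-deficient strain): the percentage of
#' replication errors of that type that the repair pathway corrects.
#' Conventionally reported rounded to the nearest integer; the returned
#' value is full precision with the rounded figure attached as attribute
#' `"reported"`.
#'
#' @param mu_proficient,mu_deficient per-category (or total) mutation rates
#'   in the repair-proficient and repair-deficient strains; the deficient
#'   rate must be positive. Vectorised.
#' @return percent efficiency; negative (with a warning) if the proficient
#'   strain mutates faster than the deficient one.
#' @examples
#' repair_efficiency(48e-8, 170e-8)   # ~72%
#' @export
repair_efficiency <- function(mu_proficient, mu_deficient) {
  if (any(mu_deficient <= 0))
    stop("repair-deficient rate must be > 0", call. = FALSE)
  if (any(mu_proficient > mu_deficient))
    warning("repair-proficient rate exceeds repair-deficient rate; ",
            "negative efficiency")
  eff <- 100 - 100 * mu_proficient / mu_deficient
  attr(eff, "reported") <- round(eff)
  eff
}
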