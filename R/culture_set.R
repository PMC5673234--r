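#' Construct a set of fluctuation-assay cultures
#'
#' A culture set holds the per-culture colony counts of one fluctuation
#' assay for one genotype and reporter locus: the selective-plate count
#' (apparent resistant colonies), the permissive-plate count (total viable
#' cells, after dilution), the dilution factors applied before plating, and
#' the number of selective colonies that failed phenotype verification
#' (e.g. FOA-resistant colonies that still grew without uracil and are
#' therefore silenced false positives, not reporter mutants).
#'
#' Dilution factors are the census multipliers: a `selective_dilution` of
#' 100 means one plated colony represents 100 cells in the culture.
#'
#' @param selective_count integer vector, colonies on selective plates.
#' @param selective_dilution positive numeric, dilution factor(s) for the
#'   selective plating (recycled across cultures).
#' @param permissive_count integer vector, colonies on permissive plates.
#' @param permissive_dilution positive numeric, dilution factor(s) for the
#'   permissive plating.
#' @param verified_silenced_count integer vector, selective colonies that
#'   were verification-positive and must be excluded. Default 0.
#' @param genotype,locus labels carried into downstream results.
#' @return A data frame of class `"culture_set"` with one row per culture
#'   and columns `culture_id`, `selective_count`, `selective_dilution`,
#'   `permissive_count`, `permissive_dilution`, `verified_silenced_count`.
#' @examples
#' cs <- culture_set(selective_count = c(3, 0, 12), selective_dilution = 1,
#'                   permissive_count = c(110, 95, 102),
#'                   permissive_dilution = 1e6, genotype = "wild type")
#' corrected_mutant_counts(cs)
#' @export
culture_set <- function(selective_count, selective_dilution,
                        permissive_count, permissive_dilution,
                        verified_silenced_count = 0,
                        genotype = "unknown", locus = "unknown") {
  n <- length(selective_count)
  df <- data.frame(
    culture_id = seq_len(n),
    selective_count = as.numeric(selective_count),
    selective_dilution = rep_len(as.numeric(selective_dilution), n),
    permissive_count = rep_len(as.numeric(permissive_count), n),
    permissive_dilution = rep_len(as.numeric(permissive_dilution), n),
    verified_silenced_count = rep_len(as.numeric(verified_silenced_count), n)
  )
  validate_culture_set(df)
  attr(df, "genotype") <- genotype
  attr(df, "locus") <- locus
  class(df) <- c("culture_set", "data.frame")
  df
}

validate_culture_set <- function(df, rows = NULL) {
  need <- c("selective_count", "selective_dilution", "permissive_count",
            "permissive_dilution", "verified_silenced_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("culture set is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(rows)) rows <- seq_len(nrow(df))
  bad_row <- function(ok, what) {
    if (any(!ok))
      stop(sprintf("culture set row %s: %s",
                   paste(rows[!ok], collapse = ", "), what), call. = FALSE)
  }
  bad_row(df$selective_count >= 0 & df$permissive_count >= 0 &
            df$verified_silenced_count >= 0, "negative count")
  bad_row(df$selective_dilution > 0 & df$permissive_dilution > 0,
          "dilution factor must be > 0")
  bad_row(df$verified_silenced_count <= df$selective_count,
          "verified_silenced_count exceeds selective_count")
  invisible(df)
}

#' @export
print.culture_set <- function(x, ...) {
  cat(sprintf("Fluctuation-assay culture set: %d cultures (%s at %s)\n",
              nrow(x), attr(x, "genotype"), attr(x, "locus")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Corrected per-culture mutant censuses
#'
#' Subtracts verification-positive (silenced false positive) colonies from
#' each selective-plate count and scales by the selective dilution factor,
#' giving the estimated number of true mutant cells in each culture.
#'
#' @param cs a [culture_set()].
#' @return numeric vector, one corrected mutant census per culture.
#' @export
corrected_mutant_counts <- function(cs) {
  validate_culture_set(cs)
  (cs$selective_count - cs$verified_silenced_count) * cs$selective_dilution
}

#' Per-culture total population censuses
#'
#' @param cs a [culture_set()].
#' @return numeric vector of permissive_count x permissive_dilution.
#' @export
population_sizes <- function(cs) {
  validate_culture_set(cs)
  cs$permissive_count * cs$permissive_dilution
}

#' Median mutant frequency across cultures
#'
#' The mutant frequency of a culture is its corrected mutant census divided
#' by its total population census; the estimator uses the median across
#' cultures (for an even number of cultures, the mean of the two central
#' order statistics).
#'
#' @param mutants numeric vector of corrected mutant censuses.
#' @param populations numeric vector of population censuses (all > 0).
#' @return the median mutant frequency, a dimensionless number.
#' @export
median_mutant_frequency <- function(mutants, populations) {
  if (length(mutants) < 1L) stop("need at least one culture", call. = FALSE)
  if (length(mutants) != length(populations))
    stop("mutants and populations differ in length", call. = FALSE)
  if (any(populations <= 0))
    stop("population census must be positive for every culture", call. = FALSE)
  stats::median(mutants / populations)
}
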