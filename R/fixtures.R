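#' Packaged ura3 mutation spectra at the heterochromatic hmr reporter
#'
#' Published spectra of 50 independent ura3 mutations each, recovered at a
#' heterochromatically silenced hmr::URA3 reporter in wild-type, msh2,
#' msh2 exo1 and exo1 budding-yeast strains. Shipped as a plain-text
#' fixture so the comparison and partitioning examples run offline.
#'
#' @return named list of four [mutation_spectrum()] objects.
#' @export
hmr_ura3_spectra <- function() {
  path <- system.file("extdata", "hmr_ura3_spectra.tsv", package = "flucspec")
  tab <- utils::read.delim(path, check.names = FALSE)
  cats <- tab$category
  out <- lapply(names(tab)[-1], function(g)
    mutation_spectrum(stats::setNames(as.integer(tab[[g]]), cats), genotype = g))
  stats::setNames(out, names(tab)[-1])
}

#' Packaged total mutation rates matching [hmr_ura3_spectra()]
#'
#' Total spontaneous reporter-loss rates (mutations per cell division) for
#' the wild-type and msh2 strains whose spectra are in
#' [hmr_ura3_spectra()], as published alongside them.
#'
#' @return data frame with columns `genotype`, `total_rate`, `n_mutations`.
#' @export
hmr_ura3_total_rates <- function() {
  path <- system.file("extdata", "hmr_ura3_total_rates.tsv", package = "flucspec")
  utils::read.delim(path, check.names = FALSE)
}
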