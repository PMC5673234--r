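#' Configuration for the synthetic fluctuation-assay generator
#'
#' Defaults describe a typical yeast reporter-loss assay: each culture is
#' inoculated with a single colony (~1.6 x 10^6 cells) and grows by six
#' synchronous doublings to exactly 10^8 cells, with a per-division
#' reporter-loss rate of 5e-8, the whole culture plated on selective
#' medium, a 10^6-fold dilution on permissive medium, and 30% silenced
#' false positives among apparent resistant colonies (the assay's
#' verification step identifies and excludes these).
#'
#' @param mu true mutation rate per cell division.
#' @param n_initial cells at inoculation.
#' @param n_final target cells at saturation; growth is deterministic
#'   synchronous doubling, so the realised population is the largest
#'   `n_initial * 2^G <= n_final` with `G >= 1`.
#' @param n_cultures number of parallel cultures.
#' @param dilution_selective,dilution_permissive census multipliers per
#'   plated colony (>= 1); plating is binomial thinning with probability
#'   `1/dilution`.
#' @param silencing_fraction fraction governing the silenced false-positive
#'   draw (see [simulate_cultures()]), in \[0, 1\].
#' @param spectrum_proportions probability of each mutation category
#'   (must sum to 1); default is a substitution-dominated wild-type-like
#'   spectrum over the five standard categories.
#' @param seed integer seed; fixing it makes every output byte-identical.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(mu = 5e-8,
                              n_initial = 1562500,
                              n_final = 1e8,
                              n_cultures = 18,
                              dilution_selective = 1,
                              dilution_permissive = 1e6,
                              silencing_fraction = 0.3,
                              spectrum_proportions = c(
                                "1-bp deletion" = 7, "base substitution" = 40,
                                "1-bp insertion" = 1, "complex" = 1,
                                "other" = 1) / 50,
                              seed = 1L) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("`mu` must be a single non-negative number", call. = FALSE)
  as_count(n_initial, "n_initial", min = 1)
  as_count(n_cultures, "n_cultures", min = 1)
  if (!(n_initial < n_final))
    stop("need 0 < n_initial < n_final", call. = FALSE)
  if (n_final / n_initial < 2)
    stop("n_final/n_initial must allow at least one doubling", call. = FALSE)
  if (dilution_selective < 1 || dilution_permissive < 1)
    stop("dilution factors must be >= 1", call. = FALSE)
  as_prob(silencing_fraction, "silencing_fraction")
  if (abs(sum(spectrum_proportions) - 1) > 1e-12)
    stop("spectrum_proportions must sum to 1", call. = FALSE)
  if (any(spectrum_proportions < 0))
    stop("spectrum_proportions must be non-negative", call. = FALSE)
  as_count(seed, "seed")
  structure(list(mu = mu, n_initial = n_initial, n_final = n_final,
                 n_cultures = n_cultures,
                 dilution_selective = dilution_selective,
                 dilution_permissive = dilution_permissive,
                 silencing_fraction = silencing_fraction,
                 spectrum_proportions = spectrum_proportions,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Final mutant-cell censuses for `n` cultures under discrete-generation
# Luria-Delbrueck growth: in generation g all n_initial*2^(g-1) cells divide,
# each division mutating with probability mu; a mutant born in generation g
# doubles deterministically to 2^(G-g) cells by saturation.
ld_mutant_census <- function(n, mu, n_initial, G) {
  M <- numeric(n)
  for (g in seq_len(G)) {
    m_g <- stats::rpois(n, mu * n_initial * 2^(g - 1))
    M <- M + m_g * 2^(G - g)
  }
  M
}

# Binomial plating at probability 1/dilution; falls back to a Poisson draw
# when a jackpot census exceeds the binomial size limit.
plate <- function(census, dilution) {
  if (dilution == 1) return(census)
  big <- census > 2^31 - 1
  out <- numeric(length(census))
  if (any(!big))
    out[!big] <- stats::rbinom(sum(!big), census[!big], 1 / dilution)
  if (any(big))
    out[big] <- stats::rpois(sum(big), census[big] / dilution)
  out
}

#' Simulate fluctuation-assay colony counts
#'
#' Each culture grows by deterministic synchronous doubling from
#' `n_initial` over \eqn{G = \lfloor \log_2(n_{final}/n_{initial}) \rfloor}
#' generations; new mutations per generation are Poisson in the number of
#' divisions, and each mutant founds a lineage that doubles thereafter
#' (the discrete-generation Luria-Delbrueck model — no back mutation, no
#' mutant fitness cost, 100% plating efficiency apart from the explicit
#' dilutions). Plating is binomial thinning at `1/dilution`.
#'
#' Silenced false positives — apparent resistant colonies that still carry a
#' functional reporter — are generated independently of the true mutants:
#' a second, independent draw of plated apparent mutants is taken and a
#' binomial fraction `silencing_fraction` of it is added to the selective
#' count and recorded as `verified_silenced_count`, mimicking colonies that
#' the verification step will identify and exclude.
#'
#' @param config a [simulation_config()].
#' @return a [culture_set()] with attributes `mu_true` and
#'   `n_population_true` (the realised saturation census).
#' @examples
#' cs <- simulate_cultures(simulation_config(n_cultures = 6, seed = 7))
#' drakefit(cs)
#' @export
simulate_cultures <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  G <- floor(log2(config$n_final / config$n_initial))
  if (G < 1)
    stop("n_final/n_initial not expressible as >= 1 doublings", call. = FALSE)
  N_real <- config$n_initial * 2^G
  n <- config$n_cultures
  cs <- with_seed(config$seed, {
    true_census <- ld_mutant_census(n, config$mu, config$n_initial, G)
    true_plated <- plate(true_census, config$dilution_selective)
    apparent2 <- plate(ld_mutant_census(n, config$mu, config$n_initial, G),
                       config$dilution_selective)
    silenced <- stats::rbinom(n, apparent2, config$silencing_fraction)
    permissive <- stats::rpois(n, N_real / config$dilution_permissive)
    culture_set(selective_count = true_plated + silenced,
                selective_dilution = config$dilution_selective,
                permissive_count = permissive,
                permissive_dilution = config$dilution_permissive,
                verified_silenced_count = silenced,
                genotype = "synthetic", locus = "synthetic")
  })
  attr(cs, "mu_true") <- config$mu
  attr(cs, "n_population_true") <- N_real
  cs
}

#' Simulate a mutation spectrum
#'
#' Multinomial draw of `n` independent mutations over the categories of
#' `proportions`.
#'
#' @param proportions named per-category probabilities summing to 1.
#' @param n number of mutations (>= 0).
#' @param seed integer seed.
#' @param genotype label for the resulting spectrum.
#' @return a [mutation_spectrum()] whose counts sum to `n`.
#' @export
simulate_spectrum <- function(proportions, n, seed = 1L, genotype = "synthetic") {
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must sum to 1", call. = FALSE)
  as_count(n, "n")
  counts <- if (n == 0) rep(0L, length(proportions))
            else with_seed(seed, as.integer(stats::rmultinom(1, n, proportions)))
  names(counts) <- names(proportions)
  mutation_spectrum(counts, genotype = genotype)
}
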