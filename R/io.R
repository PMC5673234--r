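# Tabular I/O: tab-delimited UTF-8 with header row and '.' decimals
# throughout, so every file is diff-able and spreadsheet-compatible.

#' Read a fluctuation-assay culture table
#'
#' Expects a header with columns `culture_id`, `selective_count`,
#' `selective_dilution`, `permissive_count`, `permissive_dilution`,
#' `verified_silenced_count`. Validation failures name the offending row.
#'
#' @param path TSV file path.
#' @param genotype,locus labels attached to the culture set.
#' @return a [culture_set()].
#' @export
read_culture_tsv <- function(path, genotype = "unknown", locus = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE)
  validate_culture_set(df)
  cs <- culture_set(df$selective_count, df$selective_dilution,
                    df$permissive_count, df$permissive_dilution,
                    df$verified_silenced_count,
                    genotype = genotype, locus = locus)
  if ("culture_id" %in% names(df)) cs$culture_id <- df$culture_id
  cs
}

#' Write a culture set as TSV
#' @param cs a [culture_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_culture_tsv <- function(cs, path) {
  utils::write.table(as.data.frame(cs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mutation-call table
#'
#' Columns: `isolate_id`, `position`, `ref_allele`, `alt_allele`; empty
#' `ref_allele` denotes an insertion, empty `alt_allele` a deletion.
#'
#' @param path TSV file path.
#' @return data frame ready for [classify_mutations()].
#' @export
read_mutation_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(ref_allele = "character",
                                         alt_allele = "character"),
                          na.strings = NULL)
  need <- c("isolate_id", "position", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_mutation_tsv
#' @param records mutation-record data frame.
#' @export
write_mutation_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a single-record reference FASTA
#'
#' @param path FASTA file with exactly one record, alphabet ACGTN.
#' @return uppercase sequence string. Records containing N draw a warning
#'   (run annotation is undefined across Ns).
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  if (length(set) > 1)
    stop("expected a single-record FASTA, found ", length(set), " records",
         call. = FALSE)
  s <- toupper(as.character(set[[1]]))
  if (nchar(s) == 0) stop("empty sequence in FASTA file", call. = FALSE)
  if (!grepl("^[ACGTN]+$", s))
    stop("reference contains characters outside ACGTN", call. = FALSE)
  if (grepl("N", s, fixed = TRUE))
    warning("reference contains N bases; run annotation near them is unreliable")
  s
}

#' Write a reference sequence as FASTA
#' @param sequence DNA string or a `synthetic_reference`.
#' @param path output file path.
#' @param name record name.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(sequence, path, name = "reference") {
  if (inherits(sequence, "synthetic_reference")) sequence <- sequence$sequence
  set <- Biostrings::DNAStringSet(sequence)
  names(set) <- name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Spectrum TSV round-trip
#'
#' A spectrum file has columns `category` and `count`.
#'
#' @param spectrum a [mutation_spectrum()].
#' @param path file path.
#' @param genotype label attached on read.
#' @return the written path / the read [mutation_spectrum()].
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(
    data.frame(category = names(spectrum$counts), count = spectrum$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path, genotype = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE)
  mutation_spectrum(stats::setNames(as.integer(df$count), df$category),
                    genotype = genotype)
}

#' Read a contingency table (categories x genotypes) from TSV
#'
#' First column holds category labels; remaining columns are genotype
#' counts.
#'
#' @param path file path.
#' @return integer matrix for [chisq_independence()] / [mc_homogeneity()].
#' @export
read_contingency_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a rate partition as TSV
#'
#' Upper bounds are serialised as a numeric `rate` plus a logical
#' `is_bound` column (machine-readable); pretty "<rate" rendering is left
#' to the print method.
#'
#' @param partition a [partition_rates()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(partition$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise a Drake fit as JSON
#'
#' @param fit a [drakefit()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rate_json <- function(fit, path) {
  jsonlite::write_json(
    list(genotype = fit$genotype, locus = fit$locus, mu = fit$mu,
         ci_low = fit$ci_low, ci_high = fit$ci_high,
         f_median = fit$f_median, n_population = fit$n_population,
         n_cultures = fit$n_cultures, conf_level = fit$conf.level,
         is_upper_bound = fit$is_upper_bound),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
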