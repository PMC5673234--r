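#' Standard mutation-spectrum categories
#'
#' The five categories used throughout: 1-bp deletions, base substitutions,
#' 1-bp insertions, complex mutations (>= 2 clustered changes arising as one
#' event in one isolate) and other mutations (any single event of length
#' >= 2, e.g. multi-bp indels or duplications).
#'
#' @return character vector of category names, in conventional table order.
#' @export
mutation_categories <- function() {
  c("1-bp deletion", "base substitution", "1-bp insertion", "complex", "other")
}

#' Classify mutation calls against a reference ORF
#'
#' Single-base substitutions, 1-bp deletions and 1-bp insertions are
#' classified by allele lengths. Two or more events in the same isolate
#' lying within `complex_window` bases of one another (by chaining) are
#' jointly classified as one complex mutation; a `complex_cluster` id is
#' attached so that spectrum tallies can count each cluster once. Any
#' remaining single event of length >= 2 is "other".
#'
#' Conventions: coordinates are 1-based on the plus strand of the reference
#' ORF; a deletion has an empty `alt_allele`, an insertion an empty
#' `ref_allele` (the inserted bases sit immediately before `position`).
#'
#' @param records data frame with columns `isolate_id`, `position`,
#'   `ref_allele`, `alt_allele`.
#' @param ref_seq reference ORF sequence (string) used to verify that each
#'   non-empty `ref_allele` matches the reference.
#' @param complex_window maximum gap (bases) joining events of one isolate
#'   into a complex cluster; default 10.
#' @return `records` with added columns `category` and `complex_cluster`
#'   (NA for non-complex records).
#' @export
classify_mutations <- function(records, ref_seq, complex_window = 10) {
  need <- c("isolate_id", "position", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ref_seq <- toupper(ref_seq)
  records$ref_allele <- toupper(as.character(records$ref_allele))
  records$alt_allele <- toupper(as.character(records$alt_allele))
  n <- nrow(records)
  for (i in seq_len(n)) {
    ra <- records$ref_allele[i]; aa <- records$alt_allele[i]
    if (nchar(ra) == 0 && nchar(aa) == 0)
      stop("row ", i, ": ref and alt alleles both empty", call. = FALSE)
    if (nchar(ra) > 0) {
      p <- records$position[i]
      found <- substr(ref_seq, p, p + nchar(ra) - 1L)
      if (!identical(found, ra))
        stop(sprintf("row %d: ref_allele '%s' does not match reference '%s' at position %d",
                     i, ra, found, p), call. = FALSE)
    }
  }
  len_ref <- nchar(records$ref_allele)
  len_alt <- nchar(records$alt_allele)
  category <- ifelse(len_ref == 1 & len_alt == 1, "base substitution",
              ifelse(len_ref == 1 & len_alt == 0, "1-bp deletion",
              ifelse(len_ref == 0 & len_alt == 1, "1-bp insertion", "other")))
  cluster <- rep(NA_character_, n)
  for (iso in unique(records$isolate_id)) {
    idx <- which(records$isolate_id == iso)
    if (length(idx) < 2) next
    ord <- idx[order(records$position[idx])]
    pos <- records$position[ord]
    grp <- cumsum(c(1, diff(pos) > complex_window))
    for (g in unique(grp)) {
      members <- ord[grp == g]
      if (length(members) >= 2) {
        category[members] <- "complex"
        cluster[members] <- paste0(iso, ":", g)
      }
    }
  }
  records$category <- category
  records$complex_cluster <- cluster
  records
}

#' Classify a single mutation call
#'
#' Scalar convenience wrapper around [classify_mutations()] for one event,
#' optionally given the positions of the isolate's other events.
#'
#' @param ref_seq reference sequence.
#' @param position 1-based position.
#' @param ref_allele,alt_allele alleles (one may be empty).
#' @param neighbor_positions positions of other events in the same isolate.
#' @param complex_window clustering window in bases.
#' @return the category string.
#' @export
classify_mutation <- function(ref_seq, position, ref_allele, alt_allele,
                              neighbor_positions = integer(), complex_window = 10) {
  df <- data.frame(isolate_id = "i", position = position,
                   ref_allele = ref_allele, alt_allele = alt_allele,
                   stringsAsFactors = FALSE)
  if (length(neighbor_positions)) {
    nb <- data.frame(isolate_id = "i", position = neighbor_positions,
                     ref_allele = "N", alt_allele = "N",
                     stringsAsFactors = FALSE)
    # neighbours only matter through their positions; skip ref checking
    all <- rbind(df, nb)
    len_gap <- complex_window
    pos <- sort(all$position)
    grp <- cumsum(c(1, diff(pos) > len_gap))
    mygrp <- grp[match(position, pos)]
    if (sum(grp == mygrp) >= 2) return("complex")
  }
  classify_mutations(df, ref_seq, complex_window)$category
}

#' Mononucleotide-run context of a mutation
#'
#' 1-bp indels are first left-normalised — shifted to the leftmost position
#' at which the same deletion/insertion produces the same derived sequence,
#' i.e. to the start of the run of the deleted/inserted base — and the run
#' length is that of the maximal run of that base containing the normalised
#' site. Substitutions (and other events) get the length of the maximal run
#' of the reference base at their site. A site in no run has run length 1.
#'
#' @param ref_seq reference sequence (string).
#' @param position 1-based position (for insertions, the base before which
#'   the new base is inserted).
#' @param ref_allele,alt_allele alleles as in [classify_mutations()].
#' @return list with `run_length` and the left-normalised `position`.
#' @examples
#' annotate_run_context("CAAAAG", 4, "A", "")  # run_length 4, position 2
#' @export
annotate_run_context <- function(ref_seq, position, ref_allele, alt_allele) {
  ref_seq <- toupper(ref_seq)
  bases <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  L <- length(bases)
  if (position < 1 || position > L + 1)
    stop("position outside reference", call. = FALSE)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  run_of <- function(b, p) {
    # length of maximal run of base b containing position p (0 if absent)
    if (p > L || bases[p] != b) return(0L)
    lo <- p; hi <- p
    while (lo > 1 && bases[lo - 1] == b) lo <- lo - 1
    while (hi < L && bases[hi + 1] == b) hi <- hi + 1
    as.integer(hi - lo + 1)
  }
  is_del <- nchar(ref_allele) == 1 && nchar(alt_allele) == 0
  is_ins <- nchar(ref_allele) == 0 && nchar(alt_allele) == 1
  if (is_del || is_ins) {
    b <- if (is_del) ref_allele else alt_allele
    p <- as.integer(position)
    while (p > 1 && bases[p - 1] == b) p <- p - 1L   # left-normalise
    rl <- run_of(b, p)
    list(run_length = max(1L, rl), position = p)
  } else {
    list(run_length = max(1L, run_of(bases[position], as.integer(position))),
         position = as.integer(position))
  }
}

# Vectorised run annotation over a classified record table.
annotate_records <- function(records, ref_seq) {
  ann <- lapply(seq_len(nrow(records)), function(i)
    annotate_run_context(ref_seq, records$position[i],
                         records$ref_allele[i], records$alt_allele[i]))
  records$run_length <- vapply(ann, `[[`, integer(1), "run_length")
  records$position_normalized <- vapply(ann, `[[`, integer(1), "position")
  records
}

#' Build a mutation spectrum
#'
#' Either tabulates a classified record table (a complex cluster counts as
#' one spectrum entry per isolate, since clustered changes arise as a
#' single event) or wraps a vector of per-category counts.
#'
#' @param x a data frame from [classify_mutations()] (columns `category`,
#'   `isolate_id`, optionally `complex_cluster`, `run_length`), or a named
#'   non-negative count vector over [mutation_categories()].
#' @param genotype label.
#' @param categories category universe (default [mutation_categories()]).
#' @return object of class `"mutation_spectrum"`: list with `genotype`,
#'   `counts` (named integers), `n_total`, and `records` (the classified
#'   table, or NULL when built from counts).
#' @export
mutation_spectrum <- function(x, genotype = "unknown",
                              categories = NULL) {
  if (is.data.frame(x)) {
    if (is.null(categories)) categories <- mutation_categories()
    if (!"category" %in% names(x))
      stop("record table lacks a `category` column; run classify_mutations()",
           call. = FALSE)
    ncx <- x[is.na(x$complex_cluster) | !duplicated(x$complex_cluster), , drop = FALSE]
    counts <- table(factor(ncx$category, levels = categories))
    counts <- stats::setNames(as.integer(counts), categories)
    records <- x
  } else {
    counts <- x
    if (is.null(names(counts))) {
      if (is.null(categories)) categories <- mutation_categories()
      if (length(counts) != length(categories))
        stop("unnamed counts must match the category universe in length",
             call. = FALSE)
      names(counts) <- categories
    }
    if (any(counts < 0) || any(counts != trunc(counts)))
      stop("counts must be non-negative integers", call. = FALSE)
    counts <- stats::setNames(as.integer(counts), names(counts))
    records <- NULL
  }
  structure(list(genotype = genotype, counts = counts,
                 n_total = sum(counts), records = records),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("Mutation spectrum: %s (n = %d)\n", x$genotype, x$n_total))
  print(x$counts)
  invisible(x)
}

#' Fraction of a category's mutations inside mononucleotide runs
#'
#' @param spectrum a [mutation_spectrum()] whose records carry `run_length`
#'   annotations (see [classify_mutations()] and [annotate_run_context()]).
#' @param category category of interest, default `"1-bp deletion"`.
#' @param min_run minimum run length counted as "within a run", default 3.
#' @return fraction in \[0, 1\]; `NA` (with a warning) when the spectrum has
#'   no records of the category.
#' @export
fraction_in_runs <- function(spectrum, category = "1-bp deletion", min_run = 3) {
  recs <- spectrum$records
  if (is.null(recs) || !"run_length" %in% names(recs))
    stop("spectrum has no run-annotated records", call. = FALSE)
  sel <- recs$category == category
  if (!any(sel)) {
    warning("no records of category '", category, "'; fraction undefined")
    return(NA_real_)
  }
  mean(recs$run_length[sel] >= min_run)
}
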