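#' Scan a DNA sequence for maximal mononucleotide runs
#'
#' @param sequence a single DNA string (A/C/G/T).
#' @param min_length shortest run to report (default 2).
#' @return a data frame with columns `start` (1-based), `length`, `base`,
#'   one row per maximal run of `min_length` or more identical bases.
#' @examples
#' scan_runs("CAAAAGTT")
#' @export
scan_runs <- function(sequence, min_length = 2) {
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  r <- rle(bases)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_length
  data.frame(start = start[keep], length = r$lengths[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' Generate a synthetic reference ORF with embedded mononucleotide runs
#'
#' Builds a random (or alternating-base) sequence of the requested length and
#' embeds the requested homopolymer runs at non-overlapping random positions,
#' guarding each run with a different flanking base so the embedded length is
#' exact. The run index returned is obtained by re-scanning the assembled
#' sequence, so it is consistent with the sequence by construction and lists
#' every maximal run of length >= 2.
#'
#' This reference is synthetic plumbing: a stand-in for a real reporter open
#' reading frame when exercising the classification and run-context code.
#'
#' @param length total sequence length in bases.
#' @param runs list of `c(base, run_length)` pairs to embed, e.g.
#'   `list(c("A", 5))`.
#' @param seed integer seed.
#' @param fill `"random"` (default) or `"alternating"` background; the
#'   alternating fill contains no run of length >= 2 outside embedded runs.
#' @return an object of class `"synthetic_reference"`: list with `sequence`
#'   (string) and `run_index` (data frame as from [scan_runs()]).
#' @export
generate_reference <- function(length, runs = list(), seed = 1L,
                               fill = c("random", "alternating")) {
  fill <- match.arg(fill)
  as_count(length, "length", min = 1)
  need <- sum(vapply(runs, function(r) as.numeric(r[2]), 0) + 2)
  if (length(runs) && need > length)
    stop("embedded runs (with guard bases) do not fit within `length`",
         call. = FALSE)
  with_seed(seed, {
    alphabet <- c("A", "C", "G", "T")
    bases <- if (fill == "random") sample(alphabet, length, replace = TRUE)
             else rep_len(c("A", "C"), length)
    occupied <- rep(FALSE, length)
    for (r in runs) {
      b <- toupper(as.character(r[1])); len <- as.integer(r[2])
      if (!b %in% alphabet) stop("run base must be one of A/C/G/T", call. = FALSE)
      # place [guard, run, guard]; retry random starts, then fail
      placed <- FALSE
      for (try in seq_len(1000)) {
        s <- sample.int(length - len - 1L, 1L) + 1L   # run occupies s..s+len-1
        span <- (s - 1L):(s + len)                    # including guards
        if (any(occupied[span])) next
        other <- setdiff(alphabet, b)
        bases[s - 1L] <- sample(other, 1L)
        bases[s:(s + len - 1L)] <- b
        bases[s + len] <- sample(other, 1L)
        occupied[span] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place run ", b, "x", len,
             " without overlapping a previous placement", call. = FALSE)
    }
    seq_str <- paste(bases, collapse = "")
    structure(list(sequence = seq_str, run_index = scan_runs(seq_str)),
              class = "synthetic_reference")
  })
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat(sprintf("Synthetic reference: %d nt, %d mononucleotide runs (length >= 2)\n",
              nchar(x$sequence), nrow(x$run_index)))
  invisible(x)
}
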