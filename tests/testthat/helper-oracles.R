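# Independent oracles used across the suite. These deliberately re-derive
# quantities by a different route than the package implementation.

# Textbook Pearson chi-square by an explicit double loop.
naive_chisq_stat <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
  st <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      E <- rs[i] * cs[j] / tot
      st <- st + (tab[i, j] - E)^2 / E
    }
  unname(st)
}

# Maximal mononucleotide runs via regex, independent of rle().
regex_scan_runs <- function(seq_str, min_length = 2) {
  m <- gregexpr("(A+|C+|G+|T+)", seq_str)[[1]]
  start <- as.integer(m)
  len <- attr(m, "match.length")
  keep <- len >= min_length
  data.frame(start = start[keep], length = len[keep],
             base = substring(seq_str, start[keep], start[keep]),
             stringsAsFactors = FALSE)
}

# A small record table builder.
mut_records <- function(isolate_id, position, ref_allele, alt_allele) {
  data.frame(isolate_id = isolate_id, position = position,
             ref_allele = ref_allele, alt_allele = alt_allele,
             stringsAsFactors = FALSE)
}
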