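ref20 <- "ACGTACGTGGGACCATGCAT"

test_that("single events classify by allele lengths", {
  expect_equal(classify_mutation(ref20, 2, "C", "T"), "base substitution")
  expect_equal(classify_mutation(ref20, 3, "G", ""), "1-bp deletion")
  expect_equal(classify_mutation(ref20, 5, "", "A"), "1-bp insertion")
  expect_equal(classify_mutation(ref20, 9, "GGG", "G"), "other")   # 2-bp deletion
  expect_equal(classify_mutation(ref20, 5, "", "AC"), "other")     # 2-bp insertion
  expect_equal(classify_mutation(ref20, 13, "", "CCATGCATCCATG"), "other")
  expect_error(classify_mutation(ref20, 2, "G", "T"), "does not match")
})

test_that("clustered events in one isolate are complex, per an exhaustive pairing oracle", {
  window <- 10
  for (p1 in seq(2, 28, by = 3)) {
    for (p2 in seq(2, 28, by = 3)) {
      if (p1 >= p2) next
      ref <- paste(rep("ACGT", 8), collapse = "")
      recs <- mut_records("iso1", c(p1, p2),
                          substring(ref, c(p1, p2), c(p1, p2)), c("N", "N"))
      recs$alt_allele <- ifelse(recs$ref_allele == "A", "G", "A")
      out <- classify_mutations(recs, ref, complex_window = window)
      expected <- if (p2 - p1 <= window) c("complex", "complex")
                  else rep("base substitution", 2)
      expect_equal(out$category, expected,
                   label = sprintf("positions %d,%d", p1, p2))
    }
  }
})

test_that("classification is invariant to record order and isolate boundaries", {
  ref <- paste(rep("ACGT", 8), collapse = "")
  recs <- mut_records(c("a", "a", "b"), c(5, 12, 14),
                      c("A", "T", "C"), c("G", "G", "T"))
  out1 <- classify_mutations(recs, ref)
  out2 <- classify_mutations(recs[c(3, 1, 2), ], ref)
  expect_equal(out1$category[order(recs$position)],
               out2$category[order(recs$position[c(3, 1, 2)])])
  # events 5 and 12 (same isolate, 7 apart) are complex; 14 (other isolate) is not
  expect_equal(out1$category, c("complex", "complex", "base substitution"))
})

test_that("run context is placement invariant for indels in runs up to length 8", {
  for (L in 2:8) {
    ref <- paste0("CT", strrep("A", L), "GT")
    # delete any A of the run: identical run length and normalised position
    for (p in 3:(2 + L)) {
      ann <- annotate_run_context(ref, p, "A", "")
      expect_equal(ann$run_length, L, label = sprintf("del run %d pos %d", L, p))
      expect_equal(ann$position, 3)
    }
    # insert an A at every equivalent placement across the run
    for (p in 3:(3 + L)) {
      ann <- annotate_run_context(ref, p, "", "A")
      expect_equal(ann$run_length, L, label = sprintf("ins run %d pos %d", L, p))
      expect_equal(ann$position, 3)
    }
  }
})

test_that("run context matches the worked conventions", {
  expect_equal(annotate_run_context("CAAAAG", 4, "A", "")$run_length, 4)
  expect_equal(annotate_run_context("CAAAAG", 4, "A", "")$position, 2)
  expect_equal(annotate_run_context("CATG", 3, "T", "")$run_length, 1)
  # insertion of G adjacent to GGG: all placements give 3
  expect_equal(annotate_run_context("CATGGGTC", 4, "", "G")$run_length, 3)
  expect_equal(annotate_run_context("CATGGGTC", 7, "", "G")$run_length, 3)
  # substitutions take the run of the reference base at the site
  expect_equal(annotate_run_context("CTGGGA", 4, "G", "A")$run_length, 3)
})

test_that("fraction_in_runs counts annotated records of one category", {
  # constructed fixture: 19 of 20 one-bp deletions inside runs of length >= 3
  ref <- paste0(strrep(paste0("CT", strrep("A", 4), "GT"), 7), "CTAGCTAG")
  run_starts <- 8 * (0:6) + 3
  pos <- c(rep(run_starts, length.out = 19), 8 * 7 + 3)  # 19 in-run + 1 outside
  recs <- mut_records(paste0("iso", 1:20), pos,
                      substring(ref, pos, pos), "")
  recs <- classify_mutations(recs, ref)
  ann <- mutation_spectrum(
    within(recs, {
      run_length <- vapply(seq_along(pos), function(i)
        annotate_run_context(ref, pos[i], recs$ref_allele[i], "")$run_length,
        integer(1))
    }), genotype = "synthetic")
  expect_equal(fraction_in_runs(ann, "1-bp deletion", min_run = 3), 0.95)
  # boundary cases
  all_in <- ann; all_in$records$run_length <- 5L
  expect_equal(fraction_in_runs(all_in, "1-bp deletion", 3), 1.0)
  none_in <- ann; none_in$records$run_length <- 1L
  expect_equal(fraction_in_runs(none_in, "1-bp deletion", 3), 0.0)
  expect_warning(out <- fraction_in_runs(ann, "complex", 3), "undefined")
  expect_true(is.na(out))
})

test_that("spectra built from records count each complex cluster once", {
  ref <- paste(rep("ACGT", 10), collapse = "")
  recs <- mut_records(c("a", "a", "b", "c"), c(5, 9, 2, 13),
                      c("A", "A", "C", "A"), c("G", "T", "", "C"))
  cl <- classify_mutations(recs, ref)
  sp <- mutation_spectrum(cl, genotype = "toy")
  expect_equal(sp$n_total, 3L)  # a's two clustered events collapse to one
  expect_equal(unname(sp$counts[c("complex", "1-bp deletion", "base substitution")]),
               c(1L, 1L, 1L))
})

test_that("rate partitioning reproduces per-type rates, bounds and conservation", {
  msh2 <- mutation_spectrum(c(25, 17, 6, 1, 1), genotype = "msh2")
  part <- partition_rates(500e-8, msh2)
  rates <- setNames(part$table$rate, part$table$category)
  expect_equal(unname(rates["base substitution"]), 170e-8)
  expect_equal(unname(rates["1-bp deletion"]), 250e-8)
  expect_equal(unname(rates["1-bp insertion"]), 60e-8)
  expect_equal(sum(part$table$rate[!part$table$is_bound]), 500e-8)
  wt <- mutation_spectrum(c(7, 40, 1, 1, 1), genotype = "wt")
  expect_equal(partition_rates(60e-8, wt)$table$rate[1], 8.4e-8)
  # zero count of 47 at total 1100e-8: flagged upper bound, 23e-8 at 2 s.f.
  zc <- mutation_spectrum(c(20, 20, 7, 0, 0), genotype = "z")
  expect_equal(zc$n_total, 47L)
  pz <- partition_rates(1100e-8, zc)
  expect_true(all(pz$table$is_bound[4:5]))
  expect_equal(signif(pz$table$rate[4], 2), 23e-8)
  expect_error(partition_rates(1e-7, mutation_spectrum(rep(0L, 5))), "no mutations")
})

test_that("relative rates are category-wise ratios to the reference partition", {
  wt <- partition_rates(60e-8, mutation_spectrum(c(7, 40, 1, 1, 1), "wt"))
  m2 <- partition_rates(500e-8, mutation_spectrum(c(25, 17, 6, 1, 1), "msh2"))
  rel <- relative_rates(m2, wt)
  expect_equal(signif(rel$total_relative, 2), 8.3)
  expect_equal(signif(rel$table$relative_rate[rel$table$category == "1-bp deletion"], 2), 30)
  self <- relative_rates(wt, wt)
  expect_true(all(self$table$relative_rate == 1))
})

test_that("repair efficiency follows the percent formula and its monotonicities", {
  expect_equal(attr(repair_efficiency(48e-8, 170e-8), "reported"), 72)
  expect_equal(as.numeric(repair_efficiency(1e-7, 1e-7)), 0)
  expect_equal(as.numeric(repair_efficiency(0, 1e-7)), 100)
  expect_error(repair_efficiency(1e-7, 0), "> 0")
  expect_warning(repair_efficiency(2e-7, 1e-7), "exceeds")
  # antitone in the proficient rate, isotone in the deficient rate
  prof <- seq(1e-8, 9e-8, length.out = 9)
  expect_true(all(diff(as.numeric(repair_efficiency(prof, 1e-7))) < 0))
  defi <- seq(1e-7, 1e-6, length.out = 9)
  expect_true(all(diff(as.numeric(repair_efficiency(5e-8, defi))) > 0))
})
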