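test_that("the independence statistic equals the naive double-loop oracle", {
  set.seed(42)
  for (i in 1:10) {
    tab <- matrix(rpois(10, 8) + 1, nrow = 5)
    res <- suppressWarnings(chisq_independence(tab))
    expect_equal(res$statistic, naive_chisq_stat(tab))
    # cross-check statistic, df and p against the stock implementation
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p, unname(ref$p.value))
  }
})

test_that("identical columns give statistic 0 and p = 1", {
  tab <- cbind(a = c(5, 10, 2), b = c(5, 10, 2))
  res <- suppressWarnings(chisq_independence(tab))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  mc <- mc_homogeneity(tab, n_iter = 1000, seed = 1)
  expect_equal(mc$statistic_observed, 0)
  expect_equal(mc$p_mc, 1)
})

test_that("zero-margin rows are dropped and degenerate tables rejected", {
  tab <- rbind(c(3, 4), c(0, 0), c(6, 1))
  res <- suppressWarnings(chisq_independence(tab))
  expect_equal(res$df, 1)   # (3-1 dropped to 2 rows) x (2-1)
  expect_error(chisq_independence(rbind(c(3, 4), c(0, 0))), "degenerate")
  expect_error(mc_homogeneity(cbind(c(2, 3), c(0, 0)), 1000), "zero column")
})

test_that("bonferroni multiplies, caps at one and never decreases a p-value", {
  expect_equal(bonferroni(0.0001, 7), 0.0007)
  expect_equal(bonferroni(0.5578, 7), 1)
  expect_equal(bonferroni(0, 5), 0)
  p <- runif(20)
  expect_true(all(bonferroni(p, 3) >= p))
  expect_true(all(bonferroni(p, 3) <= 1))
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
})

test_that("published spectra reproduce the printed pairwise p-values", {
  sp <- hmr_ura3_spectra()
  out <- pairwise_compare(sp, method = "chisq")
  expect_equal(nrow(out), 7)          # 6 pairs + overall, hence m = 7
  expect_equal(unique(out$m), 7)
  p_of <- function(lbl) out$p[out$comparison == lbl]
  expect_equal(round(p_of("wild type vs exo1"), 4), 0.5578)
  expect_equal(round(p_of("msh2 vs msh2 exo1"), 4), 0.9761)
  expect_equal(round(p_of("wild type vs msh2"), 4), 0.0001)
  expect_equal(out$p_adjusted[out$comparison == "wild type vs msh2"], 0.0007)
  expect_equal(out$p_adjusted[out$comparison == "wild type vs exo1"], 1)
})

test_that("pairwise results do not depend on input order", {
  sp <- hmr_ura3_spectra()
  a <- pairwise_compare(sp, method = "chisq")
  b <- pairwise_compare(rev(sp), method = "chisq")
  expect_equal(sort(round(a$p, 10)), sort(round(b$p, 10)))
  expect_error(pairwise_compare(sp[1]), "at least two")
})

test_that("two identical spectra compare with p = 1", {
  s <- mutation_spectrum(c(5, 20, 3, 1, 1), "g1")
  s2 <- mutation_spectrum(c(5, 20, 3, 1, 1), "g2")
  out <- pairwise_compare(list(s, s2), method = "chisq")
  expect_equal(out$p[out$comparison == "g1 vs g2"], 1)
})

test_that("the Monte-Carlo statistic is invariant to row order and p is add-one", {
  tab <- cbind(a = c(12, 30, 2, 5), b = c(20, 18, 6, 3))
  r1 <- mc_homogeneity(tab, n_iter = 1000, seed = 7)
  r2 <- mc_homogeneity(tab[c(3, 1, 4, 2), ], n_iter = 1000, seed = 7)
  expect_equal(r1$statistic_observed, r2$statistic_observed)
  expect_gte(r1$p_mc, 1 / 1001)
  expect_lte(r1$p_mc, 1)
})

test_that("Monte-Carlo p agrees with the stock conditional simulation", {
  tab <- cbind(a = c(12, 30, 2, 5, 1), b = c(20, 18, 6, 3, 3))
  mine <- mc_homogeneity(tab, n_iter = 20000, seed = 11)
  stock <- chisq.test(tab, simulate.p.value = TRUE, B = 20000)
  se <- sqrt(mine$p_mc * (1 - mine$p_mc) / 20000)
  se_stock <- sqrt(stock$p.value * (1 - stock$p.value) / 20000)
  expect_lt(abs(mine$p_mc - stock$p.value), 3 * sqrt(se^2 + se_stock^2))
})

test_that("two long Monte-Carlo runs with different seeds agree", {
  tab <- cbind(a = c(12, 30, 2, 5), b = c(20, 18, 6, 3))
  r1 <- mc_homogeneity(tab, n_iter = 1e5, seed = 1)
  r2 <- mc_homogeneity(tab, n_iter = 1e5, seed = 2)
  se <- function(r) sqrt(r$p_mc * (1 - r$p_mc) / r$n_iter)
  expect_lt(abs(r1$p_mc - r2$p_mc), 3 * sqrt(se(r1)^2 + se(r2)^2))
  # the 5% critical value should sit near the asymptotic chi-square quantile
  expect_lt(abs(r1$critical_value_5pct - qchisq(0.95, 3)), 1.5)
})

test_that("pairwise Monte-Carlo comparisons run over all pairs", {
  sp <- hmr_ura3_spectra()[c("msh2", "msh2 exo1", "wild type")]
  out <- pairwise_compare(sp, method = "mc", n_iter = 2000, seed = 5)
  expect_equal(nrow(out), 3)
  expect_gt(out$p_mc[out$comparison == "msh2 vs msh2 exo1"], 0.5)
  expect_lt(out$p_mc[out$comparison == "msh2 vs wild type"], 0.01)
})
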