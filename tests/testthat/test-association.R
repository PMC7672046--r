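test_that("contingency tables follow the allele-count construction", {
  chs <- reference_panel("CHS", 105)
  tab <- build_contingency(3, 0, 195, chs, "1:100:A>G")
  expect_identical(unname(tab), c(3L, 387L, 0L, 210L))
  tab0 <- build_contingency(0, 0, 195, chs, "1:100:A>G")
  expect_identical(unname(tab0), c(0L, 390L, 0L, 210L))
  # homozygous carriers contribute two alternate alleles
  tab2 <- build_contingency(2, 1, 195, chs, "1:100:A>G")
  expect_identical(unname(tab2)[1], 4L)
  # panel counts: round(af * 2n), ties up -> 0.05 * 8654 = 432.7 -> 433
  eas <- reference_panel("EAS", 4327, c("1:100:A>G" = 0.05))
  expect_identical(unname(build_contingency(3, 0, 195, eas,
                                            "1:100:A>G"))[3], 433L)
  # half-allele ties round up: 0.05 * 2*10 = 1 exactly; 0.075*20 = 1.5 -> 2
  p10 <- reference_panel("P", 10, c("1:100:A>G" = 0.075))
  expect_identical(unname(build_contingency(2, 0, 5, p10,
                                            "1:100:A>G"))[3], 2L)
  expect_error(build_contingency(4, 3, 5, chs, "1:100:A>G"))
})

test_that("Fisher exact matches hand enumeration on small tables", {
  expect_equal(fisher_exact(c(5, 5, 5, 5)), 1.0)
  # 5 margin-fixed tables; sum of probabilities <= P(observed) = 34/70
  expect_equal(fisher_exact(c(3, 1, 1, 3)), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(c(3, 387, 0, 210)),
               oracle_fisher(3, 387, 0, 210), tolerance = 1e-12)
  # degenerate margins return 1 by convention
  expect_identical(as.numeric(fisher_exact(c(0, 10, 0, 20))), 1)
  expect_true(attr(fisher_exact(c(0, 10, 0, 20)), "degenerate"))
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- sample(0:40, 4, replace = TRUE)
    m <- matrix(tab, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(tab), stats::fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("chi-squared is the 1-df Pearson statistic without correction", {
  res <- chi_squared(c(5, 5, 5, 5))
  expect_equal(as.numeric(res), 1)
  expect_equal(attr(res, "statistic"), 0)
  # hand computation: rows (10,90)/(1,99) -> X^2 = 40.5/5.5 + 40.5/94.5
  res2 <- chi_squared(c(10, 90, 1, 99))
  expect_equal(attr(res2, "statistic"), 40.5 / 5.5 + 40.5 / 94.5,
               tolerance = 1e-10)
  expect_equal(as.numeric(res2),
               stats::pchisq(40.5 / 5.5 + 40.5 / 94.5, 1,
                             lower.tail = FALSE), tolerance = 1e-10)
  # expected alt cells of (3,97,1,99) are 2 < 5: approximation flagged
  expect_true(attr(chi_squared(c(3, 97, 1, 99)), "low_expected"))
  expect_false(attr(chi_squared(c(50, 50, 50, 50)), "low_expected"))
  expect_warning(res3 <- chi_squared(c(0, 10, 0, 20)), "zero margin")
  expect_equal(as.numeric(res3), 1)
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_fdr(c(0.5, 1.2)))
  expect_error(bh_fdr(c(0.5, NA)))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("variant classification implements the novel/differential rules", {
  # recurrent and absent from every panel -> novel
  expect_identical(classify_variant(3, c(CHS = FALSE, EAS = FALSE),
                                    c(CHS = NA, EAS = NA)), "novel")
  # singleton, absent -> not associated (fails the recurrence clause)
  expect_identical(classify_variant(1, c(CHS = FALSE, EAS = FALSE),
                                    c(CHS = NA, EAS = NA)),
                   "not_associated")
  # present in both with tiny q -> differential
  expect_identical(classify_variant(5, c(CHS = TRUE, EAS = TRUE),
                                    c(CHS = 0.001, EAS = 0.001)),
                   "differential")
  # present but not significant -> not associated
  expect_identical(classify_variant(5, c(CHS = TRUE, EAS = TRUE),
                                    c(CHS = 0.5, EAS = 0.5)),
                   "not_associated")
  # "all" mode requires significance in every present panel
  expect_identical(classify_variant(5, c(CHS = TRUE, EAS = TRUE),
                                    c(CHS = 0.5, EAS = 0.001),
                                    panel_sig_mode = "all"),
                   "not_associated")
  expect_identical(classify_variant(5, c(CHS = TRUE, EAS = TRUE),
                                    c(CHS = 0.5, EAS = 0.001),
                                    panel_sig_mode = "any"),
                   "differential")
  # novel and differential are mutually exclusive: presence decides
  for (carriers in c(2, 5)) {
    for (pres in list(c(TRUE, FALSE), c(FALSE, FALSE))) {
      cls <- classify_variant(carriers, pres, c(0.001, NA))
      expect_false(cls == "novel" && any(pres))
      expect_false(cls == "differential" && !any(pres))
    }
  }
})

test_that("associate_variants corrects within panel-present families", {
  fx <- traced_fixture()
  fun <- run_funnel(fx$cohort, fx$panels)
  res <- associate_variants(fun$candidates, fx$panels)
  # candidates v1 and v8 are panel-absent -> q NA there, classified novel
  tests <- res$tests
  k1 <- variant_key("1", 1, "A", "G")
  expect_true(all(is.na(tests$q[tests$key == k1])))
  expect_identical(
    res$classifications$class[res$classifications$key == k1], "novel")
  # v6 is present in both panels; its q in each panel equals BH over the
  # panel-present members of that panel's family (v6 alone here)
  k6 <- variant_key("1", 6, "A", "G")
  sub <- tests[tests$key == k6, ]
  expect_true(all(sub$present))
  expect_equal(sub$q, sub$p_fisher)  # family of size 1 per panel
  # empty candidate set gives empty results
  empty <- associate_variants(subset_cohort_empty(fx$cohort), fx$panels)
  expect_identical(nrow(empty$tests), 0L)
})

test_that("results are ordered by minimum q and then key", {
  fx <- traced_fixture()
  fun <- run_funnel(fx$cohort, fx$panels)
  res <- associate_variants(fun$candidates, fx$panels)
  cl <- res$classifications
  mq <- ifelse(is.na(cl$min_q), Inf, cl$min_q)
  expect_false(is.unsorted(mq))
})

test_that("Fisher p-values are super-uniform under the null", {
  # case carriers drawn from the panel allele frequency; conditional
  # exact test must be level-alpha (typically conservative)
  set.seed(11)
  n_sim <- 3000
  af <- 0.01
  eas <- reference_panel("EAS", 4327, c("1:1:A>G" = af))
  p <- vapply(seq_len(n_sim), function(i) {
    het <- stats::rbinom(1, 195, 2 * af * (1 - af))
    hom <- stats::rbinom(1, 195 - het, af^2)
    fisher_exact(build_contingency(het, hom, 195, eas, "1:1:A>G"))
  }, numeric(1))
  for (alpha in c(0.01, 0.05)) {
    mc_se <- sqrt(alpha * (1 - alpha) / n_sim)
    expect_lte(mean(p <= alpha), alpha + 3 * mc_se)
  }
})
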