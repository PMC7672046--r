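mk_clinical <- function(n = 20, seed = 1) simulate_clinical(n, seed = seed)

test_that("cohort summary reproduces counts, ratio and moments", {
  cl <- simulate_clinical(195, seed = 5)
  s <- cohort_summary(cl)
  expect_identical(s$n, 195L)
  expect_identical(as.integer(s$sex[["F"]]), 156L)
  expect_identical(as.integer(s$sex[["M"]]), 39L)
  expect_equal(s$female_male_ratio, 4.0)
  expect_identical(as.integer(s$shape[["C"]]) + as.integer(s$shape[["S"]]),
                   195L)
  # sample SD (n - 1)
  expect_equal(s$cobb[["sd"]], stats::sd(cl$cobb))
  expect_error(cohort_summary(cl[0, ]), "empty")
})

test_that("degenerate cohorts report missing statistics", {
  one <- simulate_clinical(1, seed = 2)
  s1 <- cohort_summary(one)
  expect_true(is.na(s1$cobb[["sd"]]))
  allf <- simulate_clinical(10, seed = 3,
                            proportions = list(sex = c(F = 1, M = 0)))
  expect_true(is.na(cohort_summary(allf)$female_male_ratio))
})

test_that("mean-split dichotomization sends ties below by default", {
  cl <- mk_clinical(4)
  cl$cobb <- c(30, 50, 40, 20)  # mean 35
  g <- dichotomize(cl, "cobb")
  expect_identical(g, c("below", "above", "above", "below"))
  cl$cobb <- c(30, 50, 40, 40)  # mean 40: the two 40s tie at the mean
  expect_identical(dichotomize(cl, "cobb"),
                   c("below", "above", "below", "below"))
  expect_identical(dichotomize(cl, "cobb", tie = "above"),
                   c("below", "above", "above", "above"))
  # categorical features pass through
  expect_identical(dichotomize(cl, "shape"), as.character(cl$shape))
  cl$cobb <- rep(40, 4)
  expect_error(dichotomize(cl, "cobb"), "constant")
  expect_error(dichotomize(cl, "nope"), "unknown")
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p, 1 / 3, tolerance = 1e-12)
  expect_identical(w$method, "exact")
  expect_equal(w$statistic, 0)
  # degenerate: both groups a single tied value
  expect_equal(wilcoxon_rank_sum(5, 5)$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  # exact branch against the enumeration oracle, all sizes na + nb <= 10
  set.seed(99)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      vals <- sample(seq_len(40), na + nb)  # distinct -> no ties
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      expect_equal(wilcoxon_rank_sum(a, b)$p, oracle_wilcoxon(a, b),
                   tolerance = 1e-12)
    }
  }
  # tie-corrected normal approximation for larger / tied samples
  a <- c(rep(1, 8), rep(2, 6)); b <- c(rep(1, 3), rep(2, 10))
  w2 <- wilcoxon_rank_sum(a, b)
  expect_identical(w2$method, "normal_approx")
  expect_equal(w2$p, stats::wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE)$p.value)
})

test_that("rank-sum p is roughly uniform under identical distributions", {
  set.seed(123)
  p <- replicate(400, wilcoxon_rank_sum(rnorm(15), rnorm(20))$p)
  expect_gt(mean(p <= 0.05), 0.01)
  expect_lt(mean(p <= 0.05), 0.10)
  expect_gt(mean(p), 0.40)
})

screen_cohort <- function(carrier_ids, samples) {
  vv <- data.frame(key = "1:1:A>G", chrom = "1", pos = 1, ref = "A",
                   alt = "G", gene = "G1", consequence = "missense_variant",
                   sift = "deleterious", polyphen2 = "deleterious",
                   lrt = "deleterious", fathmm = "deleterious",
                   mutationtaster = "deleterious", stringsAsFactors = FALSE)
  cc <- data.frame(key = rep("1:1:A>G", length(carrier_ids)),
                   sample_id = carrier_ids, depth = 50, alt_fraction = 0.5,
                   stringsAsFactors = FALSE)
  cohort(vv, cc, samples)
}

test_that("variant screening contrasts carriers against non-carriers", {
  cl <- simulate_clinical(60, seed = 8)
  carriers <- cl$patient_id[1:10]
  cl$cobb[cl$patient_id %in% carriers] <-
    cl$cobb[cl$patient_id %in% carriers] + 3 * stats::sd(cl$cobb)
  coh <- screen_cohort(carriers, cl$patient_id)
  res <- variant_feature_screen(coh, cl)
  hit <- res[res$feature == "cobb", ]
  expect_true(hit$significant)
  expect_identical(hit$test, "wilcoxon")
  # binary features use Fisher exact by default
  expect_identical(unique(res$test[res$feature == "sex"]), "fisher")
  # all-carrier variant has no contrast: skipped with a warning
  allc <- screen_cohort(cl$patient_id, cl$patient_id)
  expect_warning(res2 <- variant_feature_screen(allc, cl), "skipped")
  expect_identical(nrow(res2), 0L)
  expect_identical(attr(res2, "skipped"), "1:1:A>G")
})

test_that("screening is invariant to patient row order", {
  cl <- simulate_clinical(40, seed = 9)
  coh <- screen_cohort(cl$patient_id[c(3, 9, 17, 25, 31)], cl$patient_id)
  r1 <- variant_feature_screen(coh, cl)
  r2 <- variant_feature_screen(coh, cl[sample(nrow(cl)), ])
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("planted carrier Cobb shifts are detected with high sensitivity", {
  # +2 SD shift in 10 carriers of 195, BH within feature, q < 0.05
  hits <- vapply(1:60, function(seed) {
    cl <- simulate_clinical(195, seed = seed)
    carriers <- sample(cl$patient_id, 10)
    cl$cobb[cl$patient_id %in% carriers] <-
      cl$cobb[cl$patient_id %in% carriers] + 2 * stats::sd(cl$cobb)
    coh <- screen_cohort(carriers, cl$patient_id)
    res <- variant_feature_screen(coh, cl, features = "cobb")
    res$significant[1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("feature correlation picks tests by type and is symmetric", {
  cl <- simulate_clinical(120, seed = 10)
  fc <- feature_correlation(cl)
  expect_identical(fc$p, t(fc$p))
  expect_true(all(diag(fc$p) == 0))
  expect_identical(fc$method["cobb", "tilted_count"], "spearman")
  expect_identical(fc$method["shape", "sex"], "fisher")
  expect_identical(fc$method["cobb", "shape"], "wilcoxon")
  # a duplicated column is perfectly associated
  cl$cobb2 <- cl$cobb
  fc2 <- feature_correlation(cl, features = c("cobb", "cobb2", "sex"))
  expect_lt(fc2$p["cobb", "cobb2"], 1e-10)
  expect_error(feature_correlation(cl, features = "cobb"), "two features")
})

test_that("independent simulated features give roughly uniform p", {
  set.seed(14)
  p <- replicate(200, {
    cl <- simulate_clinical(80, seed = sample.int(1e6, 1))
    feature_correlation(cl, features = c("cobb", "direction"))$p[1, 2]
  })
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p <= 0.05), 0.12)
})

test_that("Venn regions partition the union and match set algebra", {
  sets <- list(a = c("x", "y"), b = "x", c = c("x", "z"), d = "x")
  res <- intersect_variant_sets(sets)
  expect_identical(res$shared_by_all, 1L)  # "x" alone is in all four
  expect_identical(res$n_union, 3L)
  expect_identical(sum(res$regions$count), res$n_union)
  oracle <- oracle_venn_regions(sets)
  for (region in names(oracle)) {
    expect_identical(res$regions$count[res$regions$region == region],
                     as.integer(oracle[[region]]))
  }
  # disjoint sets share nothing
  disj <- intersect_variant_sets(list(a = "1", b = "2", c = "3", d = "4"))
  expect_identical(disj$shared_by_all, 0L)
  expect_identical(disj$n_union, 4L)
  expect_error(intersect_variant_sets(list(a = "1")), "two sets")
})

test_that("random Venn instances agree with brute-force counts", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    sets <- stats::setNames(lapply(seq_len(k), function(j)
      sample(letters, sample(0:15, 1))), paste0("s", seq_len(k)))
    res <- intersect_variant_sets(sets)
    expect_identical(res$n_union, length(unique(unlist(sets))))
    expect_identical(sum(res$regions$count), res$n_union)
    expect_true(all(res$regions$count >= 0))
    oracle <- oracle_venn_regions(sets)
    for (region in names(oracle)) {
      hit <- res$regions$count[res$regions$region == region]
      expect_identical(hit, as.integer(oracle[[region]]))
    }
  }
})
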