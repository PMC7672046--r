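small_cfg <- function(...) {
  sim_config(n_variants = 300, n_planted_novel = 5,
             n_planted_differential = 5, ...)
}

test_that("the generator is deterministic in the seed", {
  d1 <- simulate_dataset(small_cfg(seed = 17))
  d2 <- simulate_dataset(small_cfg(seed = 17))
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- simulate_dataset(small_cfg(seed = 18))
  expect_false(identical(d1$cohort$calls, d3$cohort$calls))
})

test_that("planted truth satisfies its defining rules by construction", {
  ds <- simulate_dataset(small_cfg(seed = 23))
  tr <- ds$truth
  expect_length(intersect(tr$planted_novel_ids,
                          tr$planted_differential_ids), 0)
  expect_true(all(c(tr$planted_novel_ids, tr$planted_differential_ids)
                  %in% ds$cohort$variants$key))
  cc <- carrier_counts(ds$cohort)
  cfg <- funnel_config()
  for (k in tr$planted_novel_ids) {
    # >= 2 carriers, zero frequency in every panel, >= 2 deleterious votes
    expect_gte(cc$carriers[cc$key == k], 2)
    for (p in ds$panels) expect_identical(panel_af(p, k), 0)
    row <- ds$cohort$variants[ds$cohort$variants$key == k, ]
    expect_true(deleterious_consensus(row, cfg))
  }
  for (k in tr$planted_differential_ids) {
    expect_gte(cc$carriers[cc$key == k], 5)
    expect_equal(panel_af(ds$panels$EAS, k), 0.001)
  }
  # planted genes all sit in the planted family
  planted_genes <- ds$cohort$variants$gene[
    ds$cohort$variants$key %in% c(tr$planted_novel_ids,
                                  tr$planted_differential_ids)]
  fam <- ds$family_map$family_id[ds$family_map$gene %in% planted_genes]
  expect_true(all(fam == tr$planted_family))
})

test_that("planted novel variants survive the whole funnel", {
  for (seed in c(31, 32)) {
    ds <- simulate_dataset(small_cfg(seed = seed))
    res <- run_funnel(ds$cohort, ds$panels)
    expect_true(all(ds$truth$planted_novel_ids %in%
                      res$candidates$variants$key))
  }
})

test_that("a uniformly common background leaves zero candidates", {
  cfg <- sim_config(n_variants = 200, n_planted_novel = 0,
                    n_planted_differential = 0,
                    background_af = list(type = "fixed", af = 0.10),
                    corruption_rate = 0, seed = 41)
  ds <- simulate_dataset(cfg)
  res <- run_funnel(ds$cohort, ds$panels)
  expect_identical(n_variants(res$candidates), 0L)
})

test_that("null carrier counts follow the configured binomial law", {
  af <- 0.02
  cfg <- sim_config(n_variants = 10000, n_planted_novel = 0,
                    n_planted_differential = 0,
                    background_af = list(type = "fixed", af = af),
                    seed = 53)
  ds <- simulate_dataset(cfg)
  counts <- ds$truth$null_carriers$carriers
  p_carry <- 1 - (1 - af)^2
  # chi-squared goodness of fit against Binomial(195, p_carry),
  # pooling the upper tail to keep expected counts adequate
  brk <- 0:14
  obs <- table(cut(counts, c(brk - 0.5, Inf)))
  expected <- c(stats::dbinom(brk[-length(brk)], 195, p_carry),
                stats::pbinom(brk[length(brk)] - 1, 195, p_carry,
                              lower.tail = FALSE)) * length(counts)
  keep <- expected > 1
  stat <- sum((as.numeric(obs)[keep] - expected[keep])^2 / expected[keep])
  p <- stats::pchisq(stat, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_variants = 3, n_planted_novel = 4),
               "n_variants")
  expect_error(sim_config(novel_carrier_range = c(1, 4)),
               "novel_carrier_range")
  expect_error(sim_config(differential_af = 0.2), "differential_af")
  expect_error(sim_config(differential_panel = "XYZ"),
               "differential_panel")
  expect_error(sim_config(corruption_rate = 1.5), "corruption_rate")
  expect_error(sim_config(n_patients = 0), "n_patients")
})

test_that("clinical generation allocates exact category counts", {
  cl <- simulate_clinical(195, seed = 61)
  expect_identical(sum(cl$sex == "F"), 156L)
  expect_identical(sum(cl$sex == "M"), 39L)
  expect_identical(sum(cl$shape == "C"), 131L)
  expect_identical(sum(cl$direction == "L"), 52L)
  expect_identical(sum(cl$apex_class == "1"), 106L)
  expect_true(all(cl$cobb > 0))
  expect_true(all(cl$tilted_count >= 2))
  one <- simulate_clinical(1, seed = 62)
  expect_identical(nrow(one), 1L)
  expect_false(anyNA(one))
  expect_error(simulate_clinical(5, proportions = list(sex = c(F = 0.5,
                                                               M = 0.4))),
               "sum to 1")
  expect_error(simulate_clinical(0), "n_patients")
})

test_that("corruption produces QC-failing calls at roughly the set rate", {
  cfg <- sim_config(n_variants = 1500, n_planted_novel = 0,
                    n_planted_differential = 0, corruption_rate = 0.2,
                    seed = 71)
  ds <- simulate_dataset(cfg)
  cls <- classify_genotype(ds$cohort$calls$depth,
                           ds$cohort$calls$alt_fraction)
  frac_fail <- mean(cls == "fail")
  expect_gt(frac_fail, 0.10)
  expect_lt(frac_fail, 0.30)
  # without corruption every emitted call passes QC
  ds0 <- simulate_dataset(small_cfg(seed = 72, corruption_rate = 0))
  cls0 <- classify_genotype(ds0$cohort$calls$depth,
                            ds0$cohort$calls$alt_fraction)
  expect_true(all(cls0 != "fail"))
})
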