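# Fixtures built in code: a 10-variant cohort whose passage through every
# funnel stage has been traced by hand, and cheap random mini-cohorts for
# property tests.

# n deleterious verdicts, the rest tolerated (order sift, polyphen2, lrt,
# fathmm, mutationtaster); `missing` replaces tolerated slots on request.
verdicts <- function(n_del, n_missing = 0) {
  v <- c(rep("deleterious", n_del), rep("missing", n_missing),
         rep("tolerated", 5 - n_del - n_missing))
  stats::setNames(as.list(v), varfunnel::PREDICTOR_TOOLS)
}

traced_variant <- function(id, gene, verd) {
  data.frame(key = variant_key("1", id, "A", "G"), chrom = "1", pos = id,
             ref = "A", alt = "G", gene = gene,
             consequence = "missense_variant",
             as.data.frame(verd, stringsAsFactors = FALSE),
             stringsAsFactors = FALSE)
}

traced_calls <- function(id, samples, depth, af) {
  data.frame(key = variant_key("1", id, "A", "G"), sample_id = samples,
             depth = depth, alt_fraction = af, stringsAsFactors = FALSE)
}

# Hand-traced fixture (5 samples, panels CHSx n=10 / EASx n=50):
#  v1  2 good calls, absent both panels, 3 del votes  -> candidate
#  v2  only call depth 29                             -> dropped at QC
#  v3  only call af 0.75                              -> dropped at QC
#  v4  1 good call                                    -> dropped at recurrence
#  v5  2 good calls, af .06/.07 (common in both)      -> dropped at population
#  v6  2 good calls, af .06/.01 (common in one)       -> candidate (2 votes)
#  v7  2 good calls, absent, 1 del vote               -> dropped at consensus
#  v8  3 calls of which 2 pass QC, absent, 5 votes    -> candidate
#  v9  3 good calls, af .10/.10                       -> dropped at population
#  v10 het+hom good calls, af .04/0, 0 del votes      -> dropped at consensus
# Funnel: 10 -> 8 (QC) -> 7 (recurrence) -> 5 (population) -> 3.
traced_fixture <- function() {
  samples <- paste0("S", 1:5)
  vv <- rbind(
    traced_variant(1, "GA", verdicts(3)),
    traced_variant(2, "GB", verdicts(5)),
    traced_variant(3, "GB", verdicts(5)),
    traced_variant(4, "GC", verdicts(4)),
    traced_variant(5, "GD", verdicts(4)),
    traced_variant(6, "GE", verdicts(2)),
    traced_variant(7, "GF", verdicts(1, n_missing = 4)),
    traced_variant(8, "GG", verdicts(5)),
    traced_variant(9, "GH", verdicts(3)),
    traced_variant(10, "GA", verdicts(0)))
  cc <- rbind(
    traced_calls(1, c("S1", "S2"), 50, 0.5),
    traced_calls(2, "S1", 29, 0.5),
    traced_calls(3, "S2", 50, 0.75),
    traced_calls(4, "S3", 60, 0.45),
    traced_calls(5, c("S1", "S4"), 40, 0.55),
    traced_calls(6, c("S2", "S3"), 35, 0.5),
    traced_calls(7, c("S4", "S5"), 45, 0.5),
    traced_calls(8, c("S1", "S2", "S3"), c(50, 20, 40), c(0.5, 0.5, 0.55)),
    traced_calls(9, c("S1", "S2", "S3"), 55, 0.5),
    traced_calls(10, c("S4", "S5"), 50, c(0.5, 0.95)))
  coh <- cohort(vv, cc, samples)
  k <- function(i) variant_key("1", i, "A", "G")
  panels <- list(
    CHSx = reference_panel("CHSx", 10, stats::setNames(
      c(0.06, 0.06, 0.10, 0.04), k(c(5, 6, 9, 10)))),
    EASx = reference_panel("EASx", 50, stats::setNames(
      c(0.07, 0.01, 0.10), k(c(5, 6, 9)))))
  list(cohort = coh, panels = panels,
       expected_survivors = list(
         qc = k(c(1, 4:10)), recurrence = k(c(1, 5:10)),
         population = k(c(1, 6, 7, 8, 10)), candidates = k(c(1, 6, 8))))
}

# Cheap random mini-cohort + panels for property tests (mixes passing and
# failing depths/fractions, common and rare panel frequencies).
random_cohort <- function(seed, n_var = 25, n_samp = 15) {
  set.seed(seed)
  pos <- sample.int(1e6, n_var)
  ref <- sample(c("A", "C", "G", "T"), n_var, TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  vv <- data.frame(key = variant_key("1", pos, ref, alt), chrom = "1",
                   pos = pos, ref = ref, alt = alt,
                   gene = paste0("G", sample(1:8, n_var, TRUE)),
                   consequence = "missense_variant",
                   stringsAsFactors = FALSE)
  for (tool in varfunnel::PREDICTOR_TOOLS) {
    vv[[tool]] <- sample(c("deleterious", "tolerated", "missing"), n_var,
                         TRUE, prob = c(0.4, 0.4, 0.2))
  }
  samples <- paste0("S", seq_len(n_samp))
  cc <- do.call(rbind, lapply(seq_len(n_var), function(i) {
    nc <- sample(0:4, 1)
    if (!nc) return(NULL)
    data.frame(key = vv$key[i], sample_id = sample(samples, nc),
               depth = sample(10:80, nc, TRUE),
               alt_fraction = round(stats::runif(nc), 3),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cc)) {
    cc <- data.frame(key = character(0), sample_id = character(0),
                     depth = integer(0), alt_fraction = numeric(0))
  }
  coh <- cohort(vv, cc, samples)
  in_a <- runif(n_var) < 0.5
  in_b <- runif(n_var) < 0.5
  panels <- list(
    A = reference_panel("A", 40, stats::setNames(
      round(runif(sum(in_a), 0.001, 0.2), 4), vv$key[in_a])),
    B = reference_panel("B", 200, stats::setNames(
      round(runif(sum(in_b), 0.001, 0.2), 4), vv$key[in_b])))
  list(cohort = coh, panels = panels)
}

# small manipulation helpers shared by funnel tests
subset_cohort_empty <- function(x) {
  x$variants <- x$variants[0, ]
  x$calls <- x$calls[0, ]
  x
}
subset_keys <- function(x, keys) {
  x$variants <- x$variants[x$variants$key %in% keys, ]
  x$calls <- x$calls[x$calls$key %in% keys, ]
  x
}
deleterious_filter_keys <- function(x, cfg = varfunnel::funnel_config()) {
  x$variants$key[varfunnel::deleterious_consensus(x$variants, cfg)]
}
recurrence_keys_of_deleterious <- function(qc, cfg) {
  keep <- qc$variants$key[varfunnel::deleterious_consensus(qc$variants, cfg)]
  sub <- varfunnel::recurrence_filter(subset_keys(qc, keep), cfg)
  sub$variants$key
}
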