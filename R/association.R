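## Per-variant burden testing against reference panels, BH-FDR, and
## novel / differential classification.

round_half_up <- function(x) floor(x + 0.5)

#' Build the 2x2 allele-count contingency table for one variant
#'
#' Case alternate-allele count is `het_carriers + 2 * hom_carriers`; the
#' panel alternate-allele count is the published allele frequency times the
#' panel's `2 * n_samples` alleles, rounded to the nearest integer (ties
#' up, so frequencies stay representable as integral counts for the exact
#' test).  Reference cells are the complements of the diploid allele
#' totals.
#'
#' @param case_het,case_hom Numbers of heterozygous / homozygous carriers.
#' @param n_cases Number of case individuals (diploid).
#' @param panel A [reference_panel()].
#' @param key Variant key used to look up the panel allele frequency.
#' @return Named integer vector `c(case_alt, case_ref, panel_alt,
#'   panel_ref)`.
#' @export
#' @examples
#' chs <- reference_panel("CHS", 105)
#' build_contingency(3, 0, 195, chs, "1:100:A>G")  # (3, 387, 0, 210)
build_contingency <- function(case_het, case_hom, n_cases, panel, key) {
  stopifnot(case_het >= 0, case_hom >= 0, case_het + case_hom <= n_cases)
  af <- panel_af(panel, key)
  case_alt <- as.integer(case_het + 2 * case_hom)
  panel_alt <- as.integer(round_half_up(af * 2 * panel$n_samples))
  tab <- c(case_alt = case_alt,
           case_ref = as.integer(2 * n_cases) - case_alt,
           panel_alt = panel_alt,
           panel_ref = as.integer(2 * panel$n_samples) - panel_alt)
  if (any(tab < 0)) stop("negative contingency cell", call. = FALSE)
  tab
}

#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Computes the two-sided p-value by the probability-mass definition: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7 for ties).  Any zero margin is
#' degenerate and returns p = 1 with attribute `degenerate = TRUE`.
#'
#' @param tab Named vector or 2x2 matrix with cells `case_alt, case_ref,
#'   panel_alt, panel_ref` (rows = population, columns = allele).
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact <- function(tab) {
  tab <- as_tab22(tab)
  alt_total <- tab["case_alt"] + tab["panel_alt"]
  ref_total <- tab["case_ref"] + tab["panel_ref"]
  case_total <- tab["case_alt"] + tab["case_ref"]
  panel_total <- tab["panel_alt"] + tab["panel_ref"]
  if (alt_total == 0 || ref_total == 0 || case_total == 0 ||
      panel_total == 0) {
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0, alt_total - panel_total):min(alt_total, case_total)
  probs <- stats::dhyper(support, alt_total, ref_total, case_total)
  p_obs <- probs[support == tab["case_alt"]]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  unname(min(1, p))
}

as_tab22 <- function(tab) {
  if (is.matrix(tab)) {
    tab <- c(case_alt = tab[1, 1], case_ref = tab[1, 2],
             panel_alt = tab[2, 1], panel_ref = tab[2, 2])
  }
  cells <- c("case_alt", "case_ref", "panel_alt", "panel_ref")
  if (is.null(names(tab))) names(tab) <- cells
  stopifnot(all(cells %in% names(tab)), all(tab >= 0))
  tab[cells]
}

#' Pearson chi-squared test (1 df, no continuity correction)
#'
#' @inheritParams fisher_exact
#' @return p-value with attributes `statistic` and `low_expected` (TRUE
#'   when any expected cell is below 5, flagging an unreliable
#'   approximation).  A zero margin gives p = 1 with a warning.
#' @export
chi_squared <- function(tab) {
  tab <- as_tab22(tab)
  m <- matrix(tab, nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "panel"), c("alt", "ref")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin: chi-squared statistic undefined, p set to 1",
            call. = FALSE)
    return(structure(1, statistic = NA_real_, low_expected = TRUE))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(unname(res$p.value),
            statistic = unname(res$statistic),
            low_expected = any(expected < 5))
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order; elementwise `q >= p` and invariant
#'   to permutations of the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify one variant as novel, differential or not associated
#'
#' A variant is *novel* when it recurs in at least `min_carriers` case
#' patients and has no frequency in any reference panel; *differential*
#' when it is present in at least one panel and its BH q-value is below
#' `alpha` in the required panels (`panel_sig_mode = "any"`: some present
#' panel; `"all"`: every present panel); otherwise *not_associated*.
#' Novel and differential are mutually exclusive by construction.
#'
#' @param carrier_count Number of case carriers.
#' @param present Named logical vector: is the variant present per panel?
#' @param q Named numeric vector of per-panel BH q-values (`NA` where
#'   absent).
#' @param alpha Significance level (default 0.05).
#' @param min_carriers Recurrence threshold for the novel rule.
#' @param panel_sig_mode `"any"` or `"all"`.
#' @return One of `"novel"`, `"differential"`, `"not_associated"`.
#' @export
classify_variant <- function(carrier_count, present, q, alpha = 0.05,
                             min_carriers = 2,
                             panel_sig_mode = c("any", "all")) {
  panel_sig_mode <- match.arg(panel_sig_mode)
  if (!any(present)) {
    if (carrier_count >= min_carriers) return("novel")
    return("not_associated")
  }
  sig <- q[present] < alpha
  hit <- if (panel_sig_mode == "all") all(sig) else any(sig)
  if (isTRUE(hit)) "differential" else "not_associated"
}

#' Burden-test all funnel candidates against every reference panel
#'
#' For each candidate variant and each panel, builds the allele-count
#' contingency table, computes Fisher exact and chi-squared p-values, and
#' applies Benjamini-Hochberg correction *within each panel's family of
#' panel-present variants*.  Variants absent from a panel are not part of
#' that panel's testing family (their q is `NA` there).  Classification
#' (novel / differential / not associated) uses the Fisher q-values.
#'
#' @param candidates Funnel-surviving `ais_cohort`.
#' @param panels List of [reference_panel()] objects.
#' @param n_cases Number of case individuals (defaults to the cohort
#'   roster size).
#' @param alpha Significance level for the differential call.
#' @param min_carriers Recurrence threshold for the novel call.
#' @param panel_sig_mode `"any"` (default; significant in some present
#'   panel) or `"all"`.
#' @return List with `tests` (long `data.frame`: one row per variant x
#'   panel with `chrom, pos, ref, alt, gene, carriers, case_alt, panel,
#'   panel_af, panel_alt, present, p_fisher, p_chi2, q, class`) and
#'   `classifications` (one row per variant: `key, gene, carriers, min_q,
#'   class`, sorted by `min_q` then key).
#' @export
associate_variants <- function(candidates, panels,
                               n_cases = length(candidates$samples),
                               alpha = 0.05, min_carriers = 2,
                               panel_sig_mode = c("any", "all")) {
  panel_sig_mode <- match.arg(panel_sig_mode)
  panels <- validate_panels(panels)
  cc <- carrier_counts(candidates)
  v <- candidates$variants
  if (!nrow(v)) {
    empty <- data.frame()
    return(list(tests = empty, classifications = empty))
  }
  rows <- list()
  for (pid in names(panels)) {
    pan <- panels[[pid]]
    af <- panel_af(pan, v$key)
    pres <- panel_present(pan, v$key)
    p_f <- p_c <- numeric(nrow(v))
    alt <- integer(nrow(v))
    for (i in seq_len(nrow(v))) {
      tab <- build_contingency(cc$n_het[i], cc$n_hom[i], n_cases, pan,
                               v$key[i])
      alt[i] <- tab["panel_alt"]
      p_f[i] <- fisher_exact(tab)
      p_c[i] <- suppressWarnings(as.numeric(chi_squared(tab)))
    }
    q <- rep(NA_real_, nrow(v))
    if (any(pres)) q[pres] <- bh_fdr(p_f[pres])
    rows[[pid]] <- data.frame(
      key = v$key, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      gene = v$gene, carriers = cc$carriers, case_alt = cc$n_het + 2 * cc$n_hom,
      panel = pid, panel_af = af, panel_alt = alt, present = pres,
      p_fisher = p_f, p_chi2 = p_c, q = q, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL

  cls <- vapply(v$key, function(k) {
    sub <- tests[tests$key == k, ]
    classify_variant(sub$carriers[1],
                     stats::setNames(sub$present, sub$panel),
                     stats::setNames(sub$q, sub$panel),
                     alpha = alpha, min_carriers = min_carriers,
                     panel_sig_mode = panel_sig_mode)
  }, character(1))
  min_q <- vapply(v$key, function(k) {
    qs <- tests$q[tests$key == k]
    if (all(is.na(qs))) NA_real_ else min(qs, na.rm = TRUE)
  }, numeric(1))
  classifications <- data.frame(
    key = v$key, gene = v$gene, carriers = cc$carriers,
    min_q = unname(min_q), class = unname(cls), stringsAsFactors = FALSE)
  ord <- order(ifelse(is.na(classifications$min_q), Inf,
                      classifications$min_q),
               classifications$key)
  classifications <- classifications[ord, , drop = FALSE]
  rownames(classifications) <- NULL
  tests$class <- classifications$class[match(tests$key, classifications$key)]
  list(tests = tests, classifications = classifications)
}
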