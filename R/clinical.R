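## Clinical-feature encoding, subgroup dichotomization, genotype-phenotype
## screening, feature-feature correlation and Venn-style intersection.

CLINICAL_DOMAINS <- list(
  sex = c("F", "M"),
  shape = c("C", "S"),          # "C"- vs "S"-shaped curve
  direction = c("L", "R"),      # main-curve direction
  apex_class = c("1", "2"),     # apex at T1-T9 (1) vs under T10 (2)
  lenke = as.character(1:6)
)

CONTINUOUS_FEATURES <- c("age", "cobb", "tilted_count")
BINARY_FEATURES <- c("sex", "shape", "direction", "apex_class")

## Features screened / intersected by default: apex location, Cobb angle,
## main-curve direction and tilted-vertebrae count (sex and shape are
## screened on request but excluded from the default Venn).
VENN_FEATURES <- c("apex_class", "cobb", "direction", "tilted_count")

validate_clinical <- function(clinical) {
  need <- c("patient_id", "sex", "age", "cobb", "shape", "direction",
            "apex_class", "tilted_count", "lenke")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in names(CLINICAL_DOMAINS)) {
    vals <- as.character(clinical[[f]])
    bad <- which(!vals %in% CLINICAL_DOMAINS[[f]])
    if (length(bad)) {
      stop("clinical row ", bad[1], ": field '", f, "' value '",
           vals[bad[1]], "' outside domain {",
           paste(CLINICAL_DOMAINS[[f]], collapse = ","), "}", call. = FALSE)
    }
  }
  if (any(clinical$cobb <= 0)) {
    stop("Cobb angles must be positive degrees", call. = FALSE)
  }
  if (any(clinical$tilted_count < 2)) {
    stop("tilted-vertebrae counts must be >= 2", call. = FALSE)
  }
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient ids", call. = FALSE)
  }
  invisible(clinical)
}

#' Summarize a clinical cohort table
#'
#' Means and sample standard deviations (n - 1) of age, Cobb angle and
#' tilted-vertebrae count; category counts for sex, curve shape, curve
#' direction and apex class; and the female:male ratio (reported as `NA`
#' when the cohort contains no males).  Single-patient tables report `NA`
#' standard deviations.
#'
#' @param clinical Clinical `data.frame` (see [read_clinical_csv()]).
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(clinical) {
  if (!nrow(clinical)) stop("empty clinical table", call. = FALSE)
  validate_clinical(clinical)
  msd <- function(x) {
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  counts <- function(f) table(factor(as.character(clinical[[f]]),
                                     levels = CLINICAL_DOMAINS[[f]]))
  sexes <- counts("sex")
  ratio <- if (sexes[["M"]] > 0) sexes[["F"]] / sexes[["M"]] else NA_real_
  structure(list(
    n = nrow(clinical),
    age = msd(clinical$age), cobb = msd(clinical$cobb),
    tilted_count = msd(clinical$tilted_count),
    sex = sexes, shape = counts("shape"), direction = counts("direction"),
    apex_class = counts("apex_class"),
    female_male_ratio = ratio), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f +/- %.2f", v["mean"], v["sd"])
  cat("Cohort of", x$n, "patients\n")
  cat("  age:", fmt(x$age), "years | Cobb:", fmt(x$cobb),
      "deg | tilted vertebrae:", fmt(x$tilted_count), "\n")
  cat("  sex F/M:", x$sex[["F"]], "/", x$sex[["M"]],
      sprintf("(female:male ratio %.2f)\n", x$female_male_ratio))
  cat("  shape C/S:", x$shape[["C"]], "/", x$shape[["S"]],
      "| direction L/R:", x$direction[["L"]], "/", x$direction[["R"]],
      "| apex T1-T9/under T10:", x$apex_class[["1"]], "/",
      x$apex_class[["2"]], "\n")
  invisible(x)
}

#' Dichotomize patients on a clinical feature
#'
#' Continuous features are split at the cohort mean ("above" strictly
#' greater than the mean; values equal to the mean go to "below", the
#' documented tie rule, switchable with `tie`).  Categorical features pass
#' their two levels through.
#'
#' @param clinical Clinical table.
#' @param feature Feature name.
#' @param tie For mean splits, which side receives values exactly at the
#'   mean (`"below"`, the default, or `"above"`).
#' @return Character vector of group labels, one per patient.
#' @export
dichotomize <- function(clinical, feature, tie = c("below", "above")) {
  tie <- match.arg(tie)
  vals <- clinical[[feature]]
  if (is.null(vals)) stop("unknown clinical feature '", feature, "'",
                          call. = FALSE)
  if (feature %in% names(CLINICAL_DOMAINS)) {
    return(as.character(vals))
  }
  if (length(unique(vals)) < 2) {
    stop("cannot mean-split constant feature '", feature, "'", call. = FALSE)
  }
  m <- mean(vals)
  if (tie == "below") ifelse(vals > m, "above", "below")
  else ifelse(vals >= m, "above", "below")
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact p by enumeration of rank assignments when `n_a + n_b <= 12` with
#' no ties; otherwise the normal approximation with tie-corrected variance
#' and continuity correction.  Two tied constant groups are degenerate and
#' return p = 1.
#'
#' @param a,b Numeric value vectors for the two groups (both non-empty).
#' @return List with `statistic` (the Mann-Whitney U for `a` vs `b`),
#'   `p`, and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = length(a) * length(b) / 2, p = 1,
                method = "degenerate"))
  }
  exact <- !ties && (length(a) + length(b)) <= 12
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- res$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(res$statistic), p = p,
       method = if (exact) "exact" else "normal_approx")
}

#' Screen variants for association with clinical features
#'
#' For each variant, patients are split into carriers vs non-carriers.
#' Continuous/ordinal features (Cobb angle, tilted-vertebrae count, age)
#' are compared by Wilcoxon rank-sum on the feature values; binary
#' features (sex, curve shape, curve direction, apex class) by Fisher's
#' exact test on the 2x2 carrier-by-level table (or by rank-sum on 0/1
#' coding with `binary_test = "wilcoxon"`).  BH correction is applied
#' within each feature across variants.  Variants carried by no patient or
#' by every patient provide no contrast and are skipped (recorded in the
#' `skipped` attribute).
#'
#' @param x An `ais_cohort` (QC'd; carriers are het/hom calls).
#' @param clinical Clinical table whose `patient_id`s match the cohort
#'   sample ids.
#' @param features Features to screen (default: the four structural
#'   features plus sex and shape).
#' @param alpha Significance level for the `significant` column.
#' @param binary_test `"fisher"` (default) or `"wilcoxon"`.
#' @return `data.frame`: `key, feature, test, statistic, p, q,
#'   significant`, with attribute `skipped` (keys without contrast).
#' @export
variant_feature_screen <- function(x, clinical,
                                   features = c(VENN_FEATURES, "sex",
                                                "shape"),
                                   alpha = 0.05,
                                   binary_test = c("fisher", "wilcoxon")) {
  binary_test <- match.arg(binary_test)
  validate_clinical(clinical)
  if (!all(x$samples %in% clinical$patient_id)) {
    stop("cohort samples missing from the clinical table", call. = FALSE)
  }
  clinical <- clinical[match(x$samples, clinical$patient_id), , drop = FALSE]
  carriers_of <- split(x$calls$sample_id, x$calls$key)
  skipped <- character(0)
  out <- list()
  for (key in x$variants$key) {
    carr <- x$samples %in% carriers_of[[key]]
    if (!any(carr) || all(carr)) {
      skipped <- c(skipped, key)
      next
    }
    for (f in features) {
      if (f %in% CONTINUOUS_FEATURES) {
        w <- wilcoxon_rank_sum(clinical[[f]][carr], clinical[[f]][!carr])
        row <- data.frame(key = key, feature = f, test = "wilcoxon",
                          statistic = w$statistic, p = w$p,
                          stringsAsFactors = FALSE)
      } else if (f %in% BINARY_FEATURES) {
        lev <- factor(as.character(clinical[[f]]),
                      levels = CLINICAL_DOMAINS[[f]])
        if (binary_test == "fisher") {
          tab <- table(carrier = carr, level = lev)
          p <- fisher_exact(c(case_alt = tab[2, 1], case_ref = tab[2, 2],
                              panel_alt = tab[1, 1], panel_ref = tab[1, 2]))
          row <- data.frame(key = key, feature = f, test = "fisher",
                            statistic = NA_real_, p = as.numeric(p),
                            stringsAsFactors = FALSE)
        } else {
          w <- wilcoxon_rank_sum(as.numeric(lev)[carr],
                                 as.numeric(lev)[!carr])
          row <- data.frame(key = key, feature = f, test = "wilcoxon",
                            statistic = w$statistic, p = w$p,
                            stringsAsFactors = FALSE)
        }
      } else {
        stop("unsupported feature '", f, "'", call. = FALSE)
      }
      out[[length(out) + 1]] <- row
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " variant(s) without carrier contrast skipped",
            call. = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(key = character(0), feature = character(0),
               test = character(0), statistic = numeric(0), p = numeric(0),
               stringsAsFactors = FALSE)
  res$q <- rep(NA_real_, nrow(res))
  for (f in unique(res$feature)) {
    sel <- res$feature == f
    res$q[sel] <- bh_fdr(res$p[sel])
  }
  res$significant <- !is.na(res$q) & res$q < alpha
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Per-feature significant variant sets
#'
#' Convenience accessor on a [variant_feature_screen()] result.
#'
#' @param screen Screen result table.
#' @param features Features to extract (default: the four structural
#'   Venn features, excluding sex and shape).
#' @return Named list of variant-key vectors.
#' @export
significant_variant_sets <- function(screen, features = VENN_FEATURES) {
  stats::setNames(lapply(features, function(f) {
    unique(screen$key[screen$feature == f & screen$significant])
  }), features)
}

#' Pairwise association between clinical features
#'
#' For each pair of features the test is chosen by type: categorical x
#' categorical, Fisher exact (2x2) or chi-squared; categorical x
#' continuous, Wilcoxon rank-sum (2 levels) or Kruskal-Wallis;
#' continuous x continuous, Spearman correlation.  The p-value matrix is
#' symmetric with a zero diagonal (a feature is perfectly associated with
#' itself).
#'
#' @param clinical Clinical table.
#' @param features Features to correlate.
#' @return List of class `feature_correlation` with symmetric matrices
#'   `p` and `method`.
#' @export
feature_correlation <- function(clinical,
                                features = c("cobb", "tilted_count",
                                             "apex_class", "direction",
                                             "shape", "sex")) {
  validate_clinical(clinical)
  if (length(features) < 2) stop("need at least two features", call. = FALSE)
  k <- length(features)
  p <- matrix(0, k, k, dimnames = list(features, features))
  meth <- matrix("self", k, k, dimnames = list(features, features))
  is_cat <- features %in% names(CLINICAL_DOMAINS)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      fi <- features[i]; fj <- features[j]
      if (is_cat[i] && is_cat[j]) {
        tab <- table(as.character(clinical[[fi]]),
                     as.character(clinical[[fj]]))
        if (all(dim(tab) == 2)) {
          pv <- stats::fisher.test(tab)$p.value
          m <- "fisher"
        } else {
          pv <- suppressWarnings(stats::chisq.test(tab)$p.value)
          m <- "chisq"
        }
      } else if (!is_cat[i] && !is_cat[j]) {
        pv <- suppressWarnings(
          stats::cor.test(clinical[[fi]], clinical[[fj]],
                          method = "spearman", exact = FALSE)$p.value)
        m <- "spearman"
      } else {
        cat_f <- if (is_cat[i]) fi else fj
        num_f <- if (is_cat[i]) fj else fi
        g <- factor(as.character(clinical[[cat_f]]))
        if (nlevels(g) == 2) {
          sp <- split(clinical[[num_f]], g)
          pv <- wilcoxon_rank_sum(sp[[1]], sp[[2]])$p
          m <- "wilcoxon"
        } else {
          pv <- stats::kruskal.test(clinical[[num_f]], g)$p.value
          m <- "kruskal"
        }
      }
      p[i, j] <- p[j, i] <- pv
      meth[i, j] <- meth[j, i] <- m
    }
  }
  structure(list(p = p, method = meth), class = "feature_correlation")
}

#' @export
print.feature_correlation <- function(x, ...) {
  cat("Pairwise clinical-feature association p-values:\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Venn-style intersection of per-feature variant sets
#'
#' Partitions the union of k variant sets into its 2^k - 1 disjoint
#' membership regions and reports the count of each, plus the number (and
#' percentage of the union) shared by all sets.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return List with `regions` (`data.frame`: membership `region` label
#'   such as `"cobb&direction"`, `count`), `n_union`, `shared_by_all`, and
#'   `shared_by_all_pct`.
#' @export
intersect_variant_sets <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets))) {
    stop("need a named list of at least two sets", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  union_all <- unique(unlist(sets, use.names = FALSE))
  member <- matrix(FALSE, nrow = length(union_all), ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  for (nm in names(sets)) member[, nm] <- union_all %in% sets[[nm]]
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  counts <- apply(combos, 1, function(cmb) {
    sum(apply(member, 1, function(m) all(m == cmb)))
  })
  regions <- data.frame(
    region = apply(combos, 1, function(cmb)
      paste(names(sets)[as.logical(cmb)], collapse = "&")),
    count = as.integer(counts), stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  shared <- if (length(union_all)) sum(apply(member, 1, all)) else 0L
  list(regions = regions, n_union = length(union_all),
       shared_by_all = as.integer(shared),
       shared_by_all_pct = if (length(union_all))
         100 * shared / length(union_all) else NA_real_)
}
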