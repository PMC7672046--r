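## Synthetic AIS cohort generator with planted, known-truth variants.
## Defaults mirror the study design the pipeline targets: 195 case
## patients screened against the 1000 Genomes CHS panel (105 diploid
## samples) and the ExAC EAS panel (4,327 diploid samples).

#' Simulation configuration
#'
#' Parameters of the synthetic cohort.  Defaults encode the study
#' conditions: 195 patients, panels CHS = 105 and EAS = 4,327 diploid
#' samples.  Planted *novel* variants recur in 2-6 patients, are absent
#' from every panel and carry >= 2 deleterious verdicts, so they satisfy
#' the novel-variant rule by construction.  Planted *differential*
#' variants recur in 5-10 patients with a low nonzero panel frequency
#' (default 0.001 in the large EAS panel; their CHS record is drawn
#' binomially, so rare variants are usually absent from the small panel,
#' as real 105-sample extracts are).  Null variants draw a latent
#' population frequency from a point-mass-at-zero plus scaled-Beta
#' mixture; their panel records are binomial resamples and their case
#' carrier counts are binomial in the diploid carrier probability.
#'
#' @param n_patients Number of case patients.
#' @param panel_sizes Named integer vector of diploid panel sizes.
#' @param n_variants Total variants (null + planted).
#' @param background_af Null population-frequency law: either
#'   `list(type = "mixture", p_private, shape1, shape2, max)` (probability
#'   `p_private` of a cohort-private variant with zero panel frequency,
#'   else `max * Beta(shape1, shape2)`), or `list(type = "fixed", af)`
#'   giving every null variant the same frequency (used for calibration
#'   checks against the binomial carrier law).
#' @param n_planted_novel,n_planted_differential Planted variant counts.
#' @param novel_carrier_range,differential_carrier_range Inclusive carrier
#'   ranges for the planted classes; the novel minimum must be >= 2 so
#'   planted novels survive the recurrence filter.
#' @param differential_af Panel allele frequency of planted differential
#'   variants in `differential_panel`.
#' @param differential_panel Panel carrying the planted differential
#'   frequency (default `"EAS"`, the large panel).
#' @param planted_family Family id receiving every planted gene.
#' @param n_families Number of null gene families.
#' @param deleterious_rate_null Probability a null variant receives >= 2
#'   deleterious verdicts.
#' @param private_extra_carrier_rate Poisson rate of extra carriers (beyond
#'   one) for cohort-private null variants.
#' @param depth Sequencing-depth law `list(min, mu, size)`: depth =
#'   `min + NegBinom(mu, size)`, so uncorrupted calls meet the >= 30 QC
#'   bar by construction.
#' @param corruption_rate Fraction of null carrier calls emitted as QC
#'   failures (low depth or off-window alt fraction), exercising the QC
#'   stage.
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 195,
                       panel_sizes = c(CHS = 105, EAS = 4327),
                       n_variants = 2000,
                       background_af = list(type = "mixture",
                                            p_private = 0.30,
                                            shape1 = 0.3, shape2 = 3,
                                            max = 0.5),
                       n_planted_novel = 10,
                       n_planted_differential = 10,
                       novel_carrier_range = c(2, 6),
                       differential_carrier_range = c(5, 10),
                       differential_af = 0.001,
                       differential_panel = "EAS",
                       planted_family = "FAM_AXONEMAL_DYNEIN",
                       n_families = 40,
                       deleterious_rate_null = 0.30,
                       private_extra_carrier_rate = 0.3,
                       depth = list(min = 30, mu = 40, size = 8),
                       corruption_rate = 0.05,
                       seed = 1L) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid sim_config field '", field, "': ", why,
                  call. = FALSE)
  }
  chk(n_patients >= 1, "n_patients", "must be >= 1")
  chk(length(panel_sizes) >= 1 && all(panel_sizes >= 1) &&
        !is.null(names(panel_sizes)), "panel_sizes",
      "must be a named vector of counts >= 1")
  chk(n_variants >= 0, "n_variants", "must be >= 0")
  chk(n_planted_novel >= 0 && n_planted_differential >= 0,
      "n_planted_novel", "planted counts must be >= 0")
  chk(n_planted_novel + n_planted_differential <= n_variants,
      "n_variants", "planted variants exceed n_variants")
  chk(novel_carrier_range[1] >= 2, "novel_carrier_range",
      "minimum must be >= 2 (planted novels must survive recurrence)")
  chk(novel_carrier_range[2] >= novel_carrier_range[1] &&
        novel_carrier_range[2] <= n_patients, "novel_carrier_range",
      "must be an increasing range within the cohort size")
  chk(differential_carrier_range[1] >= 2 &&
        differential_carrier_range[2] >= differential_carrier_range[1] &&
        differential_carrier_range[2] <= n_patients,
      "differential_carrier_range", "must be a range in [2, n_patients]")
  chk(differential_af > 0 && differential_af <= 0.05, "differential_af",
      "must lie in (0, 0.05]")
  chk(differential_panel %in% names(panel_sizes), "differential_panel",
      "must name a configured panel")
  chk(deleterious_rate_null >= 0 && deleterious_rate_null <= 1,
      "deleterious_rate_null", "must lie in [0, 1]")
  chk(corruption_rate >= 0 && corruption_rate <= 1, "corruption_rate",
      "must lie in [0, 1]")
  chk(depth$min >= 1, "depth", "minimum depth must be >= 1")
  chk(background_af$type %in% c("mixture", "fixed"), "background_af",
      "type must be 'mixture' or 'fixed'")
  if (background_af$type == "fixed") {
    chk(background_af$af >= 0 && background_af$af <= 0.5, "background_af",
        "fixed af must lie in [0, 0.5]")
  } else {
    chk(background_af$p_private >= 0 && background_af$p_private <= 1 &&
          background_af$max > 0 && background_af$max <= 0.5,
        "background_af", "mixture needs p_private in [0,1], max in (0,0.5]")
  }
  structure(as.list(environment())[c(
    "n_patients", "panel_sizes", "n_variants", "background_af",
    "n_planted_novel", "n_planted_differential", "novel_carrier_range",
    "differential_carrier_range", "differential_af", "differential_panel",
    "planted_family", "n_families", "deleterious_rate_null",
    "private_extra_carrier_rate", "depth", "corruption_rate", "seed")],
    class = "sim_config")
}

## Native predictor labels emitted by the generator, per verdict class.
.NATIVE_LABELS <- list(
  deleterious = list(sift = "D", polyphen2 = c("D", "probably_damaging"),
                     lrt = "D", fathmm = "D",
                     mutationtaster = c("A", "D")),
  tolerated = list(sift = "T", polyphen2 = c("B", "P"), lrt = "N",
                   fathmm = "T", mutationtaster = c("N", "P")),
  missing = list(sift = ".", polyphen2 = ".", lrt = "U", fathmm = ".",
                 mutationtaster = ".")
)

draw_verdicts <- function(n_deleterious) {
  classes <- sample(c(rep("deleterious", n_deleterious),
                      rep("tolerated", 5 - n_deleterious)))
  # a tolerated slot is occasionally unreported, as real annotations are
  classes[classes == "tolerated" & stats::runif(5) < 0.15] <- "missing"
  vapply(seq_along(PREDICTOR_TOOLS), function(i) {
    pool <- .NATIVE_LABELS[[classes[i]]][[PREDICTOR_TOOLS[i]]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
}

draw_depth <- function(n, law) {
  law$min + stats::rnbinom(n, mu = law$mu, size = law$size)
}

## integer alt-read count giving alt fraction strictly inside (0.4, 0.6)
draw_het_ad <- function(depth) {
  vapply(depth, function(d) {
    lo <- floor(d * 0.4) + 1
    hi <- ceiling(d * 0.6) - 1
    if (hi < lo) return(round(d / 2))
    lo + sample.int(hi - lo + 1, 1) - 1
  }, numeric(1))
}

corrupt_call <- function(depth) {
  if (stats::runif(1) < 0.5) {                # low depth
    d <- sample(5:29, 1)
    c(depth = d, alt_ad = round(d / 2))
  } else {                                    # off-window alt fraction
    ad <- round(depth * stats::runif(1, 0.65, 0.85))
    c(depth = depth, alt_ad = ad)
  }
}

#' Generate a synthetic clinical table
#'
#' Categorical fields are allocated to exact counts (largest-remainder
#' rounding of `proportions * n_patients`) and shuffled across patients;
#' continuous fields are truncated normals.  Defaults reproduce the
#' cohort composition the pipeline targets: 80% female, 67% "C"-shaped
#' curves, 73% right main curves, 54% apex at T1-T9; age 14.93 +/- 3.04
#' years, Cobb angle 41.88 +/- 18.35 degrees, 13.00 +/- 3.84 tilted
#' vertebrae.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed.
#' @param proportions Named list of per-field category proportions,
#'   merged fieldwise over the defaults; each field's proportions must
#'   lie in `[0, 1]` and sum to 1.
#' @param age,cobb,tilted Lists `list(mean, sd)` for the continuous
#'   fields.
#' @return Clinical `data.frame` (see [read_clinical_csv()] for schema).
#' @export
simulate_clinical <- function(n_patients, seed = 1L,
                              proportions = list(),
                              age = list(mean = 14.93, sd = 3.04),
                              cobb = list(mean = 41.88, sd = 18.35),
                              tilted = list(mean = 13.00, sd = 3.84)) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  defaults <- list(
    sex = c(F = 156, M = 39) / 195,
    shape = c(C = 131, S = 64) / 195,
    direction = c(L = 52, R = 143) / 195,
    apex_class = c("1" = 106, "2" = 89) / 195,
    lenke = stats::setNames(rep(1 / 6, 6), as.character(1:6)))
  proportions <- utils::modifyList(defaults, as.list(proportions))
  for (f in names(proportions)) {
    pr <- proportions[[f]]
    if (any(pr < 0 | pr > 1) || abs(sum(pr) - 1) > 1e-8) {
      stop("proportions for '", f, "' must lie in [0, 1] and sum to 1",
           call. = FALSE)
    }
  }
  alloc <- function(pr) {
    # largest-remainder allocation to exact integer counts summing to n
    raw <- pr * n_patients
    cnt <- floor(raw)
    rem <- n_patients - sum(cnt)
    if (rem > 0) {
      top <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[top] <- cnt[top] + 1
    }
    sample(rep(names(pr), times = cnt))
  }
  with_seed(seed, {
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      sex = alloc(proportions$sex),
      age = round(pmax(10, stats::rnorm(n_patients, age$mean, age$sd)), 1),
      cobb = round(pmax(11, stats::rnorm(n_patients, cobb$mean, cobb$sd)), 1),
      shape = alloc(proportions$shape),
      direction = alloc(proportions$direction),
      apex_class = alloc(proportions$apex_class),
      tilted_count = pmax(2, round(stats::rnorm(n_patients, tilted$mean,
                                                tilted$sd))),
      lenke = alloc(proportions$lenke),
      stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic dataset with known planted truth
#'
#' Emits a cohort (variant annotations + carrier calls), one reference
#' panel per configured population, a clinical table, a gene-family map,
#' and the planted truth.  Planted novel variants are panel-absent,
#' recurrent and deleterious by construction; planted differential
#' variants carry a configured low panel frequency and a case carrier
#' excess; null variants follow the configured background law.  Every
#' planted gene belongs to the single planted family; null genes are
#' scattered uniformly over the remaining families (a small fraction get a
#' second membership, as HGNC families overlap).  The output is a
#' deterministic function of the configuration, including its seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with elements `cohort`
#'   (`ais_cohort`), `annotation` (sidecar `data.frame` with native
#'   predictor labels), `panels`, `clinical`, `family_map`, and `truth`
#'   (list: `planted_novel_ids`, `planted_differential_ids`,
#'   `planted_family`, `effects`, `null_carriers`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_var <- config$n_variants
    n_nov <- config$n_planted_novel
    n_dif <- config$n_planted_differential
    n_null <- n_var - n_nov - n_dif
    cls <- c(rep("novel", n_nov), rep("differential", n_dif),
             rep("null", n_null))

    chrom <- as.character(sample(1:22, n_var, replace = TRUE))
    pos <- sample.int(5e7, n_var)
    ref <- sample(VARIANT_BASES, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(VARIANT_BASES, r), 1),
                  character(1))
    key <- variant_key(chrom, pos, ref, alt)
    while (anyDuplicated(key)) {            # vanishingly rare collisions
      d <- which(duplicated(key))
      pos[d] <- pos[d] + 1L
      key <- variant_key(chrom, pos, ref, alt)
    }

    ## genes and families: one gene per planted variant, all in the
    ## planted family; null variants share a smaller gene universe
    planted_genes <- sprintf("PLGENE%02d", seq_len(n_nov + n_dif))
    n_null_genes <- max(1, ceiling(n_null / 8))
    null_genes <- sprintf("GENE%04d", seq_len(n_null_genes))
    gene <- c(planted_genes,
              sample(null_genes, n_null, replace = TRUE))[seq_len(n_var)]
    fam_ids <- sprintf("FAM%02d", seq_len(config$n_families))
    family_map <- rbind(
      if (length(planted_genes)) data.frame(
        gene = planted_genes, family_id = config$planted_family,
        family_name = "planted axonemal-dynein-like family",
        stringsAsFactors = FALSE),
      data.frame(gene = null_genes,
                 family_id = sample(fam_ids, n_null_genes, replace = TRUE),
                 family_name = "background family",
                 stringsAsFactors = FALSE))
    # overlap: ~5% of null genes carry a second family membership
    extra <- null_genes[stats::runif(n_null_genes) < 0.05]
    if (length(extra)) {
      family_map <- rbind(family_map, data.frame(
        gene = extra, family_id = sample(fam_ids, length(extra),
                                         replace = TRUE),
        family_name = "background family", stringsAsFactors = FALSE))
      family_map <- family_map[!duplicated(family_map[c("gene",
                                                        "family_id")]), ]
    }

    ## panel allele frequencies --------------------------------------
    panel_ids <- names(config$panel_sizes)
    af_true <- numeric(n_var)
    bg <- config$background_af
    null_idx <- which(cls == "null")
    if (length(null_idx)) {
      if (bg$type == "fixed") {
        af_true[null_idx] <- bg$af
      } else {
        private <- stats::runif(length(null_idx)) < bg$p_private
        af_true[null_idx[!private]] <-
          bg$max * stats::rbeta(sum(!private), bg$shape1, bg$shape2)
      }
    }
    panel_af_mat <- matrix(0, n_var, length(panel_ids),
                           dimnames = list(key, panel_ids))
    for (pid in panel_ids) {
      alleles <- 2 * config$panel_sizes[[pid]]
      nz <- af_true > 0
      panel_af_mat[nz, pid] <-
        stats::rbinom(sum(nz), alleles, af_true[nz]) / alleles
    }
    dif_idx <- which(cls == "differential")
    if (length(dif_idx)) {
      # exact configured frequency in the designated (large) panel,
      # binomial resample in the others
      panel_af_mat[dif_idx, ] <- 0
      panel_af_mat[dif_idx, config$differential_panel] <-
        config$differential_af
      for (pid in setdiff(panel_ids, config$differential_panel)) {
        alleles <- 2 * config$panel_sizes[[pid]]
        panel_af_mat[dif_idx, pid] <-
          stats::rbinom(length(dif_idx), alleles,
                        config$differential_af) / alleles
      }
    }
    # planted novel rows stay at 0 everywhere

    ## case carrier counts --------------------------------------------
    sample_range <- function(rng, n) {
      vals <- seq(rng[1], rng[2])
      vals[sample.int(length(vals), n, replace = TRUE)]
    }
    carriers_n <- integer(n_var)
    carriers_n[cls == "novel"] <- sample_range(config$novel_carrier_range,
                                               n_nov)
    carriers_n[dif_idx] <- sample_range(config$differential_carrier_range,
                                        n_dif)
    if (length(null_idx)) {
      if (bg$type == "fixed") {
        nc <- stats::rbinom(length(null_idx), config$n_patients,
                            1 - (1 - bg$af)^2)
      } else {
        p_carry <- 1 - (1 - af_true[null_idx])^2
        nc <- stats::rbinom(length(null_idx), config$n_patients, p_carry)
        private0 <- af_true[null_idx] == 0
        nc[private0] <- 1 + stats::rpois(sum(private0),
                                         config$private_extra_carrier_rate)
        nc <- pmin(nc, config$n_patients)
      }
      carriers_n[null_idx] <- nc
    }

    ## predictor verdicts ----------------------------------------------
    votes <- integer(n_var)
    votes[cls != "null"] <- sample(3:5, n_nov + n_dif, replace = TRUE)
    if (length(null_idx)) {
      strong <- stats::runif(length(null_idx)) < config$deleterious_rate_null
      votes[null_idx] <- ifelse(strong,
                                sample(2:5, length(null_idx),
                                       replace = TRUE),
                                sample(0:1, length(null_idx),
                                       replace = TRUE))
    }
    native <- t(vapply(votes, draw_verdicts, character(5)))
    colnames(native) <- PREDICTOR_TOOLS

    samples <- sprintf("P%04d", seq_len(config$n_patients))

    ## carrier calls ----------------------------------------------------
    observed <- carriers_n > 0
    call_list <- vector("list", n_var)
    for (i in which(observed)) {
      who <- sample(samples, carriers_n[i])
      depth <- draw_depth(carriers_n[i], config$depth)
      ad <- draw_het_ad(depth)
      if (cls[i] == "null" && config$corruption_rate > 0) {
        for (j in which(stats::runif(carriers_n[i]) <
                        config$corruption_rate)) {
          cc <- corrupt_call(depth[j])
          depth[j] <- cc["depth"]
          ad[j] <- cc["alt_ad"]
        }
      }
      call_list[[i]] <- data.frame(
        key = key[i], sample_id = who, depth = as.integer(depth),
        alt_ad = as.integer(ad),
        alt_fraction = as.integer(ad) / as.integer(depth),
        stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, call_list[observed])
    if (is.null(calls)) {
      calls <- data.frame(key = character(0), sample_id = character(0),
                          depth = integer(0), alt_ad = integer(0),
                          alt_fraction = numeric(0))
    }

    ## assemble ----------------------------------------------------------
    keep <- observed        # variants never seen in the cohort are not emitted
    annotation <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      consequence = "missense_variant", native,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    variants <- data.frame(
      key = key, chrom = chrom, pos = pos, ref = ref, alt = alt,
      gene = gene, consequence = "missense_variant",
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    for (tool in PREDICTOR_TOOLS) {
      variants[[tool]] <- normalize_verdict(native[keep, tool], tool)
    }
    rownames(variants) <- rownames(annotation) <- NULL
    coh <- cohort(variants, calls[, c("key", "sample_id", "depth",
                                      "alt_fraction")], samples)
    panels <- lapply(panel_ids, function(pid) {
      nz <- panel_af_mat[keep, pid] > 0
      reference_panel(pid, config$panel_sizes[[pid]],
                      panel_af_mat[keep, pid][nz])
    })
    names(panels) <- panel_ids

    clinical <- simulate_clinical(config$n_patients,
                                  seed = config$seed + 104729L)

    truth <- list(
      planted_novel_ids = key[cls == "novel"],
      planted_differential_ids = key[cls == "differential"],
      planted_family = config$planted_family,
      effects = data.frame(key = key, class = cls, gene = gene,
                           carriers = carriers_n,
                           panel_af_mat, emitted = keep,
                           stringsAsFactors = FALSE, row.names = NULL),
      null_carriers = data.frame(key = key[cls == "null"],
                                 carriers = carriers_n[cls == "null"],
                                 stringsAsFactors = FALSE))
    structure(list(cohort = coh, annotation = annotation, panels = panels,
                   clinical = clinical, family_map = family_map,
                   truth = truth, config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic AIS dataset:", n_variants(x$cohort), "observed variants",
      sprintf("(%d planted novel, %d planted differential),",
              length(x$truth$planted_novel_ids),
              length(x$truth$planted_differential_ids)),
      length(x$cohort$samples), "patients,",
      length(x$panels), "reference panels\n")
  invisible(x)
}
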