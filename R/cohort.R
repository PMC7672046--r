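#' @keywords internal
"_PACKAGE"

## Shared domain constants --------------------------------------------------

VARIANT_BASES <- c("A", "C", "G", "T")

#' The five deleteriousness predictors whose verdicts the pipeline consumes
#'
#' Verdicts from SIFT, PolyPhen2, LRT, FATHMM and MutationTaster are inputs
#' (computed upstream by annotation tools), never computed here.
#' @export
PREDICTOR_TOOLS <- c("sift", "polyphen2", "lrt", "fathmm", "mutationtaster")

VERDICT_LEVELS <- c("deleterious", "tolerated", "missing")

## Native predictor labels -> normalized verdicts.  "D" means deleterious in
## SIFT/LRT/FATHMM, probably-damaging in PolyPhen2 and disease-causing in
## MutationTaster; PolyPhen2 "possibly_damaging" does not count as a
## deleterious vote.
.VERDICT_MAP <- list(
  sift = c(D = "deleterious", deleterious = "deleterious",
           T = "tolerated", tolerated = "tolerated"),
  polyphen2 = c(D = "deleterious", probably_damaging = "deleterious",
                P = "tolerated", possibly_damaging = "tolerated",
                B = "tolerated", benign = "tolerated"),
  lrt = c(D = "deleterious", deleterious = "deleterious",
          N = "tolerated", neutral = "tolerated",
          U = "missing", unknown = "missing"),
  fathmm = c(D = "deleterious", deleterious = "deleterious",
             T = "tolerated", tolerated = "tolerated"),
  mutationtaster = c(A = "deleterious", disease_causing_automatic = "deleterious",
                     D = "deleterious", disease_causing = "deleterious",
                     N = "tolerated", polymorphism = "tolerated",
                     P = "tolerated", polymorphism_automatic = "tolerated")
)

#' Build a canonical variant key
#'
#' Variants are identified throughout the package by the string
#' `"chrom:pos:ref>alt"` (1-based VCF coordinates, single-base alleles).
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (integer, >= 1).
#' @param ref,alt Single reference / alternate bases in `A,C,G,T`; must differ.
#' @return Character vector of keys.
#' @export
#' @examples
#' variant_key("1", 12345, "A", "G")
variant_key <- function(chrom, pos, ref, alt) {
  if (!length(chrom)) return(character(0))
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' Normalize a predictor's native verdict label
#'
#' Maps each tool's native labels (e.g. SIFT `"D"`, PolyPhen2
#' `"probably_damaging"`, MutationTaster `"disease_causing"`) onto
#' `{deleterious, tolerated, missing}`.  `"."`, `""` and `NA` are `missing`
#' for every tool; already-normalized labels pass through.  PolyPhen2
#' `possibly_damaging` is *not* a deleterious vote.
#'
#' @param labels Character vector of native labels.
#' @param tool One of `r paste(PREDICTOR_TOOLS, collapse = ", ")`.
#' @return Character vector over `{deleterious, tolerated, missing}`.
#' @export
normalize_verdict <- function(labels, tool) {
  tool <- match.arg(tolower(tool), PREDICTOR_TOOLS)
  out <- rep(NA_character_, length(labels))
  lab <- as.character(labels)
  is_missing <- is.na(lab) | lab %in% c("", ".", "NA", "missing")
  out[is_missing] <- "missing"
  passthrough <- !is_missing & lab %in% VERDICT_LEVELS
  out[passthrough] <- lab[passthrough]
  todo <- is.na(out)
  if (any(todo)) {
    mapped <- .VERDICT_MAP[[tool]][lab[todo]]
    bad <- is.na(mapped)
    if (any(bad)) {
      stop("unknown ", tool, " verdict label(s): ",
           paste(unique(lab[todo][bad]), collapse = ", "), call. = FALSE)
    }
    out[todo] <- unname(mapped)
  }
  out
}

## Validators ---------------------------------------------------------------

validate_variant_table <- function(variants) {
  need <- c("key", "chrom", "pos", "ref", "alt", "gene", "consequence",
            PREDICTOR_TOOLS)
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant keys in variant table", call. = FALSE)
  }
  if (any(variants$pos < 1)) stop("variant pos must be >= 1", call. = FALSE)
  if (!all(variants$ref %in% VARIANT_BASES) ||
      !all(variants$alt %in% VARIANT_BASES)) {
    stop("ref/alt must be single bases in A,C,G,T", call. = FALSE)
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt must differ", call. = FALSE)
  }
  for (tool in PREDICTOR_TOOLS) {
    bad <- !variants[[tool]] %in% VERDICT_LEVELS
    if (any(bad)) {
      stop("non-normalized ", tool, " verdicts; run normalize_verdict() first",
           call. = FALSE)
    }
  }
  invisible(variants)
}

validate_call_table <- function(calls, variant_keys) {
  need <- c("key", "sample_id", "depth", "alt_fraction")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("call table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(calls)) {
    if (any(calls$depth < 0)) stop("call depth must be >= 0", call. = FALSE)
    if (any(calls$alt_fraction < 0 | calls$alt_fraction > 1)) {
      stop("alt_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (anyDuplicated(paste(calls$key, calls$sample_id))) {
      stop("duplicate (variant, sample) call", call. = FALSE)
    }
    orphan <- setdiff(calls$key, variant_keys)
    if (length(orphan)) {
      stop("calls reference unknown variant key(s): ",
           paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(calls$genotype_class)) calls$genotype_class <- NA_character_
  calls
}

#' Construct a cohort object
#'
#' A cohort bundles the per-variant annotation table, the per-carrier
#' observed calls (read depth and read-level alternate-allele fraction), and
#' the full sample roster (needed for allele-count denominators and for
#' carrier/non-carrier contrasts).
#'
#' @param variants `data.frame` with columns `key, chrom, pos, ref, alt,
#'   gene, consequence` and one normalized verdict column per tool in
#'   [PREDICTOR_TOOLS].
#' @param calls `data.frame` with columns `key, sample_id, depth,
#'   alt_fraction` (and optionally `genotype_class`); carriers only.
#' @param samples Character vector of all cohort sample ids.
#' @return An object of class `ais_cohort`.
#' @export
cohort <- function(variants, calls, samples) {
  variants <- as.data.frame(variants)
  calls <- as.data.frame(calls)
  validate_variant_table(variants)
  calls <- validate_call_table(calls, variants$key)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (nrow(calls) && length(setdiff(calls$sample_id, samples))) {
    stop("calls reference sample ids outside the cohort roster", call. = FALSE)
  }
  structure(list(variants = variants, calls = calls,
                 samples = as.character(samples)),
            class = "ais_cohort")
}

#' @export
print.ais_cohort <- function(x, ...) {
  cat("AIS cohort:", length(x$samples), "samples,",
      nrow(x$variants), "variants,", nrow(x$calls), "carrier calls\n")
  invisible(x)
}

#' Number of variants in a cohort
#' @param x An `ais_cohort`.
#' @export
n_variants <- function(x) nrow(x$variants)

## Subset a cohort to a set of variant keys, keeping calls in step.
subset_cohort <- function(x, keys) {
  x$variants <- x$variants[x$variants$key %in% keys, , drop = FALSE]
  x$calls <- x$calls[x$calls$key %in% x$variants$key, , drop = FALSE]
  rownames(x$variants) <- rownames(x$calls) <- NULL
  x
}

#' Carrier counts per variant
#'
#' Counts heterozygous and homozygous carriers per variant from the call
#' table.  Calls whose `genotype_class` is `"fail"` are excluded; calls with
#' `genotype_class` `NA` (pre-QC) count as carriers.
#'
#' @param x An `ais_cohort`.
#' @return `data.frame` with columns `key, n_het, n_hom, carriers`, one row
#'   per variant in `x` (zero rows counted as zero carriers).
#' @export
carrier_counts <- function(x) {
  keys <- x$variants$key
  calls <- x$calls
  cls <- ifelse(is.na(calls$genotype_class), "het", calls$genotype_class)
  n_het <- table(factor(calls$key[cls == "het"], levels = keys))
  n_hom <- table(factor(calls$key[cls == "hom"], levels = keys))
  data.frame(key = keys,
             n_het = as.integer(n_het),
             n_hom = as.integer(n_hom),
             carriers = as.integer(n_het) + as.integer(n_hom),
             stringsAsFactors = FALSE)
}

## Reference panels ---------------------------------------------------------

#' Construct a reference allele-frequency panel
#'
#' Represents a population reference panel (e.g. 1000 Genomes CHS, n = 105
#' diploid individuals, or ExAC EAS, n = 4,327) as a sparse map from variant
#' key to population allele frequency.  Variants absent from the map are
#' treated as frequency 0 and "not present".
#'
#' @param panel_id Panel identifier (e.g. `"CHS"`).
#' @param n_samples Number of diploid individuals in the panel (>= 1).
#' @param af Named numeric vector of allele frequencies in `[0, 1]`, names
#'   being variant keys; or a `data.frame` with columns `key, af` (or
#'   `chrom, pos, ref, alt, af`).
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(panel_id, n_samples, af = numeric(0)) {
  if (is.data.frame(af)) {
    if (!"key" %in% names(af)) {
      af$key <- variant_key(af$chrom, af$pos, af$ref, af$alt)
    }
    af <- stats::setNames(as.numeric(af$af), af$key)
  }
  if (length(af) && anyDuplicated(names(af))) {
    stop("duplicate variant keys in panel '", panel_id, "'", call. = FALSE)
  }
  if (any(af < 0 | af > 1)) {
    stop("panel allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1) {
    stop("panel n_samples must be >= 1", call. = FALSE)
  }
  structure(list(panel_id = as.character(panel_id),
                 n_samples = n_samples, af = af),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel", x$panel_id, "- n =", x$n_samples,
      "diploid samples,", length(x$af), "variants with nonzero record\n")
  invisible(x)
}

#' Panel allele frequency for a set of variants
#'
#' @param panel A `reference_panel`.
#' @param keys Variant keys.
#' @return Numeric vector; 0 for variants absent from the panel.
#' @export
panel_af <- function(panel, keys) {
  out <- panel$af[keys]
  out[is.na(out)] <- 0
  unname(out)
}

#' Is a variant present (recorded) in a panel?
#' @inheritParams panel_af
#' @return Logical vector.
#' @export
panel_present <- function(panel, keys) {
  keys %in% names(panel$af) & panel_af(panel, keys) > 0
}

validate_panels <- function(panels) {
  if (!length(panels)) stop("at least one reference panel required",
                            call. = FALSE)
  if (!all(vapply(panels, inherits, logical(1), "reference_panel"))) {
    stop("panels must be a list of reference_panel objects", call. = FALSE)
  }
  ids <- vapply(panels, `[[`, character(1), "panel_id")
  stats::setNames(panels, ids)
}

## Seed scoping: evaluate `code` under `seed` and restore the caller's RNG
## state afterwards, so library functions never clobber user randomness.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)  # force now: a lazy seed drawn from the global
                            # stream must advance it before the snapshot
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
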