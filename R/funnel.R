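#' Configuration for the high-confidence QC and prioritization funnel
#'
#' Encodes the filtering rules of the discovery funnel:
#' \itemize{
#'   \item read depth at the variant site must be >= `min_depth` (default 30);
#'   \item read-level alternate-allele fraction must fall strictly inside
#'     the heterozygous window (0.4, 0.6) or strictly above the homozygous
#'     threshold 0.9 — boundary values fail, as do fractions in (0.6, 0.9];
#'   \item a variant must recur in at least `min_carriers` patients
#'     (default 2);
#'   \item variants with population allele frequency above
#'     `panel_af_cutoff` (default 5%) in *both* reference panels are
#'     removed (`panel_af_mode = "both"`); `"any"` removes a variant
#'     common in at least one panel;
#'   \item at least `min_deleterious_votes` (default 2) of the five
#'     predictor verdicts must be deleterious.
#' }
#'
#' @param min_depth Minimum site read depth per call.
#' @param het_low,het_high Open heterozygous alt-fraction window.
#' @param hom_threshold Exclusive lower bound of the homozygous window.
#' @param min_carriers Minimum number of carrier patients.
#' @param panel_af_cutoff Population allele-frequency cutoff.
#' @param panel_af_mode `"both"` (remove only if common in every panel) or
#'   `"any"`.
#' @param min_deleterious_votes Minimum deleterious predictor votes.
#' @return A `funnel_config` list.
#' @export
funnel_config <- function(min_depth = 30, het_low = 0.4, het_high = 0.6,
                          hom_threshold = 0.9, min_carriers = 2,
                          panel_af_cutoff = 0.05,
                          panel_af_mode = c("both", "any"),
                          min_deleterious_votes = 2) {
  panel_af_mode <- match.arg(panel_af_mode)
  if (!(0 < het_low && het_low < het_high && het_high <= hom_threshold &&
        hom_threshold < 1)) {
    stop("require 0 < het_low < het_high <= hom_threshold < 1", call. = FALSE)
  }
  if (min_carriers < 1) stop("min_carriers must be >= 1", call. = FALSE)
  if (!(panel_af_cutoff > 0 && panel_af_cutoff < 1)) {
    stop("panel_af_cutoff must lie in (0, 1)", call. = FALSE)
  }
  if (min_depth < 0) stop("min_depth must be >= 0", call. = FALSE)
  if (min_deleterious_votes < 0) {
    stop("min_deleterious_votes must be >= 0", call. = FALSE)
  }
  structure(list(min_depth = min_depth, het_low = het_low,
                 het_high = het_high, hom_threshold = hom_threshold,
                 min_carriers = min_carriers,
                 panel_af_cutoff = panel_af_cutoff,
                 panel_af_mode = panel_af_mode,
                 min_deleterious_votes = min_deleterious_votes),
            class = "funnel_config")
}

#' Classify a call as heterozygous, homozygous or failed
#'
#' Applies the read-level genotype QC rule: depth below `min_depth` fails
#' regardless of the alt fraction; alt fraction strictly inside
#' (`het_low`, `het_high`) is heterozygous; strictly above `hom_threshold`
#' is homozygous; anything else (including the window boundaries and the
#' gap (0.6, 0.9]) fails.  The three classes partition the valid domain.
#'
#' @param depth Read depth(s), >= 0.
#' @param alt_fraction Read-level alternate-allele fraction(s) in `[0, 1]`.
#' @param config A [funnel_config()].
#' @return Character vector over `{"het", "hom", "fail"}`.
#' @export
#' @examples
#' cfg <- funnel_config()
#' classify_genotype(c(50, 50, 50, 25), c(0.50, 0.95, 0.75, 0.50), cfg)
classify_genotype <- function(depth, alt_fraction, config = funnel_config()) {
  stopifnot(all(depth >= 0), all(alt_fraction >= 0 & alt_fraction <= 1))
  out <- rep("fail", length(alt_fraction))
  out[alt_fraction > config$het_low & alt_fraction < config$het_high] <- "het"
  out[alt_fraction > config$hom_threshold] <- "hom"
  out[depth < config$min_depth] <- "fail"
  out
}

#' High-confidence genotype QC
#'
#' Classifies every observed call with [classify_genotype()], removes
#' failing calls from the carrier list, and drops variants left with no
#' passing carrier.  Survivors are always a subset of the input.
#'
#' @param x An `ais_cohort`.
#' @param config A [funnel_config()].
#' @return The filtered `ais_cohort`, with `genotype_class` set on every
#'   retained call.
#' @export
qc_high_confidence <- function(x, config = funnel_config()) {
  if (nrow(x$calls)) {
    x$calls$genotype_class <- classify_genotype(x$calls$depth,
                                                x$calls$alt_fraction, config)
    x$calls <- x$calls[x$calls$genotype_class != "fail", , drop = FALSE]
  }
  subset_cohort(x, unique(x$calls$key))
}

#' Recurrence filter
#'
#' Keeps only variants mutated in at least `min_carriers` patients
#' (default two or more), the repeatability filter of the funnel.
#'
#' @inheritParams qc_high_confidence
#' @return The filtered `ais_cohort`.
#' @export
recurrence_filter <- function(x, config = funnel_config()) {
  cc <- carrier_counts(x)
  subset_cohort(x, cc$key[cc$carriers >= config$min_carriers])
}

#' Population allele-frequency filter
#'
#' Removes variants that are common polymorphisms in the reference panels.
#' Under the default `panel_af_mode = "both"`, a variant is removed only
#' when its allele frequency exceeds `panel_af_cutoff` in *every* panel;
#' absence from a panel counts as frequency 0, so single-panel-common
#' variants are kept (and flagged in the `"single_panel_common"`
#' attribute).  `"any"` removes variants common in at least one panel.
#'
#' @inheritParams qc_high_confidence
#' @param panels List of [reference_panel()] objects.
#' @return The filtered `ais_cohort`.
#' @export
population_frequency_filter <- function(x, panels,
                                        config = funnel_config()) {
  panels <- validate_panels(panels)
  keys <- x$variants$key
  afs <- matrix(0, nrow = length(keys), ncol = length(panels),
                dimnames = list(keys, names(panels)))
  for (pid in names(panels)) afs[, pid] <- panel_af(panels[[pid]], keys)
  common <- afs > config$panel_af_cutoff
  remove <- if (config$panel_af_mode == "both") {
    rowSums(common) == length(panels)
  } else {
    rowSums(common) > 0
  }
  out <- subset_cohort(x, keys[!remove])
  # common in >=1 but not all panels: surprising survivors under "both"
  attr(out, "single_panel_common") <-
    keys[!remove & rowSums(common) > 0]
  out
}

#' Deleteriousness-predictor consensus
#'
#' A variant is treated as functional when at least
#' `min_deleterious_votes` (default 2) of the five predictor verdicts
#' (SIFT, PolyPhen2, LRT, FATHMM, MutationTaster) are deleterious.
#' Missing verdicts never count as deleterious votes.
#'
#' @param verdicts `data.frame` (or `ais_cohort`) carrying one normalized
#'   verdict column per tool in [PREDICTOR_TOOLS].
#' @param config A [funnel_config()].
#' @return Logical vector, one element per row/variant.
#' @export
deleterious_consensus <- function(verdicts, config = funnel_config()) {
  if (inherits(verdicts, "ais_cohort")) verdicts <- verdicts$variants
  v <- as.matrix(verdicts[, PREDICTOR_TOOLS, drop = FALSE])
  bad <- !v %in% VERDICT_LEVELS
  if (any(bad)) {
    stop("unnormalized verdict label(s): ",
         paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  }
  rowSums(v == "deleterious") >= config$min_deleterious_votes
}

deleterious_filter <- function(x, config = funnel_config()) {
  keep <- deleterious_consensus(x$variants, config)
  subset_cohort(x, x$variants$key[keep])
}

#' Run the full prioritization funnel
#'
#' Applies, in order: genotype QC, the recurrence filter, the reference-
#' panel population-frequency filter, and the deleteriousness consensus.
#' Returns the surviving candidate set together with a stage-by-stage
#' funnel report and the gene universe (genes carrying at least one
#' variant surviving the population-frequency stage) used downstream for
#' enrichment.
#'
#' @inheritParams population_frequency_filter
#' @return A list with elements `candidates` (`ais_cohort`), `report`
#'   (`data.frame` of class `funnel_report`: `stage, n_in, n_out,
#'   n_dropped`), and `universe` (character vector of gene symbols).
#' @export
run_funnel <- function(x, panels, config = funnel_config()) {
  stages <- list(
    qc_high_confidence = function(d) qc_high_confidence(d, config),
    recurrence = function(d) recurrence_filter(d, config),
    population_frequency = function(d)
      population_frequency_filter(d, panels, config),
    deleterious_consensus = function(d) deleterious_filter(d, config)
  )
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), n_dropped = integer(0),
                       stringsAsFactors = FALSE)
  cur <- x
  universe <- character(0)
  for (nm in names(stages)) {
    n_in <- n_variants(cur)
    cur <- stages[[nm]](cur)
    report <- rbind(report, data.frame(
      stage = nm, n_in = n_in, n_out = n_variants(cur),
      n_dropped = n_in - n_variants(cur), stringsAsFactors = FALSE))
    if (nm == "population_frequency") {
      universe <- sort(unique(cur$variants$gene))
    }
  }
  class(report) <- c("funnel_report", "data.frame")
  list(candidates = cur, report = report, universe = universe)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Variant prioritization funnel:\n")
  cat(sprintf("  %-24s %8s -> %8s  (dropped %d)\n", x$stage, x$n_in,
              x$n_out, x$n_dropped), sep = "")
  invisible(x)
}
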