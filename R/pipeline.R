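## End-to-end orchestration: funnel -> association -> enrichment ->
## clinical screening, with a machine-readable run manifest.

#' Run the full case-only discovery pipeline
#'
#' Applies the prioritization funnel, burden-tests the candidates against
#' every reference panel, classifies them as novel / differential / not
#' associated, runs gene-family enrichment over the genes of associated
#' variants, and (when a clinical table is supplied) screens associated
#' variants against clinical features and intersects the per-feature
#' significant sets.  The gene universe for enrichment is the set of
#' genes carrying at least one variant that survived the population-
#' frequency stage.
#'
#' @param x An `ais_cohort`.
#' @param panels List of [reference_panel()] objects.
#' @param family_map Optional gene-family map `data.frame` (see
#'   [read_family_map()]); `sets` may be given instead.
#' @param sets Optional named list of gene sets (e.g. from [read_gmt()]).
#' @param clinical Optional clinical table.
#' @param config A [funnel_config()].
#' @param alpha Significance level for differential classification,
#'   enrichment and clinical screening.
#' @param panel_sig_mode `"any"` or `"all"` (see [associate_variants()]).
#' @param out_dir Optional directory; when given, result tables are
#'   written through [write_results()].
#' @return List of class `varfunnel_run`: `funnel`, `association`,
#'   `enrichment`, `clinical_screen`, `venn`, `manifest`.
#' @export
run_pipeline <- function(x, panels, family_map = NULL, sets = NULL,
                         clinical = NULL, config = funnel_config(),
                         alpha = 0.05, panel_sig_mode = c("any", "all"),
                         out_dir = NULL) {
  panel_sig_mode <- match.arg(panel_sig_mode)
  fun <- run_funnel(x, panels, config)
  assoc <- associate_variants(fun$candidates, panels,
                              n_cases = length(x$samples), alpha = alpha,
                              min_carriers = config$min_carriers,
                              panel_sig_mode = panel_sig_mode)
  cl <- assoc$classifications
  associated <- if (nrow(cl)) {
    cl[cl$class %in% c("novel", "differential"), , drop = FALSE]
  } else cl

  enr <- NULL
  if (is.null(sets) && !is.null(family_map)) sets <- family_sets(family_map)
  if (!is.null(sets) && nrow(associated)) {
    genes <- intersect(unique(associated$gene), fun$universe)
    if (length(genes)) {
      enr <- enrich_gene_sets(genes, sets, fun$universe, alpha = alpha)
    }
  }

  screen <- venn <- NULL
  if (!is.null(clinical) && nrow(associated)) {
    assoc_cohort <- subset_cohort(fun$candidates, associated$key)
    screen <- suppressWarnings(
      variant_feature_screen(assoc_cohort, clinical, alpha = alpha))
    sig_sets <- significant_variant_sets(screen)
    venn <- intersect_variant_sets(sig_sets)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("varfunnel")),
    n_samples = length(x$samples),
    funnel = fun$report,
    n_candidates = n_variants(fun$candidates),
    n_novel = sum(cl$class == "novel"),
    n_differential = sum(cl$class == "differential"),
    n_associated_genes = length(unique(associated$gene)),
    top_family = if (!is.null(enr) && nrow(enr)) enr$set_id[1] else NA,
    alpha = alpha, panel_sig_mode = panel_sig_mode,
    config = unclass(config))

  run <- structure(list(funnel = fun, association = assoc,
                        enrichment = enr, clinical_screen = screen,
                        venn = venn, manifest = manifest),
                   class = "varfunnel_run")
  if (!is.null(out_dir)) {
    write_results(list(candidates = fun$candidates$variants,
                       association = assoc$tests,
                       enrichment = if (is.null(enr))
                         data.frame() else enr,
                       funnel_report = fun$report), out_dir)
    jsonlite::write_json(manifest[setdiff(names(manifest), "funnel")],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, force = TRUE)
  }
  run
}

#' Human-readable summary of a pipeline run
#'
#' Tabulates the funnel stage counts, the top associated variants, the
#' top enriched gene families and the clinical Venn counts.
#'
#' @param run A `varfunnel_run`.
#' @param n_top Rows shown per section.
#' @return Character vector of report lines, invisibly (also printed).
#' @export
pipeline_report <- function(run, n_top = 5) {
  stopifnot(inherits(run, "varfunnel_run"))
  m <- run$manifest
  lines <- c("== varfunnel run report ==",
             sprintf("cohort: %d samples", m$n_samples))
  rep_df <- run$funnel$report
  lines <- c(lines, "funnel:",
             sprintf("  %-24s %7d -> %7d", rep_df$stage, rep_df$n_in,
                     rep_df$n_out),
             sprintf("candidates: %d (%d novel, %d differential; %d genes)",
                     m$n_candidates, m$n_novel, m$n_differential,
                     m$n_associated_genes))
  cl <- run$association$classifications
  if (!is.null(cl) && nrow(cl)) {
    top <- utils::head(cl[cl$class != "not_associated", ], n_top)
    lines <- c(lines, "top associated variants:",
               sprintf("  %s  %s  carriers=%d  q=%s  [%s]", top$key,
                       top$gene, top$carriers,
                       ifelse(is.na(top$min_q), "NA",
                              formatC(top$min_q, format = "e", digits = 2)),
                       top$class))
  }
  if (!is.null(run$enrichment) && nrow(run$enrichment)) {
    top <- utils::head(run$enrichment, n_top)
    lines <- c(lines, "top enriched gene families:",
               sprintf("  %-24s k=%d/%d  -log10(FDR)=%.2f", top$set_id,
                       top$k, top$K, top$neg_log10_q))
  }
  if (!is.null(run$venn)) {
    lines <- c(lines,
               sprintf("clinical venn: union=%d, shared by all=%d (%.1f%%)",
                       run$venn$n_union, run$venn$shared_by_all,
                       run$venn$shared_by_all_pct))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.varfunnel_run <- function(x, ...) {
  pipeline_report(x)
  invisible(x)
}
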