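## Readers and writers for every file the pipeline touches.  Validation is
## strict; recoverable irregularities (multiallelic or non-SNV records)
## are excluded and returned as warnings-as-data in a "warnings" attribute.

## ---- cohort VCF -----------------------------------------------------------

#' Write a cohort to a minimal VCF 4.2 file
#'
#' Emits one column per cohort sample; carriers get `GT:DP:AD` calls
#' (alternate-allele depth quantizes the read-level alt fraction),
#' non-carriers `./.`.
#'
#' @param x An `ais_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(x, path) {
  v <- x$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varfunnel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  gt <- matrix("./.", nrow = nrow(v), ncol = length(x$samples),
               dimnames = list(v$key, x$samples))
  if (nrow(x$calls)) {
    alt_ad <- round_half_up(x$calls$depth * x$calls$alt_fraction)
    gt[cbind(x$calls$key, x$calls$sample_id)] <-
      sprintf("0/1:%d:%d,%d", x$calls$depth,
              x$calls$depth - alt_ad, alt_ad)
  }
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                "GT:DP:AD",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (!nrow(v)) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort VCF (minimal VCF 4.2 subset)
#'
#' Parses through `vcfR`.  Multiallelic records, records with non-single-
#' base alleles (indels/MNVs) and records whose REF equals ALT are
#' excluded and counted in the `warnings` attribute — the pipeline is
#' defined over single-nucleotide variants with one altered nucleotide.
#' The per-sample alternate-allele fraction is `alt AD / total AD`.
#'
#' @param path VCF path; must carry a `##fileformat=VCFv4` header line and
#'   FORMAT fields `DP` and `AD`.
#' @return List with `variants` (`data.frame`: `key, chrom, pos, ref,
#'   alt`), `calls` (`key, sample_id, depth, alt_fraction`), `samples`,
#'   and attribute `warnings` (character vector).
#' @export
read_cohort_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 200L)
  if (!any(grepl("^##fileformat=VCFv4", head_lines))) {
    stop("parse error: missing ##fileformat=VCFv4 header line in ", path,
         call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  warnings <- character(0)
  if (!nrow(fix)) {
    return(structure(list(
      variants = data.frame(key = character(0), chrom = character(0),
                            pos = integer(0), ref = character(0),
                            alt = character(0)),
      calls = data.frame(key = character(0), sample_id = character(0),
                         depth = integer(0), alt_fraction = numeric(0)),
      samples = colnames(vcf@gt)[-1]), warnings = warnings))
  }
  fmt <- vcf@gt[, "FORMAT"]
  fmt_keys <- unique(unlist(strsplit(fmt, ":")))
  for (need in c("DP", "AD")) {
    if (!need %in% fmt_keys) {
      stop("parse error: FORMAT field ", need, " absent from records of ",
           path, call. = FALSE)
    }
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warnings <- c(warnings,
                  sprintf("%d multiallelic record(s) excluded", sum(multi)))
  }
  snv <- !multi & fix$REF %in% VARIANT_BASES & fix$ALT %in% VARIANT_BASES &
    fix$REF != fix$ALT
  non_snv <- !multi & !snv
  if (any(non_snv)) {
    warnings <- c(warnings,
                  sprintf("%d non-SNV record(s) excluded", sum(non_snv)))
  }
  keep <- which(snv)
  variants <- data.frame(
    key = variant_key(fix$CHROM[keep], as.integer(fix$POS[keep]),
                      fix$REF[keep], fix$ALT[keep]),
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep], stringsAsFactors = FALSE)

  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)[keep, , drop = FALSE]
  ad <- vcfR::extract.gt(vcf, "AD")[keep, , drop = FALSE]
  samples <- colnames(dp)
  calls <- NULL
  if (length(keep)) {
    idx <- which(!is.na(ad), arr.ind = TRUE)
    if (nrow(idx)) {
      parts <- strsplit(ad[idx], ",")
      ref_ad <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
      alt_ad <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
      tot <- ref_ad + alt_ad
      calls <- data.frame(
        key = variants$key[idx[, 1]],
        sample_id = samples[idx[, 2]],
        depth = as.integer(dp[idx]),
        alt_fraction = ifelse(tot > 0, alt_ad / tot, 0),
        stringsAsFactors = FALSE)
      calls <- calls[alt_ad > 0, , drop = FALSE]   # carriers only
      rownames(calls) <- NULL
    }
  }
  if (is.null(calls)) {
    calls <- data.frame(key = character(0), sample_id = character(0),
                        depth = integer(0), alt_fraction = numeric(0))
  }
  structure(list(variants = variants, calls = calls, samples = samples),
            warnings = warnings)
}

## ---- annotation sidecar ---------------------------------------------------

#' Write / read the annotation sidecar TSV
#'
#' Columns `chrom, pos, ref, alt, gene, consequence` plus one column per
#' predictor tool carrying the tool's native verdict label.
#' `read_annotation_tsv()` normalizes labels onto
#' `{deleterious, tolerated, missing}` (see [normalize_verdict()]).
#'
#' @param annotation Annotation `data.frame` (native labels).
#' @param path File path.
#' @return `read_annotation_tsv`: normalized annotation `data.frame` with
#'   a `key` column.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            PREDICTOR_TOOLS)
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotation TSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann$pos <- as.integer(ann$pos)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$key)) {
    stop("duplicate variant keys in annotation TSV", call. = FALSE)
  }
  for (tool in PREDICTOR_TOOLS) {
    ann[[tool]] <- normalize_verdict(ann[[tool]], tool)
  }
  ann[c("key", "chrom", "pos", "ref", "alt", "gene", "consequence",
        PREDICTOR_TOOLS)]
}

#' Assemble an `ais_cohort` from a VCF and its annotation sidecar
#'
#' @param vcf_path Cohort VCF path.
#' @param annotation_path Annotation sidecar TSV path.
#' @return An `ais_cohort`; reader warnings propagate in the `warnings`
#'   attribute.  Variants without annotation are an error (every cohort
#'   variant must carry a gene assignment and predictor verdicts).
#' @export
read_cohort <- function(vcf_path, annotation_path) {
  raw <- read_cohort_vcf(vcf_path)
  ann <- read_annotation_tsv(annotation_path)
  hit <- match(raw$variants$key, ann$key)
  if (anyNA(hit)) {
    stop("variant(s) missing from annotation sidecar: ",
         paste(utils::head(raw$variants$key[is.na(hit)], 3),
               collapse = ", "), call. = FALSE)
  }
  variants <- cbind(raw$variants,
                    ann[hit, c("gene", "consequence", PREDICTOR_TOOLS)])
  rownames(variants) <- NULL
  out <- cohort(variants, raw$calls, raw$samples)
  attr(out, "warnings") <- attr(raw, "warnings")
  out
}

## ---- panel TSV ------------------------------------------------------------

#' Write / read a reference-panel allele-frequency TSV
#'
#' Columns `chrom, pos, ref, alt, af`.  Frequencies outside `[0, 1]` and
#' duplicate variant rows are validation errors.
#'
#' @param panel A [reference_panel()] (for writing).
#' @param path File path.
#' @param panel_id,n_samples Panel identity and diploid sample count
#'   (metadata that frequency downloads do not carry).
#' @return `read_panel_tsv`: a [reference_panel()].
#' @export
write_panel_tsv <- function(panel, path) {
  keys <- names(panel$af)
  parts <- strsplit(keys, "[:>]")
  df <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    af = unname(panel$af), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path, panel_id, n_samples) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "af")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel TSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$af <- as.numeric(df$af)
  if (any(is.na(df$af) | df$af < 0 | df$af > 1)) {
    stop("panel af outside [0, 1]", call. = FALSE)
  }
  key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key)) {
    stop("duplicate variant rows in panel TSV", call. = FALSE)
  }
  reference_panel(panel_id, n_samples, stats::setNames(df$af, key))
}

## ---- gene-family map and GMT ----------------------------------------------

#' Read an HGNC-style gene-family map
#'
#' TSV with columns `gene, family_id, family_name`; many-to-many
#' memberships are retained (a gene may belong to several families).
#'
#' @param path File path.
#' @return `data.frame` with those three columns.
#' @export
read_family_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene", "family_id", "family_name")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("family map lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df[!duplicated(df[c("gene", "family_id")]), need]
}

#' @rdname read_family_map
#' @param family_map Family-map `data.frame` (for writing).
#' @export
write_family_map <- function(family_map, path) {
  utils::write.table(family_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Each GMT line is `set_name <tab> description <tab> gene1 <tab> ...`;
#' lines with fewer than three tab-separated fields are a parse error.
#' Reading delegates to [fgsea::gmtPathways()] after validation.
#'
#' @param path File path.
#' @return `read_gmt`: named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf < 3)) {
    stop("GMT parse error: line ", which(nf < 3)[1],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors (for writing).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- clinical CSV ---------------------------------------------------------

#' Read / write the clinical table CSV
#'
#' Columns `patient_id, sex, age, cobb, shape, direction, apex_class,
#' tilted_count, lenke`; categorical values outside their domains are a
#' validation error naming row and field.
#'
#' @param path File path.
#' @return `read_clinical_csv`: validated clinical `data.frame`.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(apex_class = "character",
                                       lenke = "character"))
  df$apex_class <- as.character(df$apex_class)
  df$lenke <- as.character(df$lenke)
  validate_clinical(df)
  df
}

#' @rdname read_clinical_csv
#' @param clinical Clinical `data.frame` (for writing).
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- synthetic dataset bundle --------------------------------------------

#' Write a synthetic dataset to a directory
#'
#' Emits `cohort.vcf`, `annotation.tsv`, `panel_<id>.tsv` per panel,
#' `clinical.csv`, `family_map.tsv` and `truth.json`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    family_map = file.path(dir, "family_map.tsv"),
    truth = file.path(dir, "truth.json"))
  write_cohort_vcf(dataset$cohort, paths["vcf"])
  write_annotation_tsv(dataset$annotation, paths["annotation"])
  write_clinical_csv(dataset$clinical, paths["clinical"])
  write_family_map(dataset$family_map, paths["family_map"])
  for (pid in names(dataset$panels)) {
    p <- file.path(dir, paste0("panel_", pid, ".tsv"))
    write_panel_tsv(dataset$panels[[pid]], p)
    paths[paste0("panel_", pid)] <- p
  }
  truth <- dataset$truth
  jsonlite::write_json(
    list(planted_novel_ids = truth$planted_novel_ids,
         planted_differential_ids = truth$planted_differential_ids,
         planted_family = truth$planted_family),
    paths["truth"], auto_unbox = FALSE)
  invisible(paths)
}

## ---- result tables --------------------------------------------------------

#' Write pipeline result tables
#'
#' Emits TSVs for the association and enrichment tables, the candidate
#' variant table, and a JSON funnel report.
#'
#' @param results Named list with any of `candidates` (`data.frame`),
#'   `association` (`data.frame`), `enrichment` (`data.frame`),
#'   `funnel_report` (`data.frame`).
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tsv <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  for (nm in intersect(c("candidates", "association", "enrichment"),
                       names(results))) {
    paths[nm] <- tsv(as.data.frame(results[[nm]]), nm)
  }
  if ("funnel_report" %in% names(results)) {
    p <- file.path(dir, "funnel_report.json")
    jsonlite::write_json(as.data.frame(results$funnel_report), p,
                         dataframe = "rows")
    paths["funnel_report"] <- p
  }
  invisible(paths)
}
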