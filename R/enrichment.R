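## Hypergeometric over-representation of candidate genes in gene families
## (HGNC-style map) or gene sets (GMT), ranked by -log10(FDR).

NEG_LOG10_FLOOR <- 1e-300  # q clipped here before log10, avoids Inf ranks

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts how many of `n` genes drawn without
#' replacement from a universe of `N` genes fall into a family of size
#' `K`.  Computed through [stats::phyper()] (log-space internally), so it
#' is stable for exome-scale universes.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Family size within the universe.
#' @param n Number of candidate genes drawn.
#' @param N Universe size.
#' @return Probability in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeometric_upper_tail(5, 5, 5, 20)   # 1 / choose(20, 5)
hypergeometric_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (!(k >= 0 && K >= 0 && n >= 0 && N >= 1 && K <= N && n <= N &&
        k <= min(K, n))) {
    stop("require 0 <= k <= min(K, n), K <= N, n <= N", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Convert a gene -> family map into named gene sets
#'
#' @param family_map `data.frame` with columns `gene, family_id` (and
#'   optionally `family_name`).  Many-to-many membership is allowed; a
#'   gene counts once per family.
#' @return Named list of unique gene vectors, names = family ids, with a
#'   `family_names` attribute when names are available.
#' @export
family_sets <- function(family_map) {
  stopifnot(all(c("gene", "family_id") %in% names(family_map)))
  sets <- lapply(split(family_map$gene, family_map$family_id), unique)
  if ("family_name" %in% names(family_map)) {
    nm <- family_map$family_name[!duplicated(family_map$family_id)]
    names(nm) <- family_map$family_id[!duplicated(family_map$family_id)]
    attr(sets, "family_names") <- nm[names(sets)]
  }
  sets
}

#' Hypergeometric gene-set / gene-family enrichment
#'
#' Tests whether candidate genes over-represent each gene set, using the
#' upper-tail hypergeometric probability with the set intersected with the
#' universe before its size `K` is computed.  Only sets with `K >= 1` and
#' observed overlap `k >= 1` are tested (unless `include_empty`); BH
#' correction is applied across all tested sets, and results are ranked by
#' `-log10(q)` descending (ties: larger overlap first, then set id).
#'
#' @param candidate_genes Character vector of candidate gene symbols;
#'   must be a subset of `universe`.
#' @param sets Named list of gene vectors (see [family_sets()],
#'   [read_gmt()]).
#' @param universe Character vector: the gene universe (e.g. genes
#'   carrying at least one variant surviving the population-frequency
#'   stage).
#' @param alpha Significance level recorded in the `significant` column.
#' @param include_empty Also report untested sets (k = 0 or K = 0) with
#'   p = 1.
#' @return `data.frame` of class `enrichment_result`: `set_id, set_name,
#'   k, K, n, N, p, q, neg_log10_q, significant, genes` (overlap genes,
#'   comma-separated).
#' @export
enrich_gene_sets <- function(candidate_genes, sets, universe,
                             alpha = 0.05, include_empty = FALSE) {
  universe <- unique(universe)
  candidate_genes <- unique(candidate_genes)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  stray <- setdiff(candidate_genes, universe)
  if (length(stray)) {
    stop("candidate gene(s) outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(sets)) || !length(sets)) {
    stop("sets must be a non-empty named list", call. = FALSE)
  }
  set_names <- attr(sets, "family_names")
  N <- length(universe)
  n <- length(candidate_genes)
  res <- lapply(names(sets), function(id) {
    in_univ <- intersect(unique(sets[[id]]), universe)
    overlap <- intersect(in_univ, candidate_genes)
    data.frame(set_id = id,
               set_name = if (!is.null(set_names)) unname(set_names[id])
                          else id,
               k = length(overlap), K = length(in_univ), n = n, N = N,
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  tested <- res$K >= 1 & res$k >= 1
  res$p <- 1
  res$p[tested] <- mapply(hypergeometric_upper_tail,
                          res$k[tested], res$K[tested],
                          res$n[tested], res$N[tested])
  res$q <- NA_real_
  if (any(tested)) res$q[tested] <- bh_fdr(res$p[tested])
  if (!include_empty) res <- res[tested, , drop = FALSE]
  res$neg_log10_q <- -log10(pmax(res$q, NEG_LOG10_FLOOR))
  res$significant <- !is.na(res$q) & res$q < alpha
  ord <- order(-ifelse(is.na(res$neg_log10_q), -1, res$neg_log10_q),
               -res$k, res$set_id)
  res <- res[ord, c("set_id", "set_name", "k", "K", "n", "N", "p", "q",
                    "neg_log10_q", "significant", "genes")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Enrichment per clinical feature
#'
#' Maps each clinical feature's significant-variant set to its gene list
#' and runs [enrich_gene_sets()] per feature, adding the reporting columns
#' `neg_log10_p` and `gene_ratio` (k / n) used for dot-plot style
#' summaries.
#'
#' @param feature_variant_sets Named list: feature -> character vector of
#'   significant variant keys.
#' @param variant_genes `data.frame` with columns `key, gene` mapping
#'   variants to gene symbols.
#' @param sets,universe,alpha Passed to [enrich_gene_sets()].
#' @return Named list of enrichment tables (one per feature; empty
#'   variant set gives an empty table).
#' @export
enrich_by_feature <- function(feature_variant_sets, variant_genes, sets,
                              universe, alpha = 0.05) {
  stopifnot(all(c("key", "gene") %in% names(variant_genes)))
  lapply(feature_variant_sets, function(keys) {
    genes <- unique(variant_genes$gene[variant_genes$key %in% keys])
    genes <- intersect(genes, universe)
    if (!length(genes)) {
      out <- data.frame(set_id = character(0), set_name = character(0),
                        k = integer(0), K = integer(0), n = integer(0),
                        N = integer(0), p = numeric(0), q = numeric(0),
                        neg_log10_q = numeric(0), significant = logical(0),
                        genes = character(0), neg_log10_p = numeric(0),
                        gene_ratio = numeric(0), stringsAsFactors = FALSE)
      class(out) <- c("enrichment_result", "data.frame")
      return(out)
    }
    out <- enrich_gene_sets(genes, sets, universe, alpha = alpha)
    out$neg_log10_p <- -log10(pmax(out$p, NEG_LOG10_FLOOR))
    out$gene_ratio <- ifelse(out$n > 0, out$k / out$n, NA_real_)
    out
  })
}
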