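# Decay-factor target calling from paired control/knockdown half-lives and
# expression, class-intersection statistics, and gene-set enrichment with
# Benjamini-Hochberg correction.

#' Call decay-factor targets from control/knockdown fold changes
#'
#' A gene is a target when both its half-life fold change (knockdown over
#' control) and its expression fold change reach the factor's thresholds
#' (>= semantics; ties at exactly the threshold are included).  Defaults
#' are 2.0-fold for UPF1/EXOSC5-style factors and 1.5-fold for STAU1-style
#' factors.  Genes with an invalid half-life in either condition, or
#' non-positive control values, are excluded with a reason.
#'
#' @param ctrl_halflives,kd_halflives Half-life record tables
#'   ([fit_all()] output) for control and knockdown.
#' @param ctrl_expr,kd_expr Expression tables (first non-`gene_id` column
#'   used), or `NULL` to waive the expression criterion (used for eRNA
#'   stabilization calls, which rest on half-life alone).
#' @param hl_fold_min Half-life fold threshold.
#' @param expr_fold_min Expression fold threshold.
#' @return A `data.frame`: `gene_id`, `halflife_fold`, `expr_fold`,
#'   `is_target`, `excluded`, `reason`.
#' @export
call_targets <- function(ctrl_halflives, kd_halflives,
                         ctrl_expr = NULL, kd_expr = NULL,
                         hl_fold_min = 2, expr_fold_min = hl_fold_min) {
  genes <- intersect(ctrl_halflives$gene_id, kd_halflives$gene_id)
  ci <- match(genes, ctrl_halflives$gene_id)
  ki <- match(genes, kd_halflives$gene_id)
  out <- data.frame(gene_id = genes,
                    halflife_fold = NA_real_, expr_fold = NA_real_,
                    is_target = FALSE, excluded = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  bad_hl <- !ctrl_halflives$valid[ci] | !kd_halflives$valid[ki]
  out$excluded[bad_hl] <- TRUE
  out$reason[bad_hl] <- "invalid half-life in a condition"
  ok <- !bad_hl
  out$halflife_fold[ok] <- kd_halflives$t_half[ki[ok]] /
    ctrl_halflives$t_half[ci[ok]]

  use_expr <- !is.null(ctrl_expr) && !is.null(kd_expr)
  if (use_expr) {
    cv <- .expr_values(ctrl_expr)[genes]
    kv <- .expr_values(kd_expr)[genes]
    bad_e <- is.na(cv) | is.na(kv) | cv <= 0
    newly <- bad_e & !out$excluded
    out$excluded[newly] <- TRUE
    out$reason[newly] <- "missing or non-positive control expression"
    okE <- !out$excluded
    out$expr_fold[okE] <- kv[okE] / cv[okE]
    out$is_target <- !out$excluded &
      out$halflife_fold >= hl_fold_min & out$expr_fold >= expr_fold_min
  } else {
    out$is_target <- !out$excluded & out$halflife_fold >= hl_fold_min
  }
  out
}

.expr_values <- function(expr) {
  col <- setdiff(names(expr), "gene_id")[1L]
  setNames(expr[[col]], expr$gene_id)
}

#' Fraction of a gene class covered by a target set
#'
#' @param targets Character vector of target gene ids (or a
#'   [call_targets()] table, in which case `is_target` rows are used).
#' @param class_members Character vector of class member ids (non-empty).
#' @return A list: `count` (targets within the class), `class_size`,
#'   `percent` (rounded to one decimal, two significant figures below 1%).
#' @export
class_fraction <- function(targets, class_members) {
  if (length(class_members) == 0L) stop("empty gene class")
  if (is.data.frame(targets)) targets <- targets$gene_id[targets$is_target]
  count <- length(intersect(targets, class_members))
  pct <- 100 * count / length(class_members)
  pct <- if (pct < 1) signif(pct, 2L) else round(pct, 1L)
  list(count = count, class_size = length(class_members), percent = pct)
}

#' Overlap between two target sets
#'
#' @param targets_a,targets_b Character vectors of gene ids.
#' @return A list: `n_a`, `n_b`, `n_intersect`, `jaccard`.
#' @export
overlap_sets <- function(targets_a, targets_b) {
  a <- unique(targets_a); b <- unique(targets_b)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(n_a = length(a), n_b = length(b), n_intersect = inter,
       jaccard = if (uni == 0L) NA_real_ else inter / uni)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n genes from a
#' universe of N containing K marked genes.
#'
#' @param k Observed hits in the draw.
#' @param K Marked genes in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeometric_p <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n), k <= min(K, n))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues Numeric vector of p-values.
#' @return q-values in the input order, clipped at 1 and monotone under
#'   the step-up ordering.
#' @export
bh_fdr <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Gene-set (GO-style) enrichment by hypergeometric test
#'
#' Tests each term for over-representation in `gene_set` against
#' `universe`, Benjamini-Hochberg corrected over all tested terms; results
#' are then filtered to terms with more than `min_genes` hits and
#' `fdr <= fdr_max`, sorted by FDR.
#'
#' @param gene_set Character vector of selected genes.
#' @param universe Character vector of all analyzable genes.
#' @param term_map `data.frame` with columns `gene_id`, `term_id` (flat
#'   mapping, no ontology propagation).
#' @param min_genes Minimum hits per reported term (strictly more than
#'   this many genes required).
#' @param fdr_max FDR ceiling for reported terms.
#' @return A `data.frame`: `term_id`, `k`, `K`, `n`, `N`, `p`, `fdr`,
#'   filtered and sorted; the unfiltered table is attached as attribute
#'   `"all_terms"`.
#' @export
gene_set_enrichment <- function(gene_set, universe, term_map,
                                min_genes = 10L, fdr_max = 0.05) {
  gene_set <- intersect(unique(gene_set), universe)
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(gene_set)
  terms <- unique(tm$term_id)
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric()))
  }
  res <- do.call(rbind, lapply(terms, function(tt) {
    members <- unique(tm$gene_id[tm$term_id == tt])
    k <- length(intersect(members, gene_set))
    data.frame(term_id = tt, k = k, K = length(members), n = n, N = N,
               p = hypergeometric_p(k, length(members), n, N),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_fdr(res$p)
  keep <- res[res$k > min_genes & res$fdr <= fdr_max, , drop = FALSE]
  keep <- keep[order(keep$fdr, keep$p), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "all_terms") <- res
  keep
}
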