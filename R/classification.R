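# Quadrant classification of genes by chromatin state vs measured RNA,
# regression-band membership around the log-log expression ~ H3K4me3 line,
# default-half-life estimation, and the association statistics.

#' Default classification thresholds
#'
#' H3K4me3 intensity above 1e4 tags plus a pol II peak defines ChIP(+);
#' RPKM above 10 defines RNA(+); half-lives under 4 h are "short".
#'
#' @param h3k4me3 H3K4me3 tag-count threshold.
#' @param rpkm RPKM threshold.
#' @param short_halflife Short half-life cut-off in hours.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(h3k4me3 = 1e4, rpkm = 10, short_halflife = 4) {
  list(h3k4me3 = h3k4me3, rpkm = rpkm, short_halflife = short_halflife)
}

#' Classify genes into ChIP/RNA quadrants
#'
#' ChIP status is `plus` when the H3K4me3 intensity exceeds the threshold
#' AND a pol II peak is present, `minus` when the intensity is below the
#' threshold AND no pol II peak is present, and `ambiguous` otherwise
#' (mixed signals; excluded from quadrant statistics).  RNA status is
#' `plus` iff RPKM exceeds the threshold.  The short-half-life flag is set
#' only where a valid half-life exists (NA otherwise).
#'
#' @param profiles A `gene_chip_profile` table.
#' @param expression Expression table; the `condition` column is used.
#' @param halflives Half-life record table from [fit_all()] (or `NULL`).
#' @param thresholds A list from [default_thresholds()].
#' @param condition Expression column to classify on.
#' @return A `data.frame`: `gene_id`, `chip_status`, `rna_status`,
#'   `short_halflife`, `t_half`, `h3k4me3_intensity`, `rpkm`.
#' @export
classify <- function(profiles, expression, halflives = NULL,
                     thresholds = default_thresholds(),
                     condition = setdiff(names(expression), "gene_id")[1L]) {
  for (nm in c("h3k4me3", "rpkm", "short_halflife")) {
    if (is.null(thresholds[[nm]])) stop("missing threshold: ", nm)
  }
  m <- merge(profiles[c("gene_id", "h3k4me3_intensity", "polii_peak")],
             expression[c("gene_id", condition)], by = "gene_id")
  names(m)[names(m) == condition] <- "rpkm"
  hi <- m$h3k4me3_intensity > thresholds$h3k4me3
  lo <- m$h3k4me3_intensity < thresholds$h3k4me3
  m$chip_status <- ifelse(hi & m$polii_peak, "plus",
                          ifelse(lo & !m$polii_peak, "minus", "ambiguous"))
  m$rna_status <- ifelse(m$rpkm > thresholds$rpkm, "plus", "minus")
  m$t_half <- NA_real_
  m$short_halflife <- NA
  if (!is.null(halflives)) {
    i <- match(m$gene_id, halflives$gene_id)
    ok <- !is.na(i) & halflives$valid[ifelse(is.na(i), 1L, i)]
    m$t_half[ok] <- halflives$t_half[i[ok]]
    m$short_halflife[ok] <- m$t_half[ok] < thresholds$short_halflife
  }
  m[c("gene_id", "chip_status", "rna_status", "short_halflife", "t_half",
      "h3k4me3_intensity", "rpkm")]
}

#' Least-squares regression of log expression on log H3K4me3 intensity
#'
#' Fitted on the ChIP(+)/RNA(+) subset in log10 space; returns the Pearson
#' correlation of the same pairs.
#'
#' @param intensity,rpkm Positive vectors (same genes).
#' @return A list of class `regression_fit`: `slope`, `intercept` (log10
#'   space), `pearson_r`, `n`.
#' @export
fit_expression_regression <- function(intensity, rpkm) {
  ok <- is.finite(intensity) & is.finite(rpkm) & intensity > 0 & rpkm > 0
  if (sum(ok) < 3L) stop("need >= 3 genes with positive intensity and RPKM")
  x <- log10(intensity[ok]); y <- log10(rpkm[ok])
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 pearson_r = cor(x, y), n = sum(ok)),
            class = "regression_fit")
}

#' Is a gene within a fold band of the regression line?
#'
#' TRUE iff |log10(rpkm) - (intercept + slope * log10(intensity))| <=
#' log10(fold); symmetric above and below the line.
#'
#' @param fit A `regression_fit`.
#' @param intensity,rpkm Gene values (vectorized).
#' @param fold Band fold (e.g. 2 or 1.1); `fold = 1` keeps only points
#'   exactly on the line.
#' @return Logical vector.
#' @export
band_membership <- function(fit, intensity, rpkm, fold) {
  pred <- fit$intercept + fit$slope * log10(intensity)
  abs(log10(rpkm) - pred) <= log10(fold)
}

#' Default half-life: median over band genes
#'
#' Median half-life of ChIP(+)/RNA(+) genes lying within the given fold of
#' the expression ~ intensity regression line.  This is the counterfactual
#' half-life used by the steady-state simulation (approximately 10.9 h in
#' the emulated study conditions for the x1.1 band).
#'
#' @param classifications Output of [classify()] (needs `t_half`).
#' @param fit A `regression_fit` from the ChIP+/RNA+ subset.
#' @param fold Band fold.
#' @return Median half-life in hours.
#' @export
default_halflife <- function(classifications, fit, fold) {
  cc <- classifications
  in_quad <- cc$chip_status == "plus" & cc$rna_status == "plus" &
    !is.na(cc$t_half)
  sub <- cc[in_quad, , drop = FALSE]
  inband <- band_membership(fit, sub$h3k4me3_intensity, sub$rpkm, fold)
  if (!any(inband)) stop("no band genes with valid half-lives")
  median(sub$t_half[inband])
}

#' Contingency table of peak strata against expression cuts
#'
#' Counts genes by H3K4me3 peak stratum (`no`, `low`, `high`) and
#' expression cut (> each RPKM threshold), with each stratum's share of the
#' genes passing the cut.  All-zero cuts give NA percentages.
#'
#' @param stratum Character vector in `{"no", "low", "high"}` per gene.
#' @param rpkm RPKM per gene.
#' @param cuts RPKM cut-offs (default `c(1, 10)`).
#' @return A list with `counts` (matrix strata x cuts, plus a `total` row
#'   and an `all` column of stratum sizes) and `percent` (stratum share of
#'   each cut's total, in %).
#' @export
quadrant_table <- function(stratum, rpkm, cuts = c(1, 10)) {
  stratum <- factor(stratum, levels = c("no", "low", "high"))
  counts <- vapply(cuts, function(ct) {
    as.integer(table(stratum[rpkm > ct]))
  }, integer(3L))
  counts <- cbind(as.integer(table(stratum)), counts)
  colnames(counts) <- c("all", paste0("gt", cuts))
  rownames(counts) <- levels(stratum)
  totals <- colSums(counts)
  percent <- sweep(counts, 2L, totals, "/") * 100
  percent[, totals == 0] <- NA_real_
  counts <- rbind(counts, total = totals)
  list(counts = counts, percent = percent)
}

#' Enrichment of short-lived genes in the ChIP+/RNA- quadrant
#'
#' One-sided hypergeometric (Fisher) upper-tail test of short-half-life
#' genes among ChIP(+)/RNA(-) genes, against the universe of genes with
#' measured half-lives.
#'
#' @param classifications Output of [classify()]; rows without a measured
#'   half-life are dropped.
#' @return A list: `p_value`, `k` (short in quadrant), `K` (short total),
#'   `n` (quadrant size), `N` (measured universe).
#' @export
short_halflife_enrichment <- function(classifications) {
  cc <- classifications[!is.na(classifications$short_halflife), , drop = FALSE]
  in_quad <- cc$chip_status == "plus" & cc$rna_status == "minus"
  k <- sum(in_quad & cc$short_halflife)
  K <- sum(cc$short_halflife)
  n <- sum(in_quad)
  N <- nrow(cc)
  list(p_value = hypergeometric_p(k, K, n, N), k = k, K = K, n = n, N = N)
}

#' Pairwise rank tests between adjacent bins
#'
#' Two-sample Wilcoxon rank-sum test between each pair of adjacent bins,
#' Benjamini-Hochberg adjusted.  Bins with fewer than 2 values are refused
#' with a warning (NA p-value).
#'
#' @param values_by_bin Named list of numeric vectors, in bin order.
#' @return A `data.frame`: `bin_a`, `bin_b`, `p_value`, `p_adjusted`.
#' @export
bin_comparison <- function(values_by_bin) {
  nb <- length(values_by_bin)
  if (nb < 2L) stop("need >= 2 bins")
  nm <- names(values_by_bin)
  if (is.null(nm)) nm <- as.character(seq_len(nb))
  p <- vapply(seq_len(nb - 1L), function(i) {
    a <- values_by_bin[[i]]; b <- values_by_bin[[i + 1L]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("bin with < 2 values: test refused for ", nm[i], " vs ",
              nm[i + 1L])
      return(NA_real_)
    }
    suppressWarnings(wilcox.test(a, b)$p.value)
  }, numeric(1L))
  data.frame(bin_a = nm[-nb], bin_b = nm[-1L], p_value = p,
             p_adjusted = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
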