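# Steady-state simulation of expression under counterfactual half-lives
# and the histone-mark linear models of expression (with and without a
# decay term).
#
# Under first-order decay at steady state, abundance = synthesis / lambda,
# i.e. RPKM is proportional to k_syn * t_half.  "Normalizing the half-life"
# to a default value is therefore the multiplicative rescaling
# predicted = measured * (t_default / t_half).

#' Predict expression at a counterfactual default half-life
#'
#' @param rpkm Measured RPKM.
#' @param t_half Fitted half-life (h); must be valid and positive.
#' @param t_default Counterfactual half-life (h), e.g. the 10.9 h default.
#' @return Predicted RPKM (`rpkm * t_default / t_half`).
#' @export
predict_at_default <- function(rpkm, t_half, t_default) {
  if (any(!is.finite(t_half) | t_half <= 0)) {
    stop("t_half must be finite and positive; exclude invalid genes first")
  }
  rpkm * (t_default / t_half)
}

#' Predict knockdown expression from the half-life change
#'
#' @param rpkm_ctrl Control RPKM.
#' @param t_ctrl,t_kd Control and knockdown half-lives (h).
#' @return Predicted knockdown RPKM (`rpkm_ctrl * t_kd / t_ctrl`).
#' @export
predict_knockdown <- function(rpkm_ctrl, t_ctrl, t_kd) {
  predict_at_default(rpkm_ctrl, t_ctrl, t_kd)
}

#' Steady-state simulation at the default half-life
#'
#' Rescales every measured RPKM to the default half-life, refits the
#' log-log regression of predicted expression on H3K4me3 intensity, and
#' counts genes within each fold band of that line.  "Rescued" genes are
#' within a band under prediction but outside the same band for their
#' measured expression (judged against the same predicted-fit line).
#'
#' @param expression Expression table (control condition used).
#' @param halflives Half-life records from [fit_all()]; invalid fits are
#'   excluded.
#' @param intensity Named vector (or `gene_id`-keyed table) of H3K4me3
#'   intensities.
#' @param t_default Default half-life (h).
#' @param folds Band folds (default `c(1.1, 2)`).
#' @param condition Expression column.
#' @return A list of class `simulation_result`: `per_gene` (gene_id,
#'   measured, predicted, in-band flags per fold for both) and `summary`
#'   (n_total plus per-fold predicted/measured/rescued counts).
#' @export
simulate_default_halflife <- function(expression, halflives, intensity,
                                      t_default, folds = c(1.1, 2),
                                      condition = setdiff(names(expression),
                                                          "gene_id")[1L]) {
  if (!is.null(dim(intensity))) {
    intensity <- setNames(intensity$h3k4me3_intensity, intensity$gene_id)
  }
  hl <- halflives[halflives$valid, c("gene_id", "t_half")]
  df <- merge(expression[c("gene_id", condition)], hl, by = "gene_id")
  names(df)[2L] <- "measured"
  df$intensity <- intensity[df$gene_id]
  df <- df[is.finite(df$intensity) & df$intensity > 0 & df$measured > 0, ]
  df$predicted <- predict_at_default(df$measured, df$t_half, t_default)

  fit <- fit_expression_regression(df$intensity, df$predicted)
  summary <- list(n_total = nrow(df), t_default = t_default,
                  regression = fit)
  for (f in folds) {
    pred_in <- band_membership(fit, df$intensity, df$predicted, f)
    meas_in <- band_membership(fit, df$intensity, df$measured, f)
    tag <- gsub("\\.", "_", paste0("x", f))
    df[[paste0("pred_in_", tag)]] <- pred_in
    df[[paste0("meas_in_", tag)]] <- meas_in
    summary[[paste0("n_", tag, "_predicted")]] <- sum(pred_in)
    summary[[paste0("n_", tag, "_measured")]] <- sum(meas_in)
    summary[[paste0("n_", tag, "_rescued")]] <- sum(pred_in & !meas_in)
  }
  structure(list(per_gene = df, summary = summary),
            class = "simulation_result")
}

#' Histone-mark linear model of expression (Models with/without decay)
#'
#' Fits ordinary least squares of log10 RPKM on log-transformed,
#' studentized (mean 0, s.d. 1) mark features: H3K4me3 and H3K27Ac over
#' TSS +/- 1 kb, H3K27me3 and H3K36me3 over the gene body.  With
#' `include_halflife = TRUE` the log-transformed decay constant
#' lambda = ln(2)/t_half is added as a fifth studentized regressor.  Genes
#' with an invalid half-life or any non-positive feature are excluded (so
#' an A-vs-B comparison shares one gene universe).  Constant features are
#' dropped with a warning.  The fit statistic is the Pearson correlation
#' between fitted and observed log expression.
#'
#' @param profiles A `gene_chip_profile` table.
#' @param halflives Half-life records (used for exclusion and the decay
#'   term).
#' @param expression Expression table.
#' @param include_halflife Add the decay-constant regressor (Model B)?
#' @param condition Expression column.
#' @return A list of class `model_fit`: `coefficients`, `r` (Pearson,
#'   fitted vs observed), `n`, `residuals`, `dropped` (dropped features).
#' @export
fit_linear_model <- function(profiles, halflives, expression,
                             include_halflife = FALSE,
                             condition = setdiff(names(expression),
                                                 "gene_id")[1L]) {
  feats <- c("h3k4me3_1kb", "h3k27ac_1kb", "h3k27me3_body", "h3k36me3_body")
  df <- merge(profiles[c("gene_id", feats)],
              expression[c("gene_id", condition)], by = "gene_id")
  names(df)[names(df) == condition] <- "rpkm"
  hl <- halflives[halflives$valid, c("gene_id", "t_half")]
  df <- merge(df, hl, by = "gene_id")
  ok <- df$rpkm > 0
  for (f in feats) ok <- ok & is.finite(df[[f]]) & df[[f]] > 0
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < 10L) stop("too few genes with positive features")

  X <- log10(as.matrix(df[feats]))
  if (include_halflife) {
    X <- cbind(X, lambda = log10(log(2) / df$t_half))
  }
  sds <- apply(X, 2L, sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  X <- scale(X)
  y <- log10(df$rpkm)
  fit <- lm(y ~ X)
  fitted <- unname(fit$fitted.values)
  structure(list(coefficients = setNames(coef(fit),
                                         c("b0", colnames(X))),
                 r = cor(fitted, y), n = nrow(df),
                 residuals = unname(fit$residuals), dropped = dropped),
            class = "model_fit")
}
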