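# First-order decay fitting for BrU pulse-chase time courses.
# Model: fraction(t) = exp(-lambda * t), lambda = ln(2) / t_half.
# Estimator: ordinary least squares of ln(fraction) on t with a free
# intercept; the free intercept absorbs normalization error at t = 0.

.FRACTION_FLOOR <- 1e-6

#' Normalize a gene's time course against a reference gene
#'
#' fraction(t) = [raw(g, t) / raw(ref, t)] / [raw(g, 0) / raw(ref, 0)],
#' so global losses shared with the reference cancel and fraction(0) = 1
#' exactly.
#'
#' @param raw A `timecourse` object.
#' @param gene Gene id to normalize.
#' @param reference_gene Reference gene id (e.g. `"GAPDH_ref"`); must be
#'   positive at every time point.
#' @return A list of class `decay_course` with `gene_id`, `times`,
#'   `fraction`, and `measurable` (FALSE with a `reason` when the gene or
#'   reference violates the preconditions).
#' @export
normalize_course <- function(raw, gene, reference_gene) {
  times <- timecourse_times(raw)
  g <- .tc_row(raw, gene)
  r <- .tc_row(raw, reference_gene)
  fail <- function(reason) {
    structure(list(gene_id = gene, times = times,
                   fraction = rep(NA_real_, length(times)),
                   measurable = FALSE, reason = reason),
              class = "decay_course")
  }
  if (is.null(r) || any(r <= 0)) return(fail("reference missing or non-positive"))
  if (is.null(g)) return(fail("gene absent from time course"))
  if (g[1L] <= 0) return(fail("zero value at t = 0"))
  frac <- (g / r) / (g[1L] / r[1L])
  structure(list(gene_id = gene, times = times, fraction = frac,
                 measurable = TRUE, reason = NA_character_),
            class = "decay_course")
}

.tc_row <- function(raw, gene) {
  i <- match(gene, raw$gene_id)
  if (is.na(i)) return(NULL)
  as.numeric(raw[i, -1L])
}

#' Fit a first-order decay half-life to a normalized course
#'
#' Ordinary least squares of ln(fraction) on time with a free intercept;
#' lambda = -slope and t_half = ln(2) / lambda.  Fractions are floored at
#' 1e-6 before the log and floored points are dropped from the fit.  The
#' record is invalid when fewer than 3 usable points remain or when the
#' slope is non-negative (no measurable decay); only genes with a positive
#' fitted half-life are analyzed downstream.
#'
#' @param course A `decay_course` from [normalize_course()].
#' @return A one-row `data.frame` (`gene_id`, `t_half`, `lambda`, `r2`,
#'   `n_points`, `valid`, `reason`).
#' @export
fit_halflife <- function(course) {
  rec <- function(t_half = NA_real_, lambda = NA_real_, r2 = NA_real_,
                  n = 0L, valid = FALSE, reason = NA_character_) {
    data.frame(gene_id = course$gene_id, t_half = t_half, lambda = lambda,
               r2 = r2, n_points = n, valid = valid, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (!isTRUE(course$measurable)) return(rec(reason = course$reason))
  use <- is.finite(course$fraction) & course$fraction > .FRACTION_FLOOR
  t <- course$times[use]
  y <- log(course$fraction[use])
  if (length(t) < 3L || length(unique(t)) < 3L) {
    return(rec(n = length(t), reason = "fewer than 3 usable points"))
  }
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    return(rec(n = length(t), reason = "no decay (slope >= 0)"))
  }
  lambda <- -slope
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  rec(t_half = log(2) / lambda, lambda = lambda, r2 = r2,
      n = length(t), valid = TRUE)
}

#' Fit half-lives for every gene in a time course
#'
#' Normalizes each gene against the reference and fits first-order decay;
#' the reference gene itself is excluded from the output.
#'
#' @param raw A `timecourse` object.
#' @param reference_gene Reference gene id.
#' @return A `data.frame` of half-life records, one row per gene, with a
#'   `n_valid`/`n_invalid` summary attached as attributes.
#' @export
fit_all <- function(raw, reference_gene) {
  genes <- setdiff(raw$gene_id, reference_gene)
  recs <- lapply(genes, function(g) {
    fit_halflife(normalize_course(raw, g, reference_gene))
  })
  out <- do.call(rbind, recs)
  attr(out, "n_valid") <- sum(out$valid)
  attr(out, "n_invalid") <- sum(!out$valid)
  message("fit_all: ", sum(out$valid), " valid / ", sum(!out$valid),
          " invalid half-life fits")
  out
}
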