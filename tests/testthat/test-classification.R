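make_cls <- function(intensity, polii, rpkm, t_half = NULL) {
  prof <- data.frame(gene_id = sprintf("g%d", seq_along(intensity)),
                     h3k4me3_intensity = intensity, polii_peak = polii,
                     stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = prof$gene_id, control = rpkm,
                     stringsAsFactors = FALSE)
  hl <- NULL
  if (!is.null(t_half)) {
    hl <- data.frame(gene_id = prof$gene_id, t_half = t_half,
                     lambda = log(2) / t_half, r2 = 1, n_points = 13L,
                     valid = !is.na(t_half), stringsAsFactors = FALSE)
    hl$t_half[is.na(hl$t_half)] <- 1
  }
  classify(prof, expr, hl)
}

test_that("quadrant thresholds are applied as the conjunctions define them", {
  cc <- make_cls(intensity = c(2e4, 5e3, 2e4, 5e3),
                 polii = c(TRUE, FALSE, FALSE, TRUE),
                 rpkm = c(5, 20, 20, 5),
                 t_half = c(3, 20, NA, 5))
  expect_equal(cc$chip_status, c("plus", "minus", "ambiguous", "ambiguous"))
  expect_equal(cc$rna_status, c("minus", "plus", "plus", "minus"))
  expect_true(cc$short_halflife[1L])
  expect_false(cc$short_halflife[2L])
  expect_true(is.na(cc$short_halflife[3L]))   # no valid half-life
  expect_error(classify(data.frame(gene_id = "g", h3k4me3_intensity = 1,
                                   polii_peak = TRUE),
                        data.frame(gene_id = "g", control = 1),
                        thresholds = list(h3k4me3 = 1e4)),
               "missing threshold")
})

test_that("classification partitions the gene universe", {
  u <- small_universe(n = 300L)
  chip <- simulate_chip(u, seed = 2L)
  expr <- simulate_expression(u, seed = 3L)
  cc <- classify(chip$features, expr, NULL)
  tab <- table(cc$chip_status, cc$rna_status)
  expect_equal(sum(tab), nrow(cc))
  expect_equal(nrow(cc), nrow(u$truth))
})

test_that("log-log regression recovers proportional data and rejects noise", {
  x <- 10^seq(2, 6, length.out = 50)
  fit <- fit_expression_regression(x, x / 100)     # exactly proportional
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, -2, tolerance = 1e-9)

  # permutation oracle: shuffled pairing kills the correlation
  set.seed(42)
  y <- x / 100
  r_perm <- replicate(200, {
    fit_expression_regression(x, sample(y))$pearson_r
  })
  expect_lt(abs(mean(r_perm)), 0.05)
  expect_lt(max(abs(r_perm)), 0.6)
  expect_error(fit_expression_regression(c(1, 2), c(1, 2)), ">= 3")
})

test_that("band membership is symmetric in log space and nested", {
  fit <- structure(list(slope = 1, intercept = 0, pearson_r = 1, n = 10),
                   class = "regression_fit")
  # point exactly on the line
  expect_true(band_membership(fit, 100, 100, 1.1))
  expect_true(band_membership(fit, 100, 100, 1))
  # predicted 100, observed 150: inside x2, outside x1.1
  expect_true(band_membership(fit, 100, 150, 2))
  expect_false(band_membership(fit, 100, 150, 1.1))
  # symmetric below the line
  expect_true(band_membership(fit, 100, 100 / 1.5, 2))
  # nesting: x1.1 implies x2 on random points
  set.seed(7)
  iv <- 10^runif(200, 2, 5)
  rv <- 10^(log10(iv) + rnorm(200, 0, 0.4))
  in11 <- band_membership(fit, iv, rv, 1.1)
  in2 <- band_membership(fit, iv, rv, 2)
  expect_true(all(in2[in11]))
})

test_that("default half-life is the band median and errors when empty", {
  cc <- data.frame(gene_id = c("a", "b", "c", "d"),
                   chip_status = "plus", rna_status = "plus",
                   short_halflife = FALSE, t_half = c(10, 11, 12, 50),
                   h3k4me3_intensity = c(100, 100, 100, 100),
                   rpkm = c(100, 100, 100, 1e6), stringsAsFactors = FALSE)
  fit <- structure(list(slope = 1, intercept = -2 + log10(1), pearson_r = 1,
                        n = 4), class = "regression_fit")
  # genes a-c on the line (rpkm = intensity/100 * 100); d far off
  fit$intercept <- 0
  expect_equal(default_halflife(cc, fit, 1.1), 11)
  cc$rpkm <- 1e9
  expect_error(default_halflife(cc, fit, 1.1), "no band genes")
})

test_that("default half-life of band genes recovers the generator median", {
  u <- generate_universe(generator_config(n_genes = 4000L, seed = 13L,
                                          genes_per_chrom = 1000L,
                                          noise_expr = 0.05,
                                          noise_chip = 0.05))
  chip <- simulate_chip(u, seed = 14L)
  expr <- simulate_expression(u, seed = 15L)
  hl <- truth_halflife_records(u)
  cc <- classify(chip$features, expr, hl)
  pp <- cc[cc$chip_status == "plus" & cc$rna_status == "plus", ]
  fit <- fit_expression_regression(pp$h3k4me3_intensity, pp$rpkm)
  med <- default_halflife(cc, fit, 1.1)
  expect_lt(abs(med - 10.9) / 10.9, 0.05)
})

test_that("contingency table reproduces the printed peak-stratum shares", {
  # gene-level realization of the published marginals:
  # strata sizes 7,737 / 2,732 / 8,384 (no/low/high) out of 18,853;
  # >1 RPKM: 957 / 1,808 / 7,656; >10 RPKM: 175 / 600 / 4,073
  lv <- function(n_all, n_gt1, n_gt10) {
    c(rep(50, n_gt10), rep(5, n_gt1 - n_gt10), rep(0.5, n_all - n_gt1))
  }
  stratum <- rep(c("no", "low", "high"), c(7737, 2732, 8384))
  rpkm <- c(lv(7737, 957, 175), lv(2732, 1808, 600), lv(8384, 7656, 4073))
  qt <- quadrant_table(stratum, rpkm, cuts = c(1, 10))
  expect_equal(qt$counts["total", "gt1"], 10421)
  expect_equal(qt$counts["total", "gt10"], 4848)
  expect_equal(qt$counts["high", "gt1"], 7656)
  expect_equal(round(qt$percent["high", "gt1"], 1), 73.5)
  expect_equal(round(qt$percent["high", "gt10"], 1), 84.0)
  # degenerate: nothing passes a cut
  qt0 <- quadrant_table(c("no", "high"), c(0, 0), cuts = c(1, 10))
  expect_true(all(is.na(qt0$percent[, c("gt1", "gt10")])))
})

test_that("short-half-life enrichment matches the extreme-table point mass", {
  # all 5 short genes inside the 5-gene quadrant, universe of 20
  cc <- data.frame(gene_id = sprintf("g%d", 1:20),
                   chip_status = rep(c("plus", "minus"), c(5, 15)),
                   rna_status = rep(c("minus", "plus"), c(5, 15)),
                   short_halflife = rep(c(TRUE, FALSE), c(5, 15)),
                   t_half = 1, h3k4me3_intensity = 1, rpkm = 1,
                   stringsAsFactors = FALSE)
  res <- short_halflife_enrichment(cc)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # cross-check the same table against the Fisher exact test
  ft <- fisher.test(matrix(c(5, 0, 0, 15), 2), alternative = "greater")
  expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
})

test_that("adjacent-bin rank tests behave under null, shift and degeneracy", {
  set.seed(9)
  same <- list(a = rnorm(100), b = rnorm(100))
  expect_gt(bin_comparison(same)$p_value, 0.001)
  shifted <- list(a = rnorm(100), b = rnorm(100) + 5)
  expect_lt(bin_comparison(shifted)$p_value, 0.001)
  expect_warning(res <- bin_comparison(list(a = 1, b = rnorm(10))),
                 "refused")
  expect_true(is.na(res$p_value[1L]))
  three <- bin_comparison(list(a = rnorm(50), b = rnorm(50), c = rnorm(50)))
  expect_equal(nrow(three), 2L)
  expect_true(all(three$p_adjusted >= three$p_value - 1e-12))
})
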