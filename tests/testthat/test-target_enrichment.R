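hl_table <- function(ids, t_half, valid = TRUE) {
  data.frame(gene_id = ids, t_half = t_half, lambda = log(2) / t_half,
             r2 = 1, n_points = 13L,
             valid = rep_len(valid, length(ids)),
             stringsAsFactors = FALSE)
}
expr_table <- function(ids, v, cond = "x") {
  df <- data.frame(gene_id = ids, v = v, stringsAsFactors = FALSE)
  names(df)[2L] <- cond
  df
}

test_that("target calling applies both fold thresholds with >= semantics", {
  ids <- c("a", "b", "c")
  ctrl_hl <- hl_table(ids, c(2, 2, 4))
  kd_hl <- hl_table(ids, c(5, 3, 8))          # folds 2.5, 1.5, 2.0
  ctrl_e <- expr_table(ids, c(3, 2, 5))
  kd_e <- expr_table(ids, c(7, 3, 10))        # folds 2.33, 1.5, 2.0
  tg22 <- call_targets(ctrl_hl, kd_hl, ctrl_e, kd_e, 2, 2)
  expect_equal(tg22$is_target, c(TRUE, FALSE, TRUE))   # ties at 2.0 included
  tg15 <- call_targets(ctrl_hl, kd_hl, ctrl_e, kd_e, 1.5, 1.5)
  expect_true(all(tg15$is_target))
  # raising either threshold never adds targets (monotonicity)
  for (hl_thr in c(1.5, 2, 3)) {
    lo <- call_targets(ctrl_hl, kd_hl, ctrl_e, kd_e, hl_thr, 1.5)$is_target
    hi <- call_targets(ctrl_hl, kd_hl, ctrl_e, kd_e, hl_thr, 2.5)$is_target
    expect_true(all(lo | !hi))
  }
})

test_that("invalid half-lives and non-positive controls are excluded with reasons", {
  ids <- c("a", "b", "c")
  ctrl_hl <- hl_table(ids, c(2, 2, 2), valid = c(TRUE, FALSE, TRUE))
  kd_hl <- hl_table(ids, c(6, 6, 6))
  ctrl_e <- expr_table(ids, c(3, 3, 0))
  kd_e <- expr_table(ids, c(9, 9, 9))
  tg <- call_targets(ctrl_hl, kd_hl, ctrl_e, kd_e, 2, 2)
  expect_true(tg$is_target[1L])
  expect_true(tg$excluded[2L])
  expect_match(tg$reason[2L], "half-life")
  expect_true(tg$excluded[3L])
  expect_match(tg$reason[3L], "expression")
})

test_that("targets on a synthetic knockdown recover the designated genes", {
  u <- generate_universe(generator_config(n_genes = 1500L, seed = 71L,
                                          genes_per_chrom = 750L,
                                          noise_bric = 0.03,
                                          noise_expr = 0.03))
  hl_ctrl <- suppressMessages(fit_all(simulate_bric(u, seed = 72L),
                                      "GAPDH_ref"))
  hl_kd <- suppressMessages(fit_all(simulate_bric(u, seed = 73L,
                                                  condition = "UPF1"),
                                    "GAPDH_ref"))
  e_ctrl <- simulate_expression(u, seed = 74L)
  e_kd <- simulate_expression(u, seed = 75L, condition = "UPF1")
  tg <- call_targets(hl_ctrl, hl_kd, e_ctrl, e_kd, 2, 2)
  truth_target <- u$truth$gene_id[u$truth$kd_fold_UPF1 >= 2 &
                                    !u$truth$is_reference]
  called <- tg$gene_id[tg$is_target]
  sens <- length(intersect(called, truth_target)) / length(truth_target)
  fpr <- length(setdiff(called, truth_target)) /
    (nrow(tg) - length(truth_target))
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.01)
})

test_that("class fractions reproduce the published target percentages", {
  class866 <- sprintf("c%d", 1:866)
  expect_equal(class_fraction(class866[1:26], class866)$percent, 3.0)
  expect_equal(class_fraction(class866[1:40], class866)$percent, 4.6)
  expect_equal(class_fraction(class866[1:4], class866)$percent, 0.46)
  # lincRNA analysis fractions
  class84 <- sprintf("l%d", 1:84)
  expect_equal(class_fraction(class84[1:26], class84)$percent, 31.0)
  class103 <- sprintf("s%d", 1:103)
  expect_equal(class_fraction(class103[1:84], class103)$percent, 81.6)
  expect_error(class_fraction("x", character()), "empty")
})

test_that("set overlap statistics match a resampling expectation", {
  expect_equal(overlap_sets(c("a", "b"), c("c", "d"))$n_intersect, 0L)
  expect_equal(overlap_sets(c("a", "b"), c("a", "b"))$jaccard, 1)
  set.seed(8)
  uni <- sprintf("g%d", 1:1279)
  ov <- replicate(10000, {
    overlap_sets(sample(uni, 23), sample(uni, 40))$n_intersect
  })
  expect_equal(mean(ov), 23 * 40 / 1279, tolerance = 0.1)
})

test_that("hypergeometric tail matches exhaustive enumeration for small N", {
  brute_p <- function(k, K, n, N) {
    # enumerate all draws of n from N with K marked
    counts <- vapply(0:min(K, n), function(x) {
      choose(K, x) * choose(N - K, n - x)
    }, numeric(1L))
    sum(counts[(k:min(K, n)) + 1L]) / choose(N, n)
  }
  for (N in c(5L, 8L, 12L)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, K + n - N):min(K, n)) {
          expect_equal(hypergeometric_p(k, K, n, N), brute_p(k, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_equal(hypergeometric_p(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeometric_p(0, 5, 5, 20), 1)
})

test_that("BH correction matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up by hand: q_i = min_{j >= i} p_(j) * m / j
  m <- length(p)
  q_hand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(bh_fdr(p), pmin(q_hand, 1))
  # permutation invariance
  perm <- sample(seq_along(p))
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
})

test_that("gene-set enrichment finds a planted term and applies the filters", {
  universe <- sprintf("g%d", 1:2000)
  planted <- universe[1:40]
  set.seed(3)
  tm <- rbind(
    data.frame(gene_id = planted, term_id = "T_PLANT"),
    do.call(rbind, lapply(1:20, function(i) {
      data.frame(gene_id = sample(universe, 60),
                 term_id = sprintf("T%02d", i))
    }))
  )
  gene_set <- c(planted[1:30], sample(universe[41:2000], 70))
  res <- gene_set_enrichment(gene_set, universe, tm)
  expect_equal(res$term_id[1L], "T_PLANT")
  expect_lt(res$fdr[1L], 0.05)
  # a term with too few hits is filtered regardless of p
  tm9 <- rbind(tm, data.frame(gene_id = gene_set[1:9], term_id = "T_NINE"))
  res9 <- gene_set_enrichment(gene_set, universe, tm9, min_genes = 10L,
                              fdr_max = 1)
  expect_false("T_NINE" %in% res9$term_id)
  all_terms <- attr(res9, "all_terms")
  expect_true("T_NINE" %in% all_terms$term_id)
})

test_that("enrichment FDR is calibrated under a null gene set", {
  set.seed(12)
  universe <- sprintf("g%d", 1:400)
  tm <- do.call(rbind, lapply(1:25, function(i) {
    data.frame(gene_id = sample(universe, 40),
               term_id = sprintf("T%02d", i))
  }))
  hits <- replicate(400, {
    gs <- sample(universe, 50)
    res <- gene_set_enrichment(gs, universe, tm, min_genes = 0L,
                               fdr_max = 0.05)
    nrow(res) > 0L
  })
  expect_lte(mean(hits), 0.06)
})
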