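# Synthetic gene universe with known ground truth (synthesis rates,
# half-lives, knockdown effects), emitting every input the downstream
# stages consume.  Steady-state model: RPKM = c * k_syn * t_half, so a
# short-lived, highly transcribed gene lands in the ChIP+/RNA- quadrant.

#' Generator configuration
#'
#' Assembles the parameters of the synthetic universe.  Defaults encode the
#' study conditions the pipeline is meant to emulate: log-normal default-band
#' half-lives with median 10.9 h and spread equivalent to an s.d. of 3 h,
#' about a quarter of genes short-lived (< 4 h), the 13-point BrU chase
#' schedule, and knockdown factors (UPF1/EXOSC5 at >= 2-fold,
#' STAU1 at >= 1.5-fold rules downstream).
#'
#' @param n_genes Number of genes (excluding the always-emitted reference
#'   gene `GAPDH_ref`).
#' @param seed Integer seed; every downstream simulation derives from it.
#' @param halflife_median Median half-life (h) of the default-band
#'   (non-short) component.
#' @param halflife_sd Spread of the default band expressed as an s.d. in
#'   hours; converted internally to the log-normal `sdlog`.
#' @param frac_short Fraction of genes drawn from the short-lived component
#'   (truncated below `short_max` hours).
#' @param short_median,short_sdlog,short_max Short-component log-normal
#'   median (h), log-scale s.d., and truncation ceiling (h).
#' @param ksyn_sdlog Log-scale s.d. of the synthesis-rate distribution
#'   (median 1, arbitrary units/h).
#' @param chip_scale Expected H3K4me3 tag count for a gene with `k_syn = 1`;
#'   also the pol II presence threshold on `chip_factor`.
#' @param rpkm_scale Global scale `c` mapping `k_syn * t_half` to RPKM.
#' @param peak_floor Minimum noisy intensity (as a fraction of `chip_scale`)
#'   below which no H3K4me3 peak is emitted for pol II-negative genes.
#' @param noise_expr,noise_chip,noise_bric Log-scale s.d. of the
#'   multiplicative measurement noise for expression, ChIP intensities and
#'   BrU time courses.
#' @param schedule Chase time points in hours; must start at 0.
#' @param knockdowns Named list of knockdown specs, each
#'   `list(n_targets =, fold_range = c(lo, hi))`; target genes get their
#'   half-life multiplied by a fold drawn uniformly from `fold_range`.
#' @param lincrna_frac Fraction of genes labelled `lincRNA`.
#' @param gene_length,gene_pitch Gene body length and spacing between
#'   consecutive gene starts (bp); pitch must leave >= 4 kb clearance.
#' @param genes_per_chrom Genes placed per synthetic chromosome.
#' @param n_erna Number of intergenic enhancer-RNA loci.
#' @param erna_length eRNA locus length (bp).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000L,
                             seed = 1L,
                             halflife_median = 10.9,
                             halflife_sd = 3,
                             frac_short = 0.25,
                             short_median = 2,
                             short_sdlog = 0.5,
                             short_max = 4,
                             ksyn_sdlog = 1,
                             chip_scale = 1e4,
                             rpkm_scale = 1,
                             peak_floor = 0.1,
                             noise_expr = 0.25,
                             noise_chip = 0.25,
                             noise_bric = 0.1,
                             schedule = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2,
                                          3, 4, 6, 8, 10, 12),
                             knockdowns = list(
                               UPF1   = list(n_targets = 50L,
                                             fold_range = c(2.5, 6)),
                               EXOSC5 = list(n_targets = 50L,
                                             fold_range = c(2.5, 6)),
                               STAU1  = list(n_targets = 20L,
                                             fold_range = c(1.8, 3))
                             ),
                             lincrna_frac = 0.02,
                             gene_length = 2000L,
                             gene_pitch = 10000L,
                             genes_per_chrom = 1000L,
                             n_erna = 50L,
                             erna_length = 400L) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  sds <- c(cfg$halflife_sd, cfg$short_sdlog, cfg$ksyn_sdlog,
           cfg$noise_expr, cfg$noise_chip, cfg$noise_bric)
  if (any(sds < 0)) stop("all spreads / noise s.d. must be >= 0")
  if (cfg$frac_short < 0 || cfg$frac_short > 1) stop("frac_short in [0,1]")
  if (cfg$schedule[1L] != 0 || any(diff(cfg$schedule) <= 0)) {
    stop("schedule must start at 0 and be strictly increasing")
  }
  class(cfg) <- "generator_config"
  cfg
}

# sdlog giving a log-normal (median m) an s.d. of `sd_h` hours:
# sd^2 = m^2 * u * (u - 1), u = exp(sdlog^2)
.halflife_sdlog <- function(median_h, sd_h) {
  r2 <- (sd_h / median_h)^2
  u <- (1 + sqrt(1 + 4 * r2)) / 2
  sqrt(log(u))
}

#' Generate the synthetic gene universe
#'
#' Samples per-gene ground truth (synthesis rate, half-life, expected ChIP
#' intensity, pol II presence, knockdown folds) and lays the genes out
#' non-overlapping on synthetic chromosomes with enough spacing that TSS
#' windows never collide.  A long-lived reference gene `GAPDH_ref` is always
#' appended for time-course normalization.  Intergenic enhancer-RNA loci
#' with their own (short) half-lives and knockdown folds are placed midway
#' between gene bodies.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_universe` with elements `truth`
#'   (per-gene ground truth incl. `base_expr`, the noise-free control RPKM),
#'   `catalog` (a `gene_catalog`), `erna` (eRNA locus truth) and `config`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$gene_pitch < config$gene_length + 4000L) {
    stop("infeasible placement: gene_pitch must leave >= 4 kb between bodies")
  }
  set.seed(config$seed)
  n <- config$n_genes

  k_syn <- rlnorm(n, meanlog = 0, sdlog = config$ksyn_sdlog)
  is_short <- runif(n) < config$frac_short
  sdlog_def <- .halflife_sdlog(config$halflife_median, config$halflife_sd)
  t_half <- rlnorm(n, log(config$halflife_median), sdlog_def)
  if (any(is_short)) {
    t_half[is_short] <- .rlnorm_trunc(sum(is_short), log(config$short_median),
                                      config$short_sdlog, config$short_max)
  }
  chip_factor <- config$chip_scale * k_syn
  polii_present <- chip_factor > config$chip_scale

  biotype <- ifelse(runif(n) < config$lincrna_frac, "lincRNA", "mRNA")
  gene_id <- sprintf("G%05d", seq_len(n))

  truth <- data.frame(
    gene_id = gene_id, k_syn = k_syn, t_half = t_half,
    chip_factor = chip_factor, polii_present = polii_present,
    biotype = biotype, short_component = is_short,
    base_expr = config$rpkm_scale * k_syn * t_half,
    is_reference = FALSE, stringsAsFactors = FALSE
  )

  for (fac in names(config$knockdowns)) {
    ks <- config$knockdowns[[fac]]
    fold <- rep(1, n)
    pool <- which(is_short)
    if (length(pool) < ks$n_targets) pool <- seq_len(n)
    idx <- sample(pool, min(ks$n_targets, length(pool)))
    fold[idx] <- runif(length(idx), ks$fold_range[1L], ks$fold_range[2L])
    truth[[paste0("kd_fold_", fac)]] <- fold
  }

  ref <- truth[1L, , drop = FALSE]
  ref$gene_id <- "GAPDH_ref"; ref$k_syn <- 1
  ref$t_half <- 30; ref$chip_factor <- config$chip_scale
  ref$polii_present <- TRUE; ref$biotype <- "mRNA"
  ref$short_component <- FALSE
  ref$base_expr <- config$rpkm_scale * 30
  ref$is_reference <- TRUE
  ref[grep("^kd_fold_", names(ref))] <- 1
  truth <- rbind(truth, ref)

  catalog <- .place_genes(truth$gene_id, truth$biotype, config)
  erna <- .place_erna(catalog, config)

  structure(list(truth = truth, catalog = catalog, erna = erna,
                 config = config),
            class = "synthetic_universe")
}

.rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rlnorm(length(need), meanlog, sdlog)
    ok <- draw < upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

.place_genes <- function(gene_ids, biotypes, config) {
  n <- length(gene_ids)
  idx <- seq_len(n) - 1L
  chrom_i <- idx %/% config$genes_per_chrom
  slot <- idx %% config$genes_per_chrom
  start <- slot * config$gene_pitch + 2000L
  strand <- c("+", "-")[(idx %% 2L) + 1L]
  df <- data.frame(
    gene_id = gene_ids,
    chrom = paste0("chrS", chrom_i + 1L),
    start = start,
    end = start + config$gene_length,
    strand = strand,
    biotype = biotypes,
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("gene_catalog", "data.frame")
  df
}

# eRNA loci midway in intergenic gaps: >= 1.5 kb clear of both gene bodies.
.place_erna <- function(catalog, config) {
  n_e <- config$n_erna
  if (n_e == 0L) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      t_half = numeric(), base_expr = numeric()))
  }
  gaps_per_chrom <- config$genes_per_chrom - 1L
  if (gaps_per_chrom < 1L) stop("infeasible placement: no intergenic gaps")
  chroms <- unique(catalog$chrom)
  avail <- expand.grid(chrom = chroms, gap = seq_len(gaps_per_chrom),
                       stringsAsFactors = FALSE)
  if (nrow(avail) < n_e) stop("infeasible placement: not enough gaps for eRNAs")
  pick <- avail[sample(nrow(avail), n_e), , drop = FALSE]
  start <- (pick$gap - 1L) * config$gene_pitch + 2000L +
    config$gene_length + 3000L
  df <- data.frame(
    chrom = pick$chrom,
    start = start,
    end = start + config$erna_length,
    stringsAsFactors = FALSE
  )
  df$id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df$t_half <- rlnorm(n_e, log(1), 0.4)
  df$base_expr <- rlnorm(n_e, log(5), 0.5)
  for (fac in names(config$knockdowns)) {
    fold <- rep(1, n_e)
    idx <- sample(n_e, max(1L, round(n_e / 4)))
    fold[idx] <- runif(length(idx), 2.2, 4)
    df[[paste0("kd_fold_", fac)]] <- fold
  }
  df[c("id", setdiff(names(df), "id"))]
}

.kd_fold <- function(truth, condition) {
  if (identical(condition, "control")) return(rep(1, nrow(truth)))
  col <- paste0("kd_fold_", condition)
  if (!col %in% names(truth)) stop("unknown condition: ", condition)
  truth[[col]]
}

#' Simulate a steady-state expression table
#'
#' RPKM = c * k_syn * t_half * exp(eps), eps ~ Normal(0, noise_sd^2), with
#' the condition's knockdown fold applied to the half-life.  Noise-free
#' values are exactly proportional to synthesis rate times half-life.
#'
#' @param universe A `synthetic_universe`.
#' @param noise_sd Log-scale s.d. of the multiplicative noise.
#' @param seed Integer seed.
#' @param condition `"control"` or a knockdown factor name.
#' @return Expression `data.frame` (`gene_id` + one column named after the
#'   condition).
#' @export
simulate_expression <- function(universe, noise_sd = NULL, seed = 1L,
                                condition = "control") {
  truth <- universe$truth
  if (is.null(noise_sd)) noise_sd <- universe$config$noise_expr
  fold <- .kd_fold(truth, condition)
  set.seed(seed)
  eps <- rnorm(nrow(truth), 0, noise_sd)
  out <- data.frame(gene_id = truth$gene_id,
                    value = truth$base_expr * fold * exp(eps),
                    stringsAsFactors = FALSE)
  names(out)[2L] <- condition
  out
}

#' Simulate ChIP-seq peaks and coverage tracks
#'
#' H3K4me3 intensity is `chip_factor * exp(eps)` with `chip_factor`
#' proportional to the synthesis rate; a +/-500 bp peak around the TSS
#' carrying that summed coverage is emitted when the gene is pol II-positive
#' or the intensity clears the peak floor.  pol II peaks are emitted for
#' pol II-positive genes only.  H3K27Ac (TSS +/-1 kb), H3K36me3 (gene body,
#' transcription-coupled) and H3K27me3 (gene body, repressive, anticorrelated
#' with synthesis) coverage blocks are emitted for every gene so the
#' histone-mark models see positive features.  H3K4me1 and H3K27Ac peaks are
#' additionally emitted at the configured intergenic eRNA loci.
#'
#' @inheritParams simulate_expression
#' @return A list with `peaks` (named list of peak `data.frame`s) and
#'   `coverage` (named list of bedGraph-style `data.frame`s), plus
#'   `intensity` (the emitted per-gene H3K4me3 intensities, a named vector).
#' @export
simulate_chip <- function(universe, noise_sd = NULL, seed = 1L) {
  truth <- universe$truth
  catalog <- universe$catalog
  cfg <- universe$config
  if (is.null(noise_sd)) noise_sd <- cfg$noise_chip
  stopifnot(identical(truth$gene_id, catalog$gene_id))
  n <- nrow(truth)
  set.seed(seed)

  k4me3 <- truth$chip_factor * exp(rnorm(n, 0, noise_sd))
  k27ac <- 0.6 * truth$chip_factor * exp(rnorm(n, 0, noise_sd)) + 1
  k36me3 <- 0.8 * truth$chip_factor * exp(rnorm(n, 0, noise_sd)) + 1
  k27me3 <- cfg$chip_scale * exp(rnorm(n, 0, noise_sd)) / (1 + truth$k_syn) + 1
  polii_level <- 0.3 * truth$chip_factor * exp(rnorm(n, 0, noise_sd))

  tss <- catalog$tss
  has_k4_peak <- truth$polii_present | (k4me3 > cfg$peak_floor * cfg$chip_scale)

  peak_win <- function(keep, intensity) {
    data.frame(chrom = catalog$chrom[keep],
               start = pmax(tss[keep] - 500L, 0L),
               end = tss[keep] + 500L,
               intensity = intensity[keep],
               stringsAsFactors = FALSE)
  }
  peaks <- list(
    H3K4me3 = peak_win(has_k4_peak, k4me3),
    polII   = peak_win(truth$polii_present, polii_level)
  )

  block <- function(center_start, center_end, total) {
    data.frame(chrom = catalog$chrom,
               start = pmax(center_start, 0L), end = center_end,
               value = total / (center_end - pmax(center_start, 0L)),
               stringsAsFactors = FALSE)
  }
  coverage <- list(
    H3K4me3  = block(tss - 500L, tss + 500L, k4me3),
    polII    = block(tss - 500L, tss + 500L, polii_level),
    H3K27Ac  = block(tss - 1000L, tss + 1000L, k27ac),
    H3K36me3 = block(catalog$start, catalog$end, k36me3),
    H3K27me3 = block(catalog$start, catalog$end, k27me3)
  )

  erna <- universe$erna
  if (nrow(erna)) {
    e_int <- rlnorm(nrow(erna), log(0.2 * cfg$chip_scale), noise_sd)
    k4me1_peaks <- data.frame(chrom = erna$chrom,
                              start = erna$start - 100L,
                              end = erna$end + 100L,
                              intensity = e_int, stringsAsFactors = FALSE)
    k27ac_erna <- data.frame(chrom = erna$chrom, start = erna$start,
                             end = erna$end, intensity = e_int,
                             stringsAsFactors = FALSE)
    peaks$H3K4me1 <- k4me1_peaks
    peaks$H3K27Ac <- rbind(peak_win(rep(TRUE, n), k27ac), k27ac_erna)
  } else {
    peaks$H3K4me1 <- data.frame(chrom = character(), start = integer(),
                                end = integer(), intensity = numeric())
    peaks$H3K27Ac <- peak_win(rep(TRUE, n), k27ac)
  }

  # expected per-gene profile: what build_profiles() recovers from the
  # emitted peaks/coverage (block coverage makes the round trip exact)
  features <- data.frame(
    gene_id = truth$gene_id,
    h3k4me3_intensity = ifelse(has_k4_peak, k4me3, 0),
    polii_peak = truth$polii_present,
    h3k4me3_1kb = k4me3,
    h3k27ac_1kb = k27ac,
    h3k27me3_body = k27me3,
    h3k36me3_body = k36me3,
    stringsAsFactors = FALSE
  )
  class(features) <- c("gene_chip_profile", "data.frame")

  list(peaks = peaks, coverage = coverage,
       intensity = setNames(k4me3, truth$gene_id),
       features = features)
}

#' Ground-truth half-life records for a universe
#'
#' Converts the generator truth into a half-life record table of the shape
#' [fit_all()] returns, for use as an oracle or as a fast stand-in where
#' fitted records are not under test.
#'
#' @param universe A `synthetic_universe`.
#' @param condition `"control"` or a knockdown factor name (applies the
#'   knockdown fold).
#' @return A half-life record `data.frame` (reference gene excluded).
#' @export
truth_halflife_records <- function(universe, condition = "control") {
  truth <- universe$truth[!universe$truth$is_reference, , drop = FALSE]
  t_half <- truth$t_half * .kd_fold(truth, condition)
  data.frame(gene_id = truth$gene_id, t_half = t_half,
             lambda = log(2) / t_half, r2 = 1,
             n_points = length(universe$config$schedule),
             valid = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate a BrU pulse-chase time course
#'
#' value(g, t) = base_expr(g) * fold * exp(-lambda t) * exp(eps), with
#' lambda = ln(2) / (t_half * fold) under the condition's knockdown fold.
#' The reference gene `GAPDH_ref` stays constant (before noise) so
#' downstream reference normalization cancels only global effects.
#'
#' @param universe A `synthetic_universe` (or a truth-like `data.frame` with
#'   `gene_id`, `t_half`, `base_expr`, optional `is_reference` and
#'   `kd_fold_*` columns, e.g. the eRNA table).
#' @param schedule Chase time points (h); defaults to the config schedule.
#' @param noise_sd Log-scale s.d. per measurement.
#' @param seed Integer seed.
#' @param condition `"control"` or a knockdown factor name.
#' @return A `timecourse` object.
#' @export
simulate_bric <- function(universe, schedule = NULL, noise_sd = NULL,
                          seed = 1L, condition = "control") {
  if (inherits(universe, "synthetic_universe")) {
    truth <- universe$truth
    if (is.null(schedule)) schedule <- universe$config$schedule
    if (is.null(noise_sd)) noise_sd <- universe$config$noise_bric
  } else {
    truth <- universe
    if (is.null(schedule) || is.null(noise_sd)) {
      stop("schedule and noise_sd required for a bare truth table")
    }
  }
  if (!"gene_id" %in% names(truth) && "id" %in% names(truth)) {
    truth$gene_id <- truth$id
  }
  if (schedule[1L] != 0) stop("schedule must start at 0")
  fold <- .kd_fold(truth, condition)
  lambda <- log(2) / (truth$t_half * fold)
  is_ref <- if ("is_reference" %in% names(truth)) truth$is_reference else
    rep(FALSE, nrow(truth))
  lambda[is_ref] <- 0
  base <- truth$base_expr * fold

  set.seed(seed)
  vals <- outer(lambda, schedule, function(l, t) exp(-l * t)) * base
  vals <- vals * exp(matrix(rnorm(length(vals), 0, noise_sd), nrow(truth)))
  df <- data.frame(gene_id = truth$gene_id, vals, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df)[-1L] <- as.character(schedule)
  attr(df, "times") <- schedule
  class(df) <- c("timecourse", "data.frame")
  df
}

#' Write every synthetic input file for a universe
#'
#' Emits the gene catalog (BED), per-mark peak BEDs and coverage bedGraphs,
#' control and knockdown expression TSVs, and control plus per-factor BrU
#' time-course TSVs into `outdir`, in exactly the formats the readers
#' consume.
#'
#' @param universe A `synthetic_universe`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for all measurement noise.
#' @return Invisibly, a named list of written paths.
#' @export
write_universe_files <- function(universe, outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  p <- function(f) file.path(outdir, f)

  write_gene_catalog(universe$catalog, p("genes.bed"))
  paths$genes <- p("genes.bed")

  chip <- simulate_chip(universe, seed = seed + 1L)
  for (mark in names(chip$peaks)) {
    f <- p(sprintf("peaks_%s.bed", mark))
    write_peaks(chip$peaks[[mark]], f)
    paths[[paste0("peaks_", mark)]] <- f
  }
  for (mark in names(chip$coverage)) {
    f <- p(sprintf("coverage_%s.bedgraph", mark))
    write_coverage(chip$coverage[[mark]], f)
    paths[[paste0("coverage_", mark)]] <- f
  }

  conds <- c("control", names(universe$config$knockdowns))
  expr <- Reduce(function(a, b) merge(a, b, by = "gene_id", sort = FALSE),
                 lapply(seq_along(conds), function(i) {
                   simulate_expression(universe, seed = seed + 10L + i,
                                       condition = conds[i])
                 }))
  write_expression(expr, p("expression.tsv"))
  paths$expression <- p("expression.tsv")

  for (i in seq_along(conds)) {
    tc <- simulate_bric(universe, seed = seed + 20L + i, condition = conds[i])
    f <- p(sprintf("bric_%s.tsv", conds[i]))
    write_timecourse(tc, f)
    paths[[paste0("bric_", conds[i])]] <- f
  }
  invisible(paths)
}
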