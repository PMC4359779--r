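# End-to-end orchestration of the synthetic-demo analysis: one config, one
# seed, a versioned JSON report.  Stages: annotate -> halflife -> classify
# -> simulate-default -> linear-model -> targets -> enrich -> erna.

.PIPELINE_STAGES <- c("annotate", "halflife", "classify", "simulate_default",
                      "linear_model", "targets", "enrich", "erna")

#' Assemble and validate a pipeline configuration
#'
#' @param seed Master seed; all randomness in the run derives from it.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param thresholds Classification thresholds ([default_thresholds()]).
#' @param band_folds Regression band folds.
#' @param factor_folds Named list of per-factor
#'   `list(hl_fold =, expr_fold =)` target-calling thresholds.
#' @param reference_gene Reference gene id for time-course normalization.
#' @param min_genes,fdr_max Gene-set enrichment reporting filters.
#' @param config Optional path to a YAML file (or a named list) whose
#'   entries override the above arguments.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = generator_config(seed = seed),
                            thresholds = default_thresholds(),
                            band_folds = c(1.1, 2),
                            factor_folds = list(
                              UPF1   = list(hl_fold = 2,   expr_fold = 2),
                              EXOSC5 = list(hl_fold = 2,   expr_fold = 2),
                              STAU1  = list(hl_fold = 1.5, expr_fold = 1.5)
                            ),
                            reference_gene = "GAPDH_ref",
                            min_genes = 10L, fdr_max = 0.05,
                            config = NULL) {
  cfg <- list(seed = seed, generator = generator, thresholds = thresholds,
              band_folds = band_folds, factor_folds = factor_folds,
              reference_gene = reference_gene, min_genes = min_genes,
              fdr_max = fdr_max)
  if (!is.null(config)) {
    over <- if (is.character(config)) yaml::read_yaml(config) else config
    for (nm in names(over)) {
      if (nm == "generator" && is.list(over[[nm]]) &&
          !inherits(over[[nm]], "generator_config")) {
        cfg$generator <- do.call(generator_config,
                                 utils::modifyList(unclass(cfg$generator),
                                                   over[[nm]]))
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
  }
  cfg$generator$seed <- cfg$seed
  for (nm in c("h3k4me3", "rpkm", "short_halflife")) {
    v <- cfg$thresholds[[nm]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      stop("pipeline config: missing or non-positive threshold '", nm, "'")
    }
  }
  if (any(cfg$band_folds <= 1)) stop("band folds must be > 1")
  for (f in names(cfg$factor_folds)) {
    ff <- cfg$factor_folds[[f]]
    if (is.null(ff$hl_fold) || is.null(ff$expr_fold) ||
        ff$hl_fold <= 1 || ff$expr_fold <= 1) {
      stop("factor fold thresholds must be > 1 for ", f)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# Table 1-style peak stratum: high = intensity above threshold with a
# pol II peak; no = neither mark's peak present; low = the rest.
.peak_stratum <- function(profiles, h3k4me3_threshold) {
  ifelse(profiles$h3k4me3_intensity > h3k4me3_threshold & profiles$polii_peak,
         "high",
         ifelse(profiles$h3k4me3_intensity > 0 | profiles$polii_peak,
                "low", "no"))
}

#' Run the full analysis pipeline on a synthetic universe
#'
#' Generates the universe from the config seed, then runs every stage and
#' assembles a versioned report.  Identical config + seed gives an
#' identical report.  A subset of stages can be requested; upstream
#' intermediates are computed on demand and can be reused across calls via
#' the returned `state` attribute.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to report (default: all of
#'   `annotate`, `halflife`, `classify`, `simulate_default`,
#'   `linear_model`, `targets`, `enrich`, `erna`).
#' @param outdir Optional directory; when given, the JSON report and
#'   per-gene tables are written there.
#' @param state Optional cached state from a previous run (the `state`
#'   attribute of its result) to skip recomputation of upstream stages.
#' @return The report (a named list; `report_version`, `seed`,
#'   per-stage summaries), with the intermediate `state` environment
#'   attached as an attribute.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = .PIPELINE_STAGES,
                         outdir = NULL, state = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  st <- if (is.null(state)) new.env(parent = emptyenv()) else state
  need <- function(name, fn) {
    if (!exists(name, envir = st, inherits = FALSE)) {
      assign(name, fn(), envir = st)
    }
    get(name, envir = st, inherits = FALSE)
  }
  seed <- config$seed
  thr <- config$thresholds
  factors <- names(config$factor_folds)

  universe <- need("universe", function() generate_universe(config$generator))
  report <- list(report_version = "1.0", seed = seed,
                 n_genes = config$generator$n_genes, stages = list())
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message("stage ", name, ": done")
    res
  }

  chip <- need("chip", function() simulate_chip(universe, seed = seed + 1L))
  expr <- need("expr", function() {
    tabs <- lapply(seq_along(c("control", factors)), function(i) {
      simulate_expression(universe, seed = seed + 10L + i,
                          condition = c("control", factors)[i])
    })
    Reduce(function(a, b) merge(a, b, by = "gene_id", sort = FALSE), tabs)
  })

  if (any(c("annotate", "classify", "simulate_default", "linear_model",
            "targets", "enrich") %in% stages)) {
    profiles <- need("profiles", function() {
      run_stage("annotate", function() build_profiles(chip, universe$catalog))
    })
    if ("annotate" %in% stages) {
      report$stages$annotate <- list(
        n_genes = nrow(profiles),
        n_h3k4me3_peak = sum(profiles$h3k4me3_intensity > 0),
        n_polii_peak = sum(profiles$polii_peak))
    }
  }

  halflives <- need("halflives", function() {
    run_stage("halflife", function() {
      res <- lapply(c("control", factors), function(cond) {
        tc <- simulate_bric(universe, seed = seed + 20L +
                              match(cond, c("control", factors)),
                            condition = cond)
        suppressMessages(fit_all(tc, config$reference_gene))
      })
      names(res) <- c("control", factors)
      res
    })
  })
  if ("halflife" %in% stages) {
    report$stages$halflife <- lapply(halflives, function(h) {
      list(n_valid = sum(h$valid), n_invalid = sum(!h$valid),
           median_t_half = median(h$t_half[h$valid]))
    })
  }

  cls <- need("classification", function() {
    run_stage("classify", function() {
      cc <- classify(profiles, expr, halflives$control, thr,
                     condition = "control")
      pp <- cc[cc$chip_status == "plus" & cc$rna_status == "plus", ]
      fit <- fit_expression_regression(pp$h3k4me3_intensity, pp$rpkm)
      list(table = cc, fit = fit)
    })
  })
  if ("classify" %in% stages) {
    cc <- cls$table
    quad <- table(chip = cc$chip_status, rna = cc$rna_status)
    quad_list <- setNames(as.list(as.vector(quad)),
                          as.vector(outer(rownames(quad), colnames(quad),
                                          paste, sep = "_")))
    strat <- .peak_stratum(profiles[match(cc$gene_id, profiles$gene_id), ],
                           thr$h3k4me3)
    qt <- quadrant_table(strat, cc$rpkm, cuts = c(1, thr$rpkm))
    enr <- short_halflife_enrichment(cc)
    defaults <- vapply(config$band_folds, function(f) {
      default_halflife(cc, cls$fit, f)
    }, numeric(1L))
    report$stages$classify <- list(
      quadrant_counts = quad_list,
      n_ambiguous = sum(cc$chip_status == "ambiguous"),
      pearson_r_chip_rna = cls$fit$pearson_r,
      contingency = qt,
      short_enrichment_p = enr$p_value,
      default_halflife_h = setNames(as.list(defaults),
                                    paste0("x", config$band_folds)))
  }

  if ("simulate_default" %in% stages) {
    sim <- need("simulation", function() {
      run_stage("simulate_default", function() {
        t_def <- default_halflife(cls$table, cls$fit, min(config$band_folds))
        simulate_default_halflife(
          expr, halflives$control,
          setNames(cls$table$h3k4me3_intensity, cls$table$gene_id),
          t_default = t_def, folds = config$band_folds,
          condition = "control")
      })
    })
    s <- sim$summary
    s$regression <- unclass(s$regression)
    report$stages$simulate_default <- s
  }

  if ("linear_model" %in% stages) {
    models <- need("models", function() {
      run_stage("linear_model", function() {
        list(A = fit_linear_model(profiles, halflives$control, expr,
                                  include_halflife = FALSE,
                                  condition = "control"),
             B = fit_linear_model(profiles, halflives$control, expr,
                                  include_halflife = TRUE,
                                  condition = "control"))
      })
    })
    report$stages$linear_model <- list(
      model_a_r = models$A$r, model_b_r = models$B$r,
      n = models$A$n,
      coefficients_b = as.list(models$B$coefficients))
  }

  if (any(c("targets", "enrich") %in% stages)) {
    targets <- need("targets", function() {
      run_stage("targets", function() {
        lapply(setNames(factors, factors), function(fac) {
          ff <- config$factor_folds[[fac]]
          ce <- expr[c("gene_id", "control")]
          ke <- expr[c("gene_id", fac)]
          call_targets(halflives$control, halflives[[fac]], ce, ke,
                       hl_fold_min = ff$hl_fold, expr_fold_min = ff$expr_fold)
        })
      })
    })
  }
  if ("targets" %in% stages) {
    cc <- cls$table
    class_ids <- cc$gene_id[cc$chip_status == "plus" &
                              cc$rna_status == "minus" &
                              !is.na(cc$short_halflife) & cc$short_halflife]
    per_factor <- lapply(targets, function(tg) {
      fr <- if (length(class_ids)) class_fraction(tg, class_ids) else
        list(count = 0L, class_size = 0L, percent = NA_real_)
      list(n_targets = sum(tg$is_target), class_count = fr$count,
           class_size = fr$class_size, class_percent = fr$percent)
    })
    ov <- if (all(c("UPF1", "EXOSC5") %in% factors)) {
      overlap_sets(targets$UPF1$gene_id[targets$UPF1$is_target],
                   targets$EXOSC5$gene_id[targets$EXOSC5$is_target])
    } else NULL
    report$stages$targets <- list(per_factor = per_factor,
                                  upf1_exosc5_overlap = ov)
  }

  if ("enrich" %in% stages) {
    enrich <- need("enrichment", function() {
      run_stage("enrich", function() {
        tm <- .synthetic_term_map(universe, seed = seed + 40L)
        cc <- cls$table
        sel <- cc$gene_id[cc$chip_status == "plus" & cc$rna_status == "minus" &
                            !is.na(cc$short_halflife) & cc$short_halflife]
        gene_set_enrichment(sel, universe$truth$gene_id, tm,
                            min_genes = config$min_genes,
                            fdr_max = config$fdr_max)
      })
    })
    report$stages$enrich <- list(
      n_terms_reported = nrow(enrich),
      top_terms = utils::head(enrich$term_id, 5L))
  }

  if ("erna" %in% stages) {
    er <- need("erna_result", function() {
      run_stage("erna", function() {
        regions <- define_erna_regions(chip$peaks$H3K4me1, chip$peaks$H3K27Ac,
                                       universe$catalog, min_dist = 1500L)
        etc_ctrl <- .erna_timecourse(universe, seed + 50L, "control")
        res <- lapply(setNames(factors, factors), function(fac) {
          etc_kd <- .erna_timecourse(universe, seed + 50L +
                                       match(fac, factors), fac)
          erna_halflives(regions$id, etc_ctrl, config$reference_gene,
                         kd_timecourse = etc_kd, stabilized_fold = 2)
        })
        list(regions = regions, stabilized = res)
      })
    })
    report$stages$erna <- list(
      n_regions = nrow(er$regions),
      n_stabilized = lapply(er$stabilized, function(x) {
        sum(x$stabilized, na.rm = TRUE)
      }))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (exists("classification", envir = st, inherits = FALSE)) {
      write_table(cls$table, file.path(outdir, "classification.tsv"))
    }
  }
  attr(report, "state") <- st
  report
}

# eRNA time courses use the eRNA truth table plus the reference gene row.
.erna_timecourse <- function(universe, seed, condition) {
  ref <- universe$truth[universe$truth$is_reference, , drop = FALSE]
  tab <- universe$erna
  tab$gene_id <- tab$id
  keep <- intersect(c("gene_id", "t_half", "base_expr",
                      grep("^kd_fold_", names(tab), value = TRUE)),
                    names(tab))
  tab <- tab[keep]
  tab$is_reference <- FALSE
  reftab <- ref[c("gene_id", "t_half", "base_expr",
                  grep("^kd_fold_", names(ref), value = TRUE))]
  reftab$is_reference <- TRUE
  simulate_bric(rbind(tab, reftab), schedule = universe$config$schedule,
                noise_sd = universe$config$noise_bric, seed = seed,
                condition = condition)
}

# Flat synthetic gene -> term map: random background terms plus one term
# concentrated in short-lived genes so enrichment has signal to find.
.synthetic_term_map <- function(universe, seed, n_terms = 30L,
                                genes_per_term = 80L) {
  set.seed(seed)
  genes <- universe$truth$gene_id[!universe$truth$is_reference]
  short <- universe$truth$gene_id[universe$truth$short_component &
                                    !universe$truth$is_reference]
  tm <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(gene_id = sample(genes, min(genes_per_term, length(genes))),
               term_id = sprintf("T%03d", i), stringsAsFactors = FALSE)
  }))
  if (length(short) >= 20L) {
    tm <- rbind(tm, data.frame(
      gene_id = sample(short, min(60L, length(short))),
      term_id = "T_SHORT", stringsAsFactors = FALSE))
  }
  tm
}
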