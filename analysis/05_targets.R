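#!/usr/bin/env Rscript
# Stage 5: decay-factor target calling and class statistics.
#
# Calls UPF1/EXOSC5 targets at >= 2-fold (STAU1 at >= 1.5-fold) increases
# in BOTH half-life and expression under knockdown, measures their overlap
# and their share of the ChIP+/RNA-/short class, checks the calls against
# the generator's designated targets, and runs gene-set enrichment of the
# class against a synthetic term map.

suppressPackageStartupMessages(library(chromdecay))

expr <- read_expression("results/demo_inputs/expression.tsv")
truth <- read.table("results/demo_inputs/truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
cc <- read.table("results/classification.tsv", header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
hl_ctrl <- read.table("results/halflives_control.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)

class_ids <- cc$gene_id[cc$chip_status == "plus" & cc$rna_status == "minus" &
                          !is.na(cc$short_halflife) & cc$short_halflife]
cat(sprintf("ChIP+/RNA-/short class: %d genes\n", length(class_ids)))

folds <- list(UPF1 = 2, EXOSC5 = 2, STAU1 = 1.5)
called <- list()
for (fac in names(folds)) {
  hl_kd <- read.table(sprintf("results/halflives_%s.tsv", fac),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tg <- call_targets(hl_ctrl, hl_kd,
                     expr[c("gene_id", "control")], expr[c("gene_id", fac)],
                     hl_fold_min = folds[[fac]], expr_fold_min = folds[[fac]])
  write_table(tg, sprintf("results/targets_%s.tsv", fac))
  called[[fac]] <- tg$gene_id[tg$is_target]
  designated <- truth$gene_id[truth[[paste0("kd_fold_", fac)]] >= folds[[fac]]]
  fr <- if (length(class_ids)) class_fraction(tg, class_ids) else
    list(count = 0, percent = NA)
  cat(sprintf("%-7s %3d targets (designated: %3d, recovered: %3d); %d in class (%.2g%%)\n",
              fac, length(called[[fac]]), length(designated),
              length(intersect(called[[fac]], designated)),
              fr$count, fr$percent))
}

ov <- overlap_sets(called$UPF1, called$EXOSC5)
cat(sprintf("UPF1/EXOSC5 overlap: %d of %d and %d (Jaccard %.2f)\n",
            ov$n_intersect, ov$n_a, ov$n_b, ov$jaccard))

# gene-set enrichment of the class (synthetic flat term map: one term is
# concentrated in short-lived genes, the rest are background)
set.seed(42)
genes <- truth$gene_id
short <- truth$gene_id[truth$short_component]
tm <- do.call(rbind, c(
  lapply(1:30, function(i) data.frame(gene_id = sample(genes, 80),
                                      term_id = sprintf("T%03d", i))),
  list(data.frame(gene_id = sample(short, min(60, length(short))),
                  term_id = "T_SHORT"))))
enr <- gene_set_enrichment(class_ids, genes, tm)
write_table(enr, "results/enrichment.tsv")
cat(sprintf("enriched terms (FDR <= 0.05, > 10 genes): %s\n",
            if (nrow(enr)) paste(enr$term_id, collapse = ", ") else "none"))
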