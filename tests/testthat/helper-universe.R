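# Shared fixture builders.  Everything is generated in code; no files on
# disk beyond temporary ones created inside tests.

small_universe <- function(n = 200L, seed = 11L, ...) {
  generate_universe(generator_config(n_genes = n, seed = seed,
                                     genes_per_chrom = max(10L, n %/% 2L),
                                     n_erna = 10L, ...))
}

# A minimal gene catalog built by hand (0-based half-open).
tiny_catalog <- function() {
  df <- data.frame(
    gene_id = c("GA", "GB"),
    chrom = c("chr1", "chr1"),
    start = c(5000L, 20000L),
    end = c(9000L, 26000L),
    strand = c("+", "-"),
    biotype = "mRNA",
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("gene_catalog", "data.frame")
  df
}

# Noise-free exponential decay course at the given schedule.
exact_course <- function(t_half, times, gene = "g1") {
  structure(list(gene_id = gene, times = times,
                 fraction = exp(-log(2) / t_half * times),
                 measurable = TRUE, reason = NA_character_),
            class = "decay_course")
}

# Build a timecourse object in memory.
make_timecourse <- function(values, times) {
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1L] <- as.character(times)
  rownames(df) <- NULL
  attr(df, "times") <- times
  class(df) <- c("timecourse", "data.frame")
  df
}
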