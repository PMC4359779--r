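#' @importFrom stats coef cor fisher.test lm median p.adjust phyper predict
#'   quantile rbinom rlnorm rnorm runif sd setNames wilcox.test
#' @importFrom utils read.table write.table
NULL

# ---------------------------------------------------------------------------
# Coordinate convention: everything inside the package is 0-based half-open
# [start, end), the BED convention.  Inputs written 1-based closed must be
# declared via `one_based = TRUE` on the readers, which absorbs the off-by-one
# exactly once at the boundary.
# ---------------------------------------------------------------------------

#' Read a gene catalog from a BED-like file
#'
#' Parses a BED6-style table (chrom, start, end, name, score, strand) into a
#' gene catalog.  Coordinates are interpreted as 0-based half-open unless
#' `one_based = TRUE`, in which case 1-based closed input coordinates are
#' converted on entry.  The transcription start site (TSS) is derived
#' strand-aware: `start` for + genes, `end - 1` for - genes (the biological
#' 5' end).
#'
#' @param path Path to a whitespace-delimited BED-like file with >= 6 columns.
#' @param biotype Biotype label attached to every gene (`"mRNA"` or
#'   `"lincRNA"`), or `NA` to take it from a 7th column when present.
#' @param one_based Set `TRUE` when the file uses 1-based closed coordinates.
#' @return A `data.frame` of class `gene_catalog` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`, `tss`.
#' @export
read_gene_catalog <- function(path, biotype = "mRNA", one_based = FALSE) {
  raw <- .read_bed_lines(path, min_cols = 6L)
  df <- data.frame(
    gene_id = as.character(raw[[4L]]),
    chrom   = as.character(raw[[1L]]),
    start   = .as_coord(raw[[2L]], path, "start"),
    end     = .as_coord(raw[[3L]], path, "end"),
    strand  = as.character(raw[[6L]]),
    stringsAsFactors = FALSE
  )
  if (one_based) df$start <- df$start - 1L
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad)) {
    stop("malformed strand at line ", bad[1L], " of ", path, ": '",
         df$strand[bad[1L]], "'")
  }
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad)) {
    stop("invalid interval at line ", bad[1L], " of ", path,
         ": need 0 <= start < end")
  }
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id in ", path, ": ", df$gene_id[which(dup)[1L]])
  }
  if (is.na(biotype) && ncol(raw) >= 7L) {
    df$biotype <- as.character(raw[[7L]])
  } else {
    df$biotype <- if (is.na(biotype)) "mRNA" else biotype
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Write a gene catalog as BED6 (+ biotype column)
#'
#' @param catalog A `gene_catalog`.
#' @param path Output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  out <- data.frame(catalog$chrom, catalog$start, catalog$end,
                    catalog$gene_id, 0L, catalog$strand, catalog$biotype)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED3+ file
#'
#' Column 4 (when numeric) or column 5 is taken as the peak intensity
#' (summed tags); absent intensity defaults to 0.
#'
#' @inheritParams read_gene_catalog
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `intensity`.
#' @export
read_peaks <- function(path, one_based = FALSE) {
  raw <- .read_bed_lines(path, min_cols = 3L, allow_empty = TRUE)
  if (nrow(raw) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), intensity = numeric()))
  }
  intensity <- rep(0, nrow(raw))
  if (ncol(raw) >= 5L && is.numeric(raw[[5L]])) {
    intensity <- as.numeric(raw[[5L]])
  } else if (ncol(raw) >= 4L && is.numeric(raw[[4L]])) {
    intensity <- as.numeric(raw[[4L]])
  }
  df <- data.frame(
    chrom = as.character(raw[[1L]]),
    start = .as_coord(raw[[2L]], path, "start"),
    end   = .as_coord(raw[[3L]], path, "end"),
    intensity = intensity,
    stringsAsFactors = FALSE
  )
  if (one_based) df$start <- df$start - 1L
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop("invalid peak at line ", bad[1L], " of ", path, ": start >= end")
  }
  if (any(df$intensity < 0)) stop("negative peak intensity in ", path)
  df
}

#' Write peaks as BED with the intensity in column 5
#' @param peaks Peak `data.frame` (`chrom`, `start`, `end`, `intensity`).
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    sprintf("peak_%d", seq_len(nrow(peaks))),
                    format(peaks$intensity, digits = 15, scientific = FALSE,
                           trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a coverage track from a bedGraph file
#'
#' bedGraph semantics: 0-based half-open step intervals carrying a tag-count
#' value.  Intervals must be non-overlapping within a chromosome and values
#' non-negative.
#'
#' @inheritParams read_gene_catalog
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_coverage <- function(path, one_based = FALSE) {
  raw <- .read_bed_lines(path, min_cols = 4L, allow_empty = TRUE)
  if (nrow(raw) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  df <- data.frame(
    chrom = as.character(raw[[1L]]),
    start = .as_coord(raw[[2L]], path, "start"),
    end   = .as_coord(raw[[3L]], path, "end"),
    value = as.numeric(raw[[4L]]),
    stringsAsFactors = FALSE
  )
  if (one_based) df$start <- df$start - 1L
  if (any(df$start >= df$end)) stop("invalid interval (start >= end) in ", path)
  if (any(is.na(df$value)) || any(df$value < 0)) {
    stop("negative or non-numeric coverage value in ", path)
  }
  .check_no_overlap(df, path)
  df
}

#' Write a coverage track as bedGraph
#' @param track Coverage `data.frame` (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @export
write_coverage <- function(track, path) {
  out <- data.frame(track$chrom, track$start, track$end,
                    format(track$value, digits = 15, scientific = FALSE,
                           trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression table (TSV with header)
#'
#' First column is `gene_id`; each remaining column is a named condition of
#' RPKM values.  All conditions share one gene universe.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.frame` with `gene_id` plus one numeric column per condition.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs gene_id + >=1 condition: ", path)
  names(df)[1L] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  vals <- df[-1L]
  if (any(vapply(vals, function(v) any(is.na(v)) || !is.numeric(v) || any(v < 0),
                 logical(1L)))) {
    stop("negative or non-numeric RPKM in ", path)
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
  df
}

#' Write an expression table as TSV
#' @param expression Expression `data.frame` from [read_expression()].
#' @param path Output path.
#' @export
write_expression <- function(expression, path) {
  write_table(expression, path)
}

#' Read a BrU pulse-chase time-course table
#'
#' TSV with header: first column `gene_id`, remaining column names are the
#' chase time points in hours (e.g. `0`, `4`, `8`, `12`).  Times must be
#' strictly increasing and start at 0.
#'
#' @param path Path to the TSV.
#' @return A `timecourse` object: a `data.frame` with `gene_id` and one
#'   column per time point, plus a `times` attribute (numeric hours).
#' @export
read_timecourse <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  times <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (any(is.na(times))) stop("non-numeric time-point header in ", path)
  if (length(times) < 2L || times[1L] != 0) {
    stop("time course must start at t = 0: ", path)
  }
  if (any(diff(times) <= 0)) stop("time points not strictly increasing in ", path)
  vals <- as.matrix(df[-1L])
  if (any(is.na(vals)) || any(vals < 0)) stop("negative or missing RPKM in ", path)
  attr(df, "times") <- times
  class(df) <- c("timecourse", "data.frame")
  df
}

#' Write a time-course table as TSV
#' @param tc A `timecourse` object.
#' @param path Output path.
#' @export
write_timecourse <- function(tc, path) {
  write_table(as.data.frame(tc), path)
}

#' Write any result table as TSV with header
#' @param result A `data.frame`.
#' @param path Output path.
#' @export
write_table <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Time points of a time course
#' @param tc A `timecourse` object.
#' @return Numeric vector of time points in hours.
#' @export
timecourse_times <- function(tc) attr(tc, "times")

# -- internal helpers --------------------------------------------------------

.read_bed_lines <- function(path, min_cols, allow_empty = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0L || length(readLines(path, n = 1L)) == 0L) {
    if (allow_empty) return(data.frame())
    stop("empty file: ", path)
  }
  raw <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#", fill = FALSE),
    error = function(e) stop("malformed table in ", path, ": ",
                             conditionMessage(e))
  )
  if (ncol(raw) < min_cols) {
    stop("expected >= ", min_cols, " columns in ", path, ", found ", ncol(raw))
  }
  raw
}

.as_coord <- function(x, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop("malformed ", what, " coordinate at line ", bad[1L], " of ", path)
  }
  v
}

.check_no_overlap <- function(df, path) {
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    o <- order(sub$start)
    if (any(sub$start[o][-1L] < sub$end[o][-length(o)])) {
      stop("overlapping coverage intervals on ", ch, " in ", path)
    }
  }
  invisible(TRUE)
}

# Convert 0-based half-open intervals to an IRanges (1-based closed) view.
.as_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# Convert to GRanges for cross-chromosome overlap queries.
.as_granges <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = .as_iranges(start0, end0))
}
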