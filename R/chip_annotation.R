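# Peak-to-gene assignment via TSS windows and tag quantification over
# windows and gene bodies.  All interval logic goes through
# GenomicRanges/IRanges on the package's 0-based half-open coordinates.

#' Assign ChIP-seq peaks to genes via TSS windows
#'
#' A gene receives a peak iff the window `[TSS - window_bp, TSS + window_bp)`
#' (clipped at 0) and the peak interval intersect in at least one base.
#' One peak may serve several genes.
#'
#' @param peaks Peak `data.frame` (`chrom`, `start`, `end`, `intensity`).
#' @param catalog A `gene_catalog`.
#' @param window_bp Half-width of the TSS window in bp (default 1500).
#' @return A `data.frame` with one row per (gene, peak) assignment:
#'   `gene_id`, `peak_start`, `peak_end`, `intensity`; zero rows when
#'   nothing overlaps.
#' @export
assign_peaks <- function(peaks, catalog, window_bp = 1500L) {
  empty <- data.frame(gene_id = character(), peak_start = integer(),
                      peak_end = integer(), intensity = numeric())
  if (nrow(peaks) == 0L || nrow(catalog) == 0L) return(empty)
  win_start <- pmax(catalog$tss - window_bp, 0L)
  win_end <- catalog$tss + window_bp
  gr_win <- .as_granges(catalog$chrom, win_start, win_end)
  gr_peak <- .as_granges(peaks$chrom, peaks$start, peaks$end)
  hits <- GenomicRanges::findOverlaps(gr_win, gr_peak)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(gene_id = catalog$gene_id[qi],
             peak_start = peaks$start[si],
             peak_end = peaks$end[si],
             intensity = peaks$intensity[si],
             stringsAsFactors = FALSE)
}

#' Sum coverage tags over a peak region
#'
#' Sums per-base values over `[start, end)`: each coverage step interval
#' contributes its value times the overlap length.  Regions outside the
#' track sum to 0.
#'
#' @param track Coverage `data.frame` (`chrom`, `start`, `end`, `value`).
#' @param chrom,start,end Query region (0-based half-open).
#' @return Tag sum (numeric scalar).
#' @export
region_tags <- function(track, chrom, start, end) {
  sub <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0L) return(0)
  ov <- pmin(sub$end, end) - pmax(sub$start, start)
  sum(sub$value[ov > 0] * ov[ov > 0])
}

#' Tag sum over a peak
#' @param track Coverage track.
#' @param peak One-row peak `data.frame` (or a list with `chrom`, `start`,
#'   `end`).
#' @return Tag sum.
#' @export
peak_intensity <- function(track, peak) {
  region_tags(track, peak$chrom[1L], peak$start[1L], peak$end[1L])
}

#' Tag sum over a gene-anchored window
#'
#' @param track Coverage track.
#' @param gene One-row `gene_catalog` entry.
#' @param mode `"tss1k"` (TSS +/- 1 kb), `"tss1500"` (TSS +/- 1.5 kb) or
#'   `"body"` (the gene body `[start, end)`).  The TSS is strand-aware.
#' @return Tag sum.
#' @export
window_intensity <- function(track, gene, mode = c("tss1k", "tss1500", "body")) {
  mode <- match.arg(mode)
  if (mode == "body") {
    return(region_tags(track, gene$chrom[1L], gene$start[1L], gene$end[1L]))
  }
  w <- if (mode == "tss1k") 1000L else 1500L
  tss <- gene$tss[1L]
  region_tags(track, gene$chrom[1L], max(tss - w, 0L), tss + w)
}

#' Build per-gene ChIP profiles across all marks
#'
#' Classification features: `h3k4me3_intensity` is the tag sum over the
#' regions of all H3K4me3 peaks assigned to the gene's TSS +/- 1.5 kb
#' window (tags per peak, not window coverage); `polii_peak` marks an
#' assigned pol II peak.  Model features: TSS +/- 1 kb tag sums for
#' H3K4me3/H3K27Ac and gene-body sums for H3K27me3/H3K36me3.  Missing marks
#' yield 0 with a warning.
#'
#' @param marks A list with elements `peaks` (named list of peak tables;
#'   `H3K4me3` and `polII` used) and `coverage` (named list of tracks;
#'   `H3K4me3`, `H3K27Ac`, `H3K27me3`, `H3K36me3` used).
#' @param catalog A `gene_catalog`.
#' @param window_bp TSS window half-width for peak assignment.
#' @return A `data.frame` of class `gene_chip_profile`, one row per gene.
#' @export
build_profiles <- function(marks, catalog, window_bp = 1500L) {
  n <- nrow(catalog)
  get_peaks <- function(mark) {
    p <- marks$peaks[[mark]]
    if (is.null(p)) {
      warning("no peak set for mark ", mark, "; treating as absent")
      p <- data.frame(chrom = character(), start = integer(),
                      end = integer(), intensity = numeric())
    }
    p
  }
  get_cov <- function(mark) {
    tr <- marks$coverage[[mark]]
    if (is.null(tr)) {
      warning("no coverage track for mark ", mark, "; intensities set to 0")
      tr <- data.frame(chrom = character(), start = integer(),
                       end = integer(), value = numeric())
    }
    tr
  }

  k4_assign <- assign_peaks(get_peaks("H3K4me3"), catalog, window_bp)
  k4_cov <- get_cov("H3K4me3")
  k4_intensity <- setNames(numeric(n), catalog$gene_id)
  if (nrow(k4_assign)) {
    # tag sum over each assigned peak's region; distinct peaks summed per gene
    per <- vapply(seq_len(nrow(k4_assign)), function(i) {
      g <- match(k4_assign$gene_id[i], catalog$gene_id)
      region_tags(k4_cov, catalog$chrom[g],
                  k4_assign$peak_start[i], k4_assign$peak_end[i])
    }, numeric(1L))
    dedup <- !duplicated(k4_assign[c("gene_id", "peak_start", "peak_end")])
    agg <- tapply(per[dedup], k4_assign$gene_id[dedup], sum)
    k4_intensity[names(agg)] <- as.numeric(agg)
  }
  pol_assign <- assign_peaks(get_peaks("polII"), catalog, window_bp)
  polii_peak <- catalog$gene_id %in% pol_assign$gene_id

  cov_feature <- function(mark, mode) {
    tr <- get_cov(mark)
    vapply(seq_len(n), function(i) {
      window_intensity(tr, catalog[i, , drop = FALSE], mode)
    }, numeric(1L))
  }

  out <- data.frame(
    gene_id = catalog$gene_id,
    h3k4me3_intensity = as.numeric(k4_intensity),
    polii_peak = polii_peak,
    h3k4me3_1kb = cov_feature("H3K4me3", "tss1k"),
    h3k27ac_1kb = cov_feature("H3K27Ac", "tss1k"),
    h3k27me3_body = cov_feature("H3K27me3", "body"),
    h3k36me3_body = cov_feature("H3K36me3", "body"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_chip_profile", "data.frame")
  out
}
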