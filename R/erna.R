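# Intergenic enhancer-RNA regions: intersections of H3K4me1 and H3K27Ac
# peaks, merged, and kept only when at least `min_dist` bp away from every
# gene body.

#' Define enhancer-RNA regions from H3K4me1/H3K27Ac overlap
#'
#' Intersects the two peak sets, merges overlapping intersections into
#' maximal regions, and discards any region within `min_dist` bp of a gene
#' body (gene `[start, end)` expanded by `min_dist` on both sides;
#' edge-to-edge distance).
#'
#' @param h3k4me1_peaks,h3k27ac_peaks Peak `data.frame`s.
#' @param catalog A `gene_catalog`.
#' @param min_dist Minimum clearance from any gene body (bp).
#' @return A `data.frame`: `id` (`chrom:start-end`), `chrom`, `start`,
#'   `end`, `dist_to_gene` (bp to the nearest gene body; `Inf` when the
#'   chromosome has no genes).
#' @export
define_erna_regions <- function(h3k4me1_peaks, h3k27ac_peaks, catalog,
                                min_dist = 1500L) {
  empty <- data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      dist_to_gene = numeric())
  if (nrow(h3k4me1_peaks) == 0L || nrow(h3k27ac_peaks) == 0L) return(empty)
  gr1 <- .as_granges(h3k4me1_peaks$chrom, h3k4me1_peaks$start,
                     h3k4me1_peaks$end)
  gr2 <- .as_granges(h3k27ac_peaks$chrom, h3k27ac_peaks$start,
                     h3k27ac_peaks$end)
  inter <- GenomicRanges::reduce(GenomicRanges::intersect(
    GenomicRanges::reduce(gr1), GenomicRanges::reduce(gr2)))
  if (length(inter) == 0L) return(empty)
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(inter)),
    start = GenomicRanges::start(inter) - 1L,
    end = GenomicRanges::end(inter),
    stringsAsFactors = FALSE
  )
  dist <- vapply(seq_len(nrow(regions)), function(i) {
    g <- catalog[catalog$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(Inf)
    # edge-to-edge gap between [start, end) intervals; 0 when overlapping
    max(0, min(pmax(g$start - regions$end[i], regions$start[i] - g$end)))
  }, numeric(1L))
  keep <- dist >= min_dist
  regions <- regions[keep, , drop = FALSE]
  regions$dist_to_gene <- dist[keep]
  regions$id <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  rownames(regions) <- NULL
  regions[c("id", "chrom", "start", "end", "dist_to_gene")]
}

#' RPKM-style quantification of a region
#'
#' value = count / (length_kb * depth_millions): reads normalized by region
#' length (to 1 kb) and sequencing depth (to per million).
#'
#' @param read_count Reads mapped to the region.
#' @param region One-row region `data.frame` (`start`, `end`), or a list
#'   with those fields.
#' @param depth_millions Library depth in millions of mapped reads.
#' @return Normalized expression value.
#' @export
quantify_region <- function(read_count, region, depth_millions) {
  len_kb <- (region$end[1L] - region$start[1L]) / 1000
  if (len_kb <= 0) stop("region has non-positive length")
  if (depth_millions <= 0) stop("depth must be positive")
  read_count / (len_kb * depth_millions)
}

#' Half-lives (and stabilization calls) for enhancer-RNA regions
#'
#' Normalizes each region's time course against the reference gene and
#' fits first-order decay exactly as for genes, with the region id as the
#' gene id.  Regions absent from the time course are skipped with a
#' warning.  When a knockdown time course is supplied, regions whose
#' half-life is extended by at least `stabilized_fold` are flagged
#' stabilized (half-life criterion alone, as for eRNA analysis).
#'
#' @param region_ids Character vector of region ids.
#' @param timecourse A `timecourse` whose rows are region ids (plus the
#'   reference gene).
#' @param reference_gene Reference id for normalization.
#' @param kd_timecourse Optional knockdown `timecourse`.
#' @param stabilized_fold Half-life fold threshold for the stabilization
#'   call.
#' @return Half-life record table (one row per present region), with
#'   columns `kd_t_half`, `halflife_fold`, `stabilized` when a knockdown
#'   course is given.
#' @export
erna_halflives <- function(region_ids, timecourse, reference_gene,
                           kd_timecourse = NULL, stabilized_fold = 2) {
  present <- region_ids %in% timecourse$gene_id
  if (any(!present)) {
    warning(sum(!present), " region(s) absent from time course; skipped")
  }
  ids <- region_ids[present]
  recs <- do.call(rbind, lapply(ids, function(id) {
    fit_halflife(normalize_course(timecourse, id, reference_gene))
  }))
  if (is.null(kd_timecourse)) return(recs)
  kd <- do.call(rbind, lapply(ids, function(id) {
    fit_halflife(normalize_course(kd_timecourse, id, reference_gene))
  }))
  calls <- call_targets(recs, kd, hl_fold_min = stabilized_fold)
  i <- match(recs$gene_id, calls$gene_id)
  recs$kd_t_half <- kd$t_half[match(recs$gene_id, kd$gene_id)]
  recs$halflife_fold <- calls$halflife_fold[i]
  recs$stabilized <- calls$is_target[i]
  recs
}
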