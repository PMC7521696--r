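# Gene-to-QTL interval mapping on 0-based half-open coordinates.

as_granges0 <- function(df, seqlevels) {
  # internal 0-based half-open -> GRanges 1-based inclusive
  GenomicRanges::GRanges(factor(df$chrom, levels = seqlevels),
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Map genes onto QTL intervals
#'
#' A gene hits a QTL when both lie on the same chromosome and their intervals
#' share at least 1 bp (half-open arithmetic: an interval ending where
#' another starts does not overlap it). A gene may hit several QTLs and vice
#' versa. Strand is ignored (QTLs are strandless).
#'
#' @param genes `gene_intervals` data.frame (gene_id, chrom, start, end).
#' @param qtls `qtl_intervals` data.frame (qtl_id, trait, chrom, start, end).
#' @return data.frame (gene_id, qtl_id, trait, overlap_bp) sorted by
#'   (trait, qtl_id, gene_id).
#' @export
map_genes_to_qtls <- function(genes, qtls) {
  empty <- data.frame(gene_id = character(), qtl_id = character(),
                      trait = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(genes) || !nrow(qtls)) return(empty)
  lev <- sort(unique(c(genes$chrom, qtls$chrom)))
  gg <- as_granges0(genes, lev)
  qq <- as_granges0(qtls, lev)
  ov <- GenomicRanges::findOverlaps(gg, qq, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gg)[qh], GenomicRanges::ranges(qq)[sh]))
  hits <- data.frame(gene_id = genes$gene_id[qh], qtl_id = qtls$qtl_id[sh],
                     trait = qtls$trait[sh], overlap_bp = as.integer(w),
                     stringsAsFactors = FALSE)
  hits[order(hits$trait, hits$qtl_id, hits$gene_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Per-trait summary of QTL hits
#'
#' Counts, per trait, the distinct QTLs hit and the distinct genes hitting
#' them. A gene hitting two QTLs of the same trait counts once for that
#' trait; genes are not deduplicated across traits.
#'
#' @param hits data.frame from [map_genes_to_qtls()].
#' @return data.frame (trait, n_qtls_hit, n_unique_genes).
#' @export
summarize_by_trait <- function(hits) {
  if (!nrow(hits))
    return(data.frame(trait = character(), n_qtls_hit = integer(),
                      n_unique_genes = integer(), stringsAsFactors = FALSE))
  sp <- split(hits, hits$trait)
  data.frame(trait = names(sp),
             n_qtls_hit = vapply(sp, function(d)
               length(unique(d$qtl_id)), 1L),
             n_unique_genes = vapply(sp, function(d)
               length(unique(d$gene_id)), 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
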