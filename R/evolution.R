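#' Select the top and bottom TFCRs of a species, scaled by genome size
#'
#' TFCRs are sorted from high to low complexity (ties broken by
#' strength, chromosome and start for determinism); the first
#' `round(50 * N)` are the top set and the last `round(50 * N)` the
#' bottom set, where `N` is the species' genome-size multiple relative
#' to yeast (`N = 1` selects 50 each, the yeast rule).
#'
#' @param tfcrs TFCR `GRanges`.
#' @param n_multiple genome-size multiple `N` (see
#'   [genome_assembly()]`$size_multiple_n`).
#' @param per_unit TFCRs selected per unit of `N` (50).
#' @return list with `top` and `bottom` `GRanges` and the selection
#'   size `k`.
#' @export
select_top_bottom <- function(tfcrs, n_multiple, per_unit = 50L) {
  if (n_multiple <= 0) stop("n_multiple must be positive")
  k <- as.integer(round(per_unit * n_multiple))
  if (k < 1L) stop("selection size round(50 * N) is zero")
  if (length(tfcrs) < 2L * k) {
    stop(sprintf("need at least %d TFCRs for top+bottom selection, got %d",
                 2L * k, length(tfcrs)))
  }
  ord <- order(-tfcrs$complexity, -tfcrs$strength,
               as.character(GenomicRanges::seqnames(tfcrs)),
               GenomicRanges::start(tfcrs))
  sorted <- tfcrs[ord]
  list(top = sorted[seq_len(k)],
       bottom = sorted[seq.int(length(sorted) - k + 1L, length(sorted))],
       k = k)
}

#' Fraction of TFCRs associated with genes (promoter overlap)
#'
#' A TFCR is associated with a gene when it overlaps the gene's
#' promoter by at least 1 bp.
#'
#' @param tfcrs non-empty TFCR `GRanges` (e.g. a top or bottom set).
#' @param genes annotated gene `GRanges`.
#' @return fraction of `tfcrs` overlapping at least one promoter.
#' @export
gene_association_fraction <- function(tfcrs, genes) {
  if (length(tfcrs) == 0L) stop("tfcrs must be non-empty")
  if (length(genes) == 0L) stop("no gene models supplied")
  mean(IRanges::overlapsAny(tfcrs, promoter_ranges(genes),
                            ignore.strand = TRUE))
}

#' Fraction of genes associated with TFCRs (gene-side view)
#'
#' @param tfcrs TFCR `GRanges`.
#' @param genes non-empty annotated gene `GRanges`.
#' @return fraction of genes whose promoter overlaps at least one TFCR.
#' @export
associated_gene_fraction <- function(tfcrs, genes) {
  if (length(genes) == 0L) stop("no gene models supplied")
  mean(IRanges::overlapsAny(promoter_ranges(genes), tfcrs,
                            ignore.strand = TRUE))
}
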