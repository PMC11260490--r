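#' Annotate TFCRs against gene models
#'
#' Assigns each TFCR a genomic-feature category with priority
#' promoter > exon > intergenic on at-least-1-bp overlap (gene models
#' here are single-exon, so the `intron` category of the full
#' vocabulary can never fire), plus the nearest gene by
#' promoter-to-TFCR gap distance (ties broken by smaller gene id) and
#' the gap distances to that gene's promoter and TSS.
#'
#' @param tfcrs TFCR `GRanges`.
#' @param genes annotated gene `GRanges` from [read_gene_models()] /
#'   [make_dataset()].
#' @return data.frame with columns `tfcr_id`, `category`,
#'   `nearest_gene_id`, `distance_to_promoter`, `distance_to_tss`.
#' @export
annotate_tfcrs <- function(tfcrs, genes) {
  if (length(genes) == 0L) stop("no gene models supplied")
  if (length(tfcrs) == 0L) {
    return(data.frame(tfcr_id = character(0), category = character(0),
                      nearest_gene_id = character(0),
                      distance_to_promoter = numeric(0),
                      distance_to_tss = numeric(0)))
  }
  proms <- promoter_ranges(genes)
  in_prom <- IRanges::overlapsAny(tfcrs, proms, ignore.strand = TRUE)
  in_gene <- IRanges::overlapsAny(tfcrs, genes, ignore.strand = TRUE)
  category <- ifelse(in_prom, "promoter",
                     ifelse(in_gene, "exon", "intergenic"))

  # nearest gene by promoter gap; deterministic tie-break on gene_id
  n <- length(tfcrs)
  nearest <- character(n)
  dprom <- numeric(n)
  dtss <- numeric(n)
  tf_chrom <- as.character(GenomicRanges::seqnames(tfcrs))
  g_chrom <- as.character(GenomicRanges::seqnames(proms))
  for (chrom in unique(tf_chrom)) {
    ti <- which(tf_chrom == chrom)
    gi <- which(g_chrom == chrom)
    if (length(gi) == 0L) gi <- seq_along(proms) # fall back to all genes
    ts <- GenomicRanges::start(tfcrs)[ti]
    te <- GenomicRanges::end(tfcrs)[ti]
    ps <- GenomicRanges::start(proms)[gi]
    pe <- GenomicRanges::end(proms)[gi]
    ids <- proms$gene_id[gi]
    ord <- order(ids)
    for (k in seq_along(ti)) {
      gap <- pmax(0, pmax(ps - te[k], ts[k] - pe))
      best <- ord[which.min(gap[ord])]
      nearest[ti[k]] <- ids[best]
      dprom[ti[k]] <- gap[best]
      tss <- genes$tss[gi[best]]
      dtss[ti[k]] <- max(0, max(tss - te[k], ts[k] - tss))
    }
  }
  data.frame(
    tfcr_id = tfcrs$tfcr_id,
    category = category,
    nearest_gene_id = nearest,
    distance_to_promoter = dprom,
    distance_to_tss = dtss,
    stringsAsFactors = FALSE
  )
}

#' Fraction of TFCRs located in promoters
#'
#' @param tfcrs non-empty TFCR `GRanges`.
#' @param genes annotated gene `GRanges`.
#' @return `|promoter-overlapping TFCRs| / |TFCRs|`.
#' @export
promoter_fraction <- function(tfcrs, genes) {
  if (length(tfcrs) == 0L) stop("tfcrs must be non-empty")
  if (length(genes) == 0L) stop("no gene models supplied")
  mean(IRanges::overlapsAny(tfcrs, promoter_ranges(genes),
                            ignore.strand = TRUE))
}

#' Genome-size-normalised mode of a distance distribution
#'
#' Summarises TFCR-to-nearest-gene distances by the peak (mode) of
#' their Gaussian KDE (Silverman bandwidth), divided by the genome-size
#' multiple `N = genome_size / yeast_size` so the statistic is
#' comparable across species with very different genome sizes.
#'
#' @param distances at least 10 distances in bp.
#' @param assembly [genome_assembly()] of the species.
#' @param yeast_size reference genome size (denominator of `N`).
#' @return mode of the distance KDE divided by `N`.
#' @export
normalized_distance_mode <- function(distances, assembly,
                                     yeast_size = YEAST_GENOME_SIZE) {
  if (length(distances) < 10L) {
    stop("need at least 10 distances, got ", length(distances))
  }
  n_mult <- assembly$genome_size / yeast_size
  if (length(unique(distances)) == 1L) {
    return(distances[[1L]] / n_mult) # degenerate: KDE mode is the point
  }
  d <- stats::density(distances, bw = "nrd0")
  d$x[which.max(d$y)] / n_mult
}
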