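#' RegulatoryScore: synchronisation of TFCR complexity and expression
#'
#' Both TFCR complexity and gene expression are divided into ten
#' equal-count groups (0 = lowest, 9 = highest). For a gene whose
#' promoter-associated TFCR sits in complexity group `g_tfcr` and whose
#' expression sits in group `g_expr`,
#'
#' \deqn{score = \frac{g_{tfcr}}{9} \cdot \frac{g_{expr}}{9} \cdot
#'   e^{-|g_{tfcr} - g_{expr}|/5}}
#'
#' The score lies in \[0, 1\]; it is 1 only at (9, 9), 0 exactly when
#' either group is 0, symmetric in its arguments, and penalises
#' mismatched groups through the exponential term, so a high score
#' means a complex promoter TFCR *and* high expression *in matching
#' deciles* — good synchronisation.
#'
#' @param g_tfcr,g_expr integer decile groups in 0..9 (vectorised).
#' @return numeric score(s) in \[0, 1\].
#' @examples
#' regulatory_score(9, 9) # 1
#' regulatory_score(5, 5) # 25/81, just above the 0.3 threshold
#' @export
regulatory_score <- function(g_tfcr, g_expr) {
  if (any(g_tfcr != round(g_tfcr)) || any(g_expr != round(g_expr)) ||
      any(g_tfcr < 0 | g_tfcr > 9) || any(g_expr < 0 | g_expr > 9)) {
    stop("decile groups must be integers in 0..9")
  }
  (g_tfcr / 9) * (g_expr / 9) * exp(-abs(g_tfcr - g_expr) / 5)
}

# Equal-count decile groups 0..9 of a numeric vector, ascending, with
# deterministic tie-breaking by `tie_break` (e.g. gene id).
decile_groups <- function(x, tie_break = seq_along(x)) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 values for decile groups")
  ord <- order(x, tie_break)
  grp <- integer(n)
  grp[ord] <- as.integer(floor((seq_len(n) - 1L) * 10 / n))
  grp
}

#' Build the per-gene RegulatoryScore table
#'
#' Associates every TFCR with the gene whose promoter is nearest (gap
#' distance; ties to the smaller gene id). A gene hit by several TFCRs
#' keeps the one with the highest complexity (ties: strength, then
#' coordinates). `G_tfcr` is the TFCR's complexity decile over the
#' whole TFCR set; `G_expr` is the gene's expression decile over all
#' genes in the expression table. Genes with no associated TFCR are
#' emitted with `NA` groups and score and are excluded from ranking.
#'
#' @param tfcrs TFCR `GRanges` (decile groups are computed here if the
#'   `decile_group` column is missing).
#' @param genes annotated gene `GRanges`.
#' @param expression expression list (`stage_id`, `values`) as from
#'   [read_expression()], covering at least 10 genes.
#' @return data.frame with `gene_id`, `g_tfcr`, `g_expr`, `score`,
#'   `tfcr_id`, `distance` (TFCR-to-promoter gap, bp), ordered by
#'   decreasing score with `NA`s last.
#' @export
build_gene_table <- function(tfcrs, genes, expression) {
  if (length(expression$values) == 0L) stop("empty expression table")
  if (length(expression$values) < 10L) {
    stop("need at least 10 expressed genes for decile groups")
  }
  if (length(tfcrs) < 10L) stop("need at least 10 TFCRs for decile groups")
  if (is.null(tfcrs$decile_group) || all(is.na(tfcrs$decile_group))) {
    tfcrs <- assign_decile_groups(tfcrs)
  }
  ann <- annotate_tfcrs(tfcrs, genes)
  expr_genes <- names(expression$values)
  g_expr_all <- stats::setNames(
    decile_groups(as.numeric(expression$values), expr_genes), expr_genes)

  # per gene: the max-complexity TFCR among those whose nearest gene it is
  tab <- data.frame(
    gene_id = ann$nearest_gene_id,
    tfcr_id = tfcrs$tfcr_id,
    complexity = tfcrs$complexity,
    strength = tfcrs$strength,
    chrom = as.character(GenomicRanges::seqnames(tfcrs)),
    start = GenomicRanges::start(tfcrs),
    g_tfcr = tfcrs$decile_group,
    distance = ann$distance_to_promoter,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$gene_id, -tab$complexity, -tab$strength,
                   tab$chrom, tab$start), ]
  tab <- tab[!duplicated(tab$gene_id), ]

  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  m <- match(out$gene_id, tab$gene_id)
  out$g_tfcr <- tab$g_tfcr[m]
  out$tfcr_id <- tab$tfcr_id[m]
  out$distance <- tab$distance[m]
  out$g_expr <- unname(g_expr_all[out$gene_id])
  has <- !is.na(out$g_tfcr) & !is.na(out$g_expr)
  out$score <- NA_real_
  out$score[has] <- regulatory_score(out$g_tfcr[has], out$g_expr[has])
  out[order(-out$score, out$gene_id, na.last = TRUE),
      c("gene_id", "g_tfcr", "g_expr", "score", "tfcr_id", "distance")]
}

# Top-fraction gene set of one species' table: strict floor(frac * n)
# of the score-ranked scored genes.
top_score_genes <- function(gene_table, top_frac = 0.2) {
  scored <- gene_table[!is.na(gene_table$score), ]
  k <- floor(top_frac * nrow(scored))
  if (k < 1L) return(character(0))
  scored <- scored[order(-scored$score, scored$gene_id), ]
  scored$gene_id[seq_len(k)]
}

#' Species-specific and conserved well-synchronised genes
#'
#' Over a homolog map restricted to groups present in every species,
#' each species contributes its top `top_frac` genes by
#' RegulatoryScore. A homolog group is *species-specific* when it
#' appears in exactly one species' top set (a group in two or more top
#' sets is excluded), and *conserved* when it appears in all of them.
#'
#' @param tables named list of per-species gene tables from
#'   [build_gene_table()].
#' @param homolog_map data.frame with one gene-id column per species
#'   (column names matching `names(tables)`).
#' @param top_frac fraction of ranked genes kept per species.
#' @return list with `specific` (named list of per-species data.frames
#'   of homolog rows) and `conserved` (data.frame of homolog rows).
#' @export
species_specific_genes <- function(tables, homolog_map, top_frac = 0.2) {
  species <- names(tables)
  if (length(species) < 2L) stop("need at least 2 species")
  if (!all(species %in% names(homolog_map))) {
    stop("homolog map lacks columns for: ",
         paste(setdiff(species, names(homolog_map)), collapse = ", "))
  }
  hm <- homolog_map[species]
  # keep homolog groups whose member is scored in every species
  present <- rep(TRUE, nrow(hm))
  for (sp in species) {
    scored <- tables[[sp]]$gene_id[!is.na(tables[[sp]]$score)]
    present <- present & hm[[sp]] %in% scored
  }
  hm <- hm[present, , drop = FALSE]
  if (nrow(hm) == 0L) stop("no homolog group is scored in all species")
  in_top <- sapply(species, function(sp) {
    hm[[sp]] %in% top_score_genes(tables[[sp]], top_frac)
  })
  if (is.null(dim(in_top))) in_top <- matrix(in_top, nrow = 1)
  counts <- rowSums(in_top)
  specific <- lapply(stats::setNames(species, species), function(sp) {
    hm[counts == 1L & in_top[, sp], , drop = FALSE]
  })
  list(specific = specific,
       conserved = hm[counts == length(species), , drop = FALSE])
}

#' Cluster species by RegulatoryScore profiles
#'
#' Distance between two species is `1 - Spearman correlation` of their
#' RegulatoryScore vectors over shared genes (average ranks for ties);
#' species are agglomerated by complete-linkage `hclust`.
#'
#' @param score_matrix numeric matrix, genes x species (>= 10 genes,
#'   >= 3 species); rows with any `NA` are dropped.
#' @return an `hclust` object.
#' @export
cluster_species <- function(score_matrix) {
  score_matrix <- score_matrix[stats::complete.cases(score_matrix), ,
                               drop = FALSE]
  if (ncol(score_matrix) < 3L) stop("need at least 3 species")
  if (nrow(score_matrix) < 10L) stop("need at least 10 shared genes")
  sds <- apply(score_matrix, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant RegulatoryScore vector for species: ",
         paste(colnames(score_matrix)[sds == 0], collapse = ", "))
  }
  rho <- stats::cor(score_matrix, method = "spearman")
  stats::hclust(stats::as.dist(1 - rho), method = "complete")
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of drawing at least the observed overlap between a hit
#' set and a gene set when `|hit_set|` genes are drawn without
#' replacement from the universe.
#'
#' @param hit_set,gene_set character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return p-value `P(X >= |hit_set intersect gene_set|)`.
#' @export
hypergeom_enrich <- function(hit_set, gene_set, universe) {
  if (length(universe) == 0L) stop("empty universe")
  hit_set <- unique(hit_set)
  gene_set <- unique(gene_set)
  if (!all(hit_set %in% universe) || !all(gene_set %in% universe)) {
    stop("hit_set and gene_set must be subsets of the universe")
  }
  q <- length(intersect(hit_set, gene_set))
  stats::phyper(q - 1, m = length(gene_set),
                n = length(universe) - length(gene_set),
                k = length(hit_set), lower.tail = FALSE)
}
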