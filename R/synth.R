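#' Configuration of the synthetic TFCR world
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: TFBSs arrive in Gaussian-jittered clusters that are
#' preferentially placed inside gene promoters, plus a uniform
#' background; cluster sets evolve across developmental stages by
#' random loss and gain with a large gain burst at a ZGA-like stage;
#' and per-stage expression is rank-coupled (Gaussian copula) to the
#' total TFBS-cluster size in each gene's promoter.
#'
#' Defaults describe a small but realistic world: a 4 Mb genome, 300
#' genes with disjoint 4 kb promoters, 300 clusters of geometric size
#' (mean 5) with 80 bp jitter so one cluster maps to one density peak
#' at the caller's 300 bp bandwidth, a 30% gain/loss turnover per stage
#' and a 75% gain burst at the ZGA stage, matching the 70-80% gained
#' fraction reported for zygotic genome activation.
#'
#' @param seed integer seed; every draw in the generator derives from it.
#' @param n_chroms,chrom_length genome shape (all chromosomes equal).
#' @param n_genes number of genes, evenly spaced along the genome.
#' @param n_clusters TFBS clusters at the first stage.
#' @param promoter_cluster_prob probability a cluster anchors inside a
#'   (randomly chosen) promoter rather than uniformly in the genome.
#' @param cluster_size_dist `list(type = "geometric", p = ...)` (sizes
#'   `1 + rgeom(p)`) or `list(type = "fixed", k = ...)`.
#' @param cluster_jitter_sd SD (bp) of hit centers around the cluster
#'   anchor; 80 bp keeps a cluster inside one KDE peak at h = 300.
#' @param background_rate uniform background hits per Mb per stage.
#' @param motif_width width (bp) of each synthetic binding site.
#' @param n_stages number of developmental stages.
#' @param gain_rate,loss_rate per-stage fraction of clusters gained /
#'   lost between consecutive stages.
#' @param zga_stage_index stage (2..n_stages) at which the gain burst
#'   happens, or `NA` for no burst.
#' @param zga_gain_rate gained-cluster fraction at the ZGA stage.
#' @param expr_coupling_rho target Spearman correlation between a
#'   gene's promoter cluster size and its expression.
#' @param distance_effect_weight strength of the TFCR-promoter-distance
#'   effect wired into expression, for ML-recovery experiments.
#' @param same_family_clusters if `TRUE`, all hits of a cluster share
#'   one TF family (exercises family merging); default assigns the 20
#'   families round-robin so within-cluster families are distinct.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 2L,
                         chrom_length = 2e6,
                         n_genes = 300L,
                         n_clusters = 300L,
                         promoter_cluster_prob = 0.7,
                         cluster_size_dist = list(type = "geometric", p = 0.2),
                         cluster_jitter_sd = 80,
                         background_rate = 5,
                         motif_width = 10L,
                         n_stages = 4L,
                         gain_rate = 0.3,
                         loss_rate = 0.3,
                         zga_stage_index = 2L,
                         zga_gain_rate = 0.75,
                         expr_coupling_rho = 0.6,
                         distance_effect_weight = 0,
                         same_family_clusters = FALSE) {
  cfg <- as.list(environment())
  probs <- c(cfg$promoter_cluster_prob, cfg$gain_rate, cfg$loss_rate,
             cfg$zga_gain_rate, cfg$expr_coupling_rho)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$chrom_length <= 0 || cfg$n_chroms < 1) stop("invalid genome shape")
  if (!cfg$cluster_size_dist$type %in% c("geometric", "fixed")) {
    stop("cluster_size_dist$type must be 'geometric' or 'fixed'")
  }
  if (!is.na(cfg$zga_stage_index) &&
      (cfg$zga_stage_index < 2L || cfg$zga_stage_index > cfg$n_stages)) {
    stop("zga_stage_index out of range (needs a preceding stage)")
  }
  if (cfg$n_genes * 4000 > cfg$n_chroms * cfg$chrom_length) {
    stop("n_genes x 4 kb promoters exceed the genome size")
  }
  structure(cfg, class = "synth_config")
}

SYNTH_FAMILIES <- sprintf("TF%02d", 1:20)

synth_assembly <- function(cfg) {
  genome_assembly(
    sprintf("synth_seed%d", as.integer(cfg$seed)),
    stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                    sprintf("chr%d", seq_len(cfg$n_chroms)))
  )
}

# Evenly spaced genes with jittered TSSs and disjoint promoters.
synth_genes <- function(cfg, assembly) {
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  rows <- list()
  g <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    spacing <- floor(cfg$chrom_length / n)
    anchor <- floor(spacing / 2) + spacing * (seq_len(n) - 1L)
    jit <- round(stats::runif(n, -0.05, 0.05) * spacing)
    tss <- pmin(pmax(anchor + jit, 2001), cfg$chrom_length - 2000)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- round(stats::runif(n, 1000, 3000))
    start <- ifelse(strand == "+", tss, pmax(tss - len + 1, 1))
    end <- ifelse(strand == "+", pmin(tss + len - 1, cfg$chrom_length), tss)
    rows[[ci]] <- data.frame(
      gene_id = sprintf("G%04d", g + seq_len(n)),
      chrom = sprintf("chr%d", ci),
      start = start, end = end, strand = strand
    )
    g <- g + n
  }
  df <- do.call(rbind, rows)
  genes <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, gene_id = df$gene_id
  )
  build_gene_annotation(genes, assembly)
}

draw_cluster_sizes <- function(cfg, n) {
  d <- cfg$cluster_size_dist
  if (d$type == "fixed") rep(as.integer(d$k), n)
  else 1L + stats::rgeom(n, d$p)
}

# Draw n new clusters: data.frame(cluster_id, chrom, anchor, size,
# in_promoter, gene_id).
draw_clusters <- function(cfg, assembly, genes, n, id_offset = 0L) {
  if (n == 0L) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      anchor = numeric(0), size = integer(0),
                      in_promoter = logical(0), gene_id = character(0)))
  }
  in_prom <- stats::runif(n) < cfg$promoter_cluster_prob
  chrom <- character(n)
  anchor <- numeric(n)
  gene_id <- rep(NA_character_, n)
  n_prom <- sum(in_prom)
  if (n_prom > 0L) {
    gi <- sample.int(length(genes), n_prom, replace = TRUE)
    gene_id[in_prom] <- genes$gene_id[gi]
    chrom[in_prom] <- as.character(GenomicRanges::seqnames(genes))[gi]
    # anchor near the TSS so the whole jittered cluster stays inside
    # the 4 kb promoter
    anchor[in_prom] <- genes$tss[gi] + round(stats::runif(n_prom, -500, 500))
  }
  n_bg <- n - n_prom
  if (n_bg > 0L) {
    ci <- sample.int(cfg$n_chroms, n_bg, replace = TRUE)
    chrom[!in_prom] <- sprintf("chr%d", ci)
    anchor[!in_prom] <- round(stats::runif(n_bg, 2000, cfg$chrom_length - 2000))
  }
  data.frame(cluster_id = id_offset + seq_len(n), chrom = chrom,
             anchor = anchor, size = draw_cluster_sizes(cfg, n),
             in_promoter = in_prom, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

# Draw the hit table of a cluster set once, at cluster creation, so a
# cluster that persists across stages keeps the same binding sites
# (gain/loss dynamics then reflect cluster turnover, not re-jitter).
make_cluster_hit_table <- function(cfg, assembly, clusters) {
  if (nrow(clusters) == 0L) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      center = numeric(0), family = character(0),
                      score = numeric(0), p_value = numeric(0)))
  }
  half <- floor(cfg$motif_width / 2)
  sizes <- clusters$size
  idx <- rep(seq_len(nrow(clusters)), sizes)
  centers <- clusters$anchor[idx] +
    round(stats::rnorm(length(idx), 0, cfg$cluster_jitter_sd))
  centers <- pmin(pmax(centers, half + 1),
                  assembly$chrom_sizes[clusters$chrom[idx]] - half)
  fam <- if (cfg$same_family_clusters) {
    SYNTH_FAMILIES[1L + (clusters$cluster_id[idx] %% 20L)]
  } else {
    # round-robin within each cluster: families distinct for size <= 20
    SYNTH_FAMILIES[1L + ((sequence(sizes) - 1L) %% 20L)]
  }
  data.frame(
    cluster_id = clusters$cluster_id[idx],
    chrom = clusters$chrom[idx],
    center = centers,
    family = fam,
    score = round(stats::runif(length(idx), 5, 20), 3),
    p_value = 10^stats::runif(length(idx), -9, -5),
    stringsAsFactors = FALSE
  )
}

# Stage hit set: persistent hits of the alive clusters plus a fresh
# draw of uniform background hits (transient noise).
stage_hits_granges <- function(cfg, assembly, hit_table, alive_ids) {
  half <- floor(cfg$motif_width / 2)
  tbl <- hit_table[hit_table$cluster_id %in% alive_ids, , drop = FALSE]
  n_bg <- stats::rpois(1, cfg$background_rate * assembly$genome_size / 1e6)
  if (n_bg > 0L) {
    ci <- sample.int(cfg$n_chroms, n_bg, replace = TRUE)
    bg <- data.frame(
      cluster_id = NA_integer_,
      chrom = sprintf("chr%d", ci),
      center = round(stats::runif(n_bg, half + 1, cfg$chrom_length - half)),
      family = sample(SYNTH_FAMILIES, n_bg, replace = TRUE),
      score = round(stats::runif(n_bg, 5, 20), 3),
      p_value = 10^stats::runif(n_bg, -9, -5),
      stringsAsFactors = FALSE
    )
    tbl <- rbind(tbl, bg)
  }
  hits <- GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$center - half,
                              width = cfg$motif_width),
    strand = "*",
    motif_id = sprintf("%s_m", tbl$family),
    tf_family = tbl$family,
    score = tbl$score,
    p_value = tbl$p_value,
    cluster_id = tbl$cluster_id
  )
  hits <- GenomicRanges::sort(hits, ignore.strand = TRUE)
  hits$center <- hit_centers(hits)
  hits
}

# Evolve a cluster table one stage: drop a loss_rate fraction, add new
# clusters so the gained fraction of the resulting set is ~gain.
evolve_clusters <- function(cfg, assembly, genes, clusters, gain,
                            next_id) {
  n_prev <- nrow(clusters)
  n_lost <- round(cfg$loss_rate * n_prev)
  kept <- if (n_lost > 0L) {
    clusters[-sample.int(n_prev, n_lost), , drop = FALSE]
  } else clusters
  n_new <- if (gain >= 1) stop("gain rate must be < 1") else {
    round(gain / (1 - gain) * nrow(kept))
  }
  new <- draw_clusters(cfg, assembly, genes, n_new, id_offset = next_id)
  list(clusters = rbind(kept, new), next_id = next_id + n_new)
}

# Gene-level expression rank-coupled to promoter cluster size via a
# Gaussian copula. The latent correlation is 2*sin(pi*rho/6) so the
# realised Spearman correlation targets rho; tied cluster sizes share a
# latent value, making the coupling exact at rho = 1.
couple_expression <- function(sizes, rho, distance_term = NULL,
                              distance_weight = 0) {
  n <- length(sizes)
  r <- rank(sizes, ties.method = "average")
  z_size <- stats::qnorm(r / (n + 1))
  rho_lat <- if (rho >= 1) 1 else 2 * sin(pi * rho / 6)
  z <- rho_lat * z_size + sqrt(max(0, 1 - rho_lat^2)) * stats::rnorm(n)
  if (!is.null(distance_term) && distance_weight > 0) {
    zd <- -scale(distance_term)[, 1L]
    z <- z + distance_weight * ifelse(is.finite(zd), zd, 0)
  }
  exp(z) # lognormal, strictly positive
}

# Total cluster size anchored in each gene's promoter.
promoter_cluster_sizes <- function(genes, clusters) {
  sizes <- stats::setNames(rep(0L, length(genes)), genes$gene_id)
  cl <- clusters[clusters$in_promoter & !is.na(clusters$gene_id), ,
                 drop = FALSE]
  if (nrow(cl)) {
    agg <- tapply(cl$size, cl$gene_id, sum)
    sizes[names(agg)] <- as.integer(agg)
  }
  sizes
}

#' Generate a complete synthetic dataset
#'
#' Produces a genome assembly, gene models, per-stage motif-hit sets
#' with cluster ground truth, per-stage expression coupled to promoter
#' cluster size, and (optionally) a random genome sequence. Everything
#' is reproducible from `config$seed`.
#'
#' @param config a [synth_config()].
#' @param make_sequence also generate a uniform-random genome
#'   `DNAStringSet` (skip for large genomes).
#' @return list with `assembly`, `genes`, `stages` (each stage a list
#'   of `hits`, `clusters`, `expression`), `sequence` (or `NULL`), and
#'   the `config`.
#' @export
make_dataset <- function(config, make_sequence = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    assembly <- synth_assembly(config)
    genes <- synth_genes(config, assembly)
    stages <- vector("list", config$n_stages)
    clusters <- draw_clusters(config, assembly, genes, config$n_clusters)
    hit_table <- make_cluster_hit_table(config, assembly, clusters)
    next_id <- config$n_clusters + 1L
    for (t in seq_len(config$n_stages)) {
      if (t > 1L) {
        gain <- if (!is.na(config$zga_stage_index) &&
                    t == config$zga_stage_index) {
          config$zga_gain_rate
        } else config$gain_rate
        ev <- evolve_clusters(config, assembly, genes, clusters, gain,
                              next_id)
        new_clusters <- ev$clusters[!ev$clusters$cluster_id %in%
                                      clusters$cluster_id, , drop = FALSE]
        hit_table <- rbind(hit_table,
                           make_cluster_hit_table(config, assembly,
                                                  new_clusters))
        clusters <- ev$clusters
        next_id <- ev$next_id
      }
      hits <- stage_hits_granges(config, assembly, hit_table,
                                 clusters$cluster_id)
      sizes <- promoter_cluster_sizes(genes, clusters)
      expr <- couple_expression(sizes, config$expr_coupling_rho)
      stages[[t]] <- list(
        stage_id = sprintf("stage%02d", t),
        clusters = clusters,
        hits = hits,
        expression = list(stage_id = sprintf("stage%02d", t),
                          values = stats::setNames(expr, genes$gene_id))
      )
    }
    sequence <- if (make_sequence) random_genome(assembly) else NULL
    list(assembly = assembly, genes = genes, stages = stages,
         sequence = sequence, config = config)
  })
}

#' Per-stage hit sets with a ZGA-like gain burst
#'
#' Convenience wrapper around [make_dataset()] returning just the
#' per-stage hit `GRanges`, for dynamics experiments.
#'
#' @param config a [synth_config()] with `zga_stage_index` set.
#' @return named list of `GRanges`, one per stage.
#' @export
make_zga_series <- function(config) {
  if (is.na(config$zga_stage_index)) {
    stop("zga_stage_index must be set for make_zga_series")
  }
  ds <- make_dataset(config, make_sequence = FALSE)
  stats::setNames(lapply(ds$stages, `[[`, "hits"),
                  vapply(ds$stages, `[[`, character(1), "stage_id"))
}

# Uniform-random genome sequence for an assembly.
random_genome <- function(assembly) {
  seqs <- lapply(assembly$chrom_sizes, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits `chrom.sizes`, gene models TSV, per-stage motif-hit BED6+2 and
#' expression TSVs, and a genome FASTA when sequence is present. Same
#' config and seed give byte-identical files.
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(chrom_sizes = file.path(dir, "genome.chrom.sizes"),
             genes = file.path(dir, "genes.tsv"))
  write_chrom_sizes(dataset$assembly, paths[["chrom_sizes"]])
  write_gene_models(dataset$genes, paths[["genes"]])
  for (st in dataset$stages) {
    hp <- file.path(dir, sprintf("hits_%s.bed", st$stage_id))
    ep <- file.path(dir, sprintf("expression_%s.tsv", st$stage_id))
    write_motif_hits_bed(st$hits, hp)
    write_expression(st$expression, ep)
    paths[[paste0("hits_", st$stage_id)]] <- hp
    paths[[paste0("expression_", st$stage_id)]] <- ep
  }
  if (!is.null(dataset$sequence)) {
    fp <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(dataset$sequence, fp)
    paths[["fasta"]] <- fp
  }
  paths
}

#' Write motif hits as BED6+2 (the format [read_motif_hits()] reads)
#' @param hits motif-hit `GRanges`.
#' @param path output path.
#' @export
write_motif_hits_bed <- function(hits, path) {
  s <- as.character(GenomicRanges::strand(hits))
  utils::write.table(
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(hits)),
      start = GenomicRanges::start(hits) - 1L,
      end = GenomicRanges::end(hits),
      name = hits$motif_id,
      score = hits$score,
      strand = ifelse(s == "*", ".", s),
      tf_family = hits$tf_family,
      p_value = sprintf("%.6g", hits$p_value)
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
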