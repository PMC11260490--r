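suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Quick GRanges builder, 1-based closed coordinates.
gr <- function(chrom, start, end, strand = "*", ...) {
  GRanges(chrom, IRanges(start, end), strand = strand, ...)
}

# Motif-hit GRanges with the columns the caller expects. Families are
# distinct per hit unless given.
mk_hits <- function(centers, chrom = "chr1", width = 10L,
                    tf_family = NULL, motif_id = NULL) {
  n <- length(centers)
  half <- floor(width / 2)
  h <- gr(chrom, centers - half, centers - half + width - 1L,
          motif_id = motif_id %||% sprintf("M%03d", seq_len(n)),
          tf_family = tf_family %||% sprintf("F%03d", seq_len(n)),
          score = rep(10, n), p_value = rep(1e-6, n))
  h$center <- tfcrkit:::hit_centers(h)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TFCR-like GRanges with given complexities (strengths default to the
# complexity so ordering is stable).
mk_tfcrs <- function(starts, widths = 200L, complexity = NULL,
                     chrom = "chr1", strength = NULL) {
  n <- length(starts)
  complexity <- complexity %||% rep(1L, n)
  g <- gr(chrom, starts, starts + widths - 1L)
  g$tfcr_id <- sprintf("T%04d", seq_len(n))
  g$summit <- as.integer(starts + floor(widths / 2))
  g$complexity <- as.integer(complexity)
  g$strength <- strength %||% as.numeric(complexity)
  g
}

# Evenly spaced annotated genes on one chromosome.
mk_genes <- function(tss, chrom = "chr1", strand = "+",
                     chrom_len = NULL, len = 1000L) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss, pmax(tss - len + 1L, 1L))
  end <- ifelse(strand == "+", tss + len - 1L, tss)
  g <- gr(chrom, start, end, strand = strand,
          gene_id = sprintf("G%04d", seq_len(n)))
  asm <- if (!is.null(chrom_len)) {
    genome_assembly("toy", stats::setNames(chrom_len, chrom))
  } else NULL
  tfcrkit:::build_gene_annotation(g, asm)
}

# ---- independent oracles -------------------------------------------

# Brute-force untruncated KDE: full double sum, no islands, no cutoff.
bf_density <- function(centers, pos, h) {
  vapply(pos, function(x) sum(exp(-(x - centers)^2 / (2 * h^2))),
         numeric(1))
}

# Independent peak finder: strict maxima with plateaus collapsed to
# the floor of their midpoint (plain loop over runs).
bf_peaks <- function(dens) {
  n <- length(dens)
  if (n == 1L) return(1L)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && dens[j + 1L] == dens[i]) j <- j + 1L
    left_ok <- i == 1L || dens[i - 1L] < dens[i]
    right_ok <- j == n || dens[j + 1L] < dens[i]
    if (left_ok && right_ok) peaks <- c(peaks, as.integer(floor((i + j) / 2)))
    i <- j + 1L
  }
  peaks
}

# Cover-weighted conditional expectation of a single tree (0-based
# node/feature arrays as stored in the fitted model).
bf_expvalue <- function(tree, x, S, node = 0L) {
  f <- tree$feature[node + 1L]
  if (f < 0L) return(tree$value[node + 1L])
  if ((f + 1L) %in% S) {
    nxt <- if (x[f + 1L] <= tree$threshold[node + 1L]) {
      tree$left[node + 1L]
    } else tree$right[node + 1L]
    return(bf_expvalue(tree, x, S, nxt))
  }
  wl <- tree$cover[tree$left[node + 1L] + 1L]
  wr <- tree$cover[tree$right[node + 1L] + 1L]
  (wl * bf_expvalue(tree, x, S, tree$left[node + 1L]) +
   wr * bf_expvalue(tree, x, S, tree$right[node + 1L])) / (wl + wr)
}

# Exponential-time exact Shapley values of one tree for sample x.
bf_shapley <- function(tree, x) {
  feats <- sort(unique(tree$feature[tree$feature >= 0L])) + 1L
  phi <- numeric(length(x))
  M <- length(feats)
  for (i in feats) {
    others <- setdiff(feats, i)
    tot <- 0
    for (k in 0:length(others)) {
      combs <- if (k == 0L) list(integer(0)) else {
        utils::combn(others, k, simplify = FALSE)
      }
      w <- factorial(k) * factorial(M - k - 1) / factorial(M)
      for (S in combs) {
        tot <- tot + w * (bf_expvalue(tree, x, c(S, i)) -
                            bf_expvalue(tree, x, S))
      }
    }
    phi[i] <- tot
  }
  phi
}

# Random DNA strings.
rand_seqs <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}
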