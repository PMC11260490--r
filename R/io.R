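#' @useDynLib tfcrkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats setNames
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomised operations in the package funnel through this helper so a
# seed argument never leaks state into (or out of) the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a label.
# Stable across sessions (digest2int of the label string), kept in
# [1, 2^31 - 2] so it is always a valid R integer seed.
child_seed <- function(seed, label) {
  h <- digest::digest2int(paste0(label, ":", as.integer(seed)))
  (abs(as.numeric(h)) %% 2147483646) + 1
}

fimo_columns <- c("motif_id", "motif_alt_id", "sequence_name", "start",
                  "stop", "strand", "score", "p.value", "q.value",
                  "matched_sequence")

#' Read motif occurrences (TFBSs) from FIMO TSV or BED
#'
#' Motif hits are the atoms of TFCR calling: each is a genomic interval
#' with a motif identity, a transcription-factor family, a match score and
#' a scan p-value. Hits failing the p-value threshold are dropped on read,
#' mirroring a motif scan restricted to open chromatin at a fixed
#' stringency (1e-5 by default).
#'
#' FIMO input is the standard 10-column TSV (`motif_id`, `motif_alt_id`,
#' `sequence_name`, `start`, `stop`, `strand`, `score`, `p-value`,
#' `q-value`, `matched_sequence`) with 1-based inclusive coordinates; the
#' TF family is taken from `motif_alt_id` when present, else from
#' `motif_id`. BED input is BED6+2 (0-based half-open): `chrom`, `start`,
#' `end`, `name` = motif id, `score`, `strand`, then `tf_family` and
#' `p_value` columns.
#'
#' @param path input file.
#' @param format `"fimo_tsv"` or `"bed"`.
#' @param p_threshold keep hits with `p_value <= p_threshold`.
#' @return a [GenomicRanges::GRanges] (1-based closed, the Bioconductor
#'   convention) with metadata columns `motif_id`, `tf_family`, `score`,
#'   `p_value` and `center` (midpoint used for density estimation).
#' @export
read_motif_hits <- function(path, format = c("fimo_tsv", "bed"),
                            p_threshold = 1e-5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be in (0, 1]")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (format == "fimo_tsv") {
    if (length(lines) == 0L) stop("empty FIMO file: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    has_header <- any(header %in% c("motif_id", "sequence_name", "p-value"))
    body <- if (has_header) lines[-1L] else lines
    body <- body[nzchar(trimws(body))]
    rows <- strsplit(body, "\t", fixed = TRUE)
    offset <- if (has_header) 1L else 0L
    parsed <- lapply(seq_along(rows), function(i) {
      f <- rows[[i]]
      line_no <- i + offset
      if (length(f) < 8L) {
        stop(sprintf("malformed FIMO row at line %d of %s: expected >= 8 fields, got %d",
                     line_no, path, length(f)))
      }
      start <- suppressWarnings(as.numeric(f[[4L]]))
      stop_ <- suppressWarnings(as.numeric(f[[5L]]))
      pval <- suppressWarnings(as.numeric(f[[8L]]))
      score <- suppressWarnings(as.numeric(f[[7L]]))
      if (anyNA(c(start, stop_, pval)) || start < 1 || stop_ < start) {
        stop(sprintf("malformed FIMO row at line %d of %s", line_no, path))
      }
      list(motif_id = f[[1L]],
           tf_family = if (nzchar(f[[2L]])) f[[2L]] else f[[1L]],
           chrom = f[[3L]], start = start, end = stop_,
           strand = f[[6L]], score = score, p_value = pval)
    })
    df <- do.call(rbind.data.frame, c(parsed, stringsAsFactors = FALSE))
  } else {
    body <- lines[nzchar(trimws(lines))]
    if (length(body) == 0L) stop("empty BED file: ", path)
    rows <- strsplit(body, "\t", fixed = TRUE)
    parsed <- lapply(seq_along(rows), function(i) {
      f <- rows[[i]]
      if (length(f) < 8L) {
        stop(sprintf("malformed BED motif row at line %d of %s: expected 8 fields, got %d",
                     i, path, length(f)))
      }
      start0 <- suppressWarnings(as.numeric(f[[2L]]))
      end0 <- suppressWarnings(as.numeric(f[[3L]]))
      pval <- suppressWarnings(as.numeric(f[[8L]]))
      if (anyNA(c(start0, end0, pval)) || start0 < 0 || end0 <= start0) {
        stop(sprintf("malformed BED motif row at line %d of %s", i, path))
      }
      list(motif_id = f[[4L]], tf_family = f[[7L]], chrom = f[[1L]],
           start = start0 + 1, end = end0, strand = f[[6L]],
           score = suppressWarnings(as.numeric(f[[5L]])), p_value = pval)
    })
    df <- do.call(rbind.data.frame, c(parsed, stringsAsFactors = FALSE))
  }
  df <- df[df$p_value <= p_threshold, , drop = FALSE]
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand,
    motif_id = df$motif_id,
    tf_family = df$tf_family,
    score = df$score,
    p_value = df$p_value
  )
  gr$center <- hit_centers(gr)
  gr
}

# Midpoint of each interval: floor of the 0-based midpoint, reported on
# the 1-based grid. This is the point each Gaussian kernel is centred on.
hit_centers <- function(gr) {
  as.integer(floor((GenomicRanges::start(gr) - 1 +
                    GenomicRanges::end(gr)) / 2) + 1)
}

#' Keep motif hits overlapping open-chromatin peaks
#'
#' Restricts a hit set to accessible chromatin: a hit is kept iff it
#' shares at least 1 bp with some peak.
#'
#' @param hits `GRanges` of motif hits.
#' @param peaks `GRanges` of peak intervals.
#' @param assembly optional [genome_assembly()]; when given, both inputs
#'   are checked against its chromosome names.
#' @return the retained subset of `hits`, in input order.
#' @export
intersect_hits_with_peaks <- function(hits, peaks, assembly = NULL) {
  if (!is.null(assembly)) {
    check_chroms(hits, assembly, "hit")
    check_chroms(peaks, assembly, "peak")
  }
  ov <- GenomicRanges::findOverlaps(hits, peaks, minoverlap = 1L,
                                    ignore.strand = TRUE)
  hits[sort(unique(S4Vectors::queryHits(ov)))]
}

#' Chromosome- and length-preserving interval shuffle
#'
#' Builds a positional null by relocating each interval uniformly at
#' random on its own chromosome, preserving its length (the
#' `bedtools shuffle -chrom` behaviour). Overlaps among shuffled
#' intervals are allowed unless `no_self_overlap` is set.
#'
#' @param items `GRanges` to shuffle.
#' @param assembly [genome_assembly()] supplying chromosome lengths.
#' @param seed integer seed; required for reproducibility.
#' @param no_self_overlap if `TRUE`, rejection-sample so shuffled
#'   intervals do not overlap each other (off by default).
#' @param max_tries rejection-sampling cap per interval.
#' @return `GRanges` of the same length, same seqnames, same widths.
#' @export
shuffle_intervals <- function(items, assembly, seed,
                              no_self_overlap = FALSE, max_tries = 1000L) {
  check_chroms(items, assembly, "interval")
  widths <- GenomicRanges::width(items)
  chroms <- as.character(GenomicRanges::seqnames(items))
  lens <- assembly$chrom_sizes[chroms]
  if (any(widths > lens)) {
    stop("interval longer than its chromosome cannot be shuffled")
  }
  with_seed(seed, {
    starts <- floor(stats::runif(length(items)) * (lens - widths + 1)) + 1
    out <- GenomicRanges::GRanges(
      seqnames = chroms,
      ranges = IRanges::IRanges(start = starts, width = widths),
      strand = GenomicRanges::strand(items)
    )
    if (no_self_overlap && length(out) > 1L) {
      for (i in seq_along(out)) {
        tries <- 0L
        while (tries < max_tries) {
          others <- out[-i]
          if (!any(IRanges::overlapsAny(out[i], others,
                                        ignore.strand = TRUE))) break
          s <- floor(stats::runif(1) * (lens[i] - widths[i] + 1)) + 1
          GenomicRanges::ranges(out[i]) <-
            IRanges::IRanges(start = s, width = widths[i])
          tries <- tries + 1L
        }
        if (tries == max_tries) {
          stop("could not place non-overlapping shuffle for interval ", i)
        }
      }
    }
    out
  })
}

#' Read gene models from TSV or minimal GTF
#'
#' TSV input has a header with columns `gene_id`, `chrom`, `start`,
#' `end`, `strand` (1-based inclusive). GTF input uses lines whose
#' feature field is `gene`, with `gene_id "..."` in the attributes.
#' The TSS is the interval start on the `+` strand and the interval end
#' on the `-` strand; the promoter is the window from 2 kb upstream to
#' 2 kb downstream of the TSS (4000 bp), clipped to the chromosome when
#' an assembly is supplied.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gtf"`.
#' @param assembly optional [genome_assembly()] used to clip promoters
#'   and validate chromosome names.
#' @param promoter_halfwidth bp on each side of the TSS (default 2000).
#' @return `GRanges` of gene bodies with metadata columns `gene_id`,
#'   `tss`, and a `promoter` `IRanges` column.
#' @export
read_gene_models <- function(path, format = c("tsv", "gtf"),
                             assembly = NULL, promoter_halfwidth = 2000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(df))) {
      stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
    }
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    rows <- strsplit(lines, "\t", fixed = TRUE)
    rows <- Filter(function(f) length(f) >= 9L && f[[3L]] == "gene", rows)
    if (length(rows) == 0L) stop("no gene lines in GTF: ", path)
    gene_ids <- vapply(rows, function(f) {
      m <- regmatches(f[[9L]], regexec('gene_id "([^"]+)"', f[[9L]]))[[1L]]
      if (length(m) < 2L) stop("GTF gene line lacks gene_id attribute")
      m[[2L]]
    }, character(1))
    df <- data.frame(
      gene_id = gene_ids,
      chrom = vapply(rows, `[[`, character(1), 1L),
      start = as.numeric(vapply(rows, `[[`, character(1), 4L)),
      end = as.numeric(vapply(rows, `[[`, character(1), 5L)),
      strand = vapply(rows, `[[`, character(1), 7L),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  genes <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    gene_id = df$gene_id
  )
  build_gene_annotation(genes, assembly, promoter_halfwidth)
}

# Attach tss and promoter columns to a gene-body GRanges.
build_gene_annotation <- function(genes, assembly = NULL,
                                  promoter_halfwidth = 2000L) {
  if (!is.null(assembly)) check_chroms(genes, assembly, "gene")
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  tss <- ifelse(plus, GenomicRanges::start(genes), GenomicRanges::end(genes))
  pstart <- tss - promoter_halfwidth
  pend <- tss + promoter_halfwidth - 1L
  if (!is.null(assembly)) {
    lens <- assembly$chrom_sizes[as.character(GenomicRanges::seqnames(genes))]
    pstart <- pmax(pstart, 1)
    pend <- pmin(pend, lens)
  } else {
    pstart <- pmax(pstart, 1)
  }
  genes$tss <- as.integer(tss)
  genes$promoter <- IRanges::IRanges(start = pstart, end = pend)
  genes
}

# Promoters of an annotated gene set, as a GRanges parallel to `genes`.
promoter_ranges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = genes$promoter,
    strand = "*",
    gene_id = genes$gene_id
  )
}

#' Read a per-stage expression table
#'
#' @param path TSV with header columns `gene_id` and `expression`.
#' @param stage_id optional label; defaults to the file name.
#' @return a list with `stage_id` and `values` (named numeric vector).
#' @export
read_expression <- function(path, stage_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expression") %in% names(df))) {
    stop("expression TSV must have columns gene_id, expression")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  if (any(df$expression < 0)) stop("negative expression values in ", path)
  list(
    stage_id = if (is.null(stage_id)) {
      tools::file_path_sans_ext(basename(path))
    } else stage_id,
    values = stats::setNames(df$expression, df$gene_id)
  )
}

#' Write a per-stage expression table
#' @param expr list as returned by [read_expression()].
#' @param path output TSV path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(
    data.frame(gene_id = names(expr$values), expression = expr$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a homolog map
#'
#' @param path TSV with a header; each column is a species, each row a
#'   homolog group (one gene id per species).
#' @return data.frame, one column per species.
#' @export
read_homolog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("homolog map needs at least two species columns")
  df
}

#' Write TFCRs to BED
#'
#' BED6+4: `chrom start end name score strand complexity summit decile
#' strength`. The BED score is `round(strength * 1000)` as an integer
#' track score; the last column repeats strength at full precision so a
#' write/read round trip is exact. Coordinates follow BED (0-based
#' half-open) on disk.
#'
#' @param tfcrs `GRanges` from [call_tfcrs()].
#' @param path output path.
#' @export
write_tfcrs_bed <- function(tfcrs, path) {
  decile <- if (!is.null(tfcrs$decile_group)) tfcrs$decile_group else
    rep(NA_integer_, length(tfcrs))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tfcrs)),
    start = GenomicRanges::start(tfcrs) - 1L,
    end = GenomicRanges::end(tfcrs),
    name = tfcrs$tfcr_id,
    score = as.integer(round(tfcrs$strength * 1000)),
    strand = ".",
    complexity = tfcrs$complexity,
    summit = tfcrs$summit,
    decile = ifelse(is.na(decile), ".", as.character(decile)),
    strength = sprintf("%.17g", tfcrs$strength)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TFCRs from BED written by [write_tfcrs_bed()]
#' @param path input path.
#' @return `GRanges` with `tfcr_id`, `summit`, `strength`, `complexity`,
#'   `decile_group` metadata columns.
#' @export
read_tfcrs_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 9L) stop("not a TFCR BED6+ file: ", path)
  strength <- if (ncol(df) >= 10L) as.numeric(df[[10L]]) else df[[5L]] / 1000
  GenomicRanges::GRanges(
    seqnames = df[[1L]],
    ranges = IRanges::IRanges(start = df[[2L]] + 1L, end = df[[3L]]),
    strand = "*",
    tfcr_id = as.character(df[[4L]]),
    summit = as.integer(df[[8L]]),
    strength = strength,
    complexity = as.integer(df[[7L]]),
    decile_group = suppressWarnings(as.integer(ifelse(df[[9L]] == ".",
                                                      NA, df[[9L]])))
  )
}

#' Read a plain BED file of intervals (e.g. ATAC-seq peaks)
#' @param path BED3+ file, 0-based half-open.
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns: ", path)
  GenomicRanges::GRanges(
    seqnames = df[[1L]],
    ranges = IRanges::IRanges(start = df[[2L]] + 1L, end = df[[3L]]),
    strand = if (ncol(df) >= 6L) {
      ifelse(df[[6L]] %in% c("+", "-"), df[[6L]], "*")
    } else "*"
  )
}

#' Write a GRanges as BED6
#' @param gr intervals to write.
#' @param path output path.
#' @param names optional name column; default `.`.
#' @export
write_bed <- function(gr, path, names = NULL) {
  s <- as.character(GenomicRanges::strand(gr))
  utils::write.table(
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = if (is.null(names)) "." else names,
      score = 0L,
      strand = ifelse(s == "*", ".", s)
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write gene models as TSV
#' @param genes annotated gene `GRanges`.
#' @param path output TSV path.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(
    data.frame(
      gene_id = genes$gene_id,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes),
      end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes))
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
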