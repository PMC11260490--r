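#' Genome assembly: chromosome sizes and genome-size multiple
#'
#' A `genome_assembly` is a lightweight container for a named set of
#' chromosome lengths. Its `size_multiple_n` is the ratio of the total
#' genome size to a reference genome size (the budding-yeast sacCer3
#' assembly by default), the `N` used to scale top/bottom TFCR selection
#' across species.
#'
#' @param name assembly name, e.g. `"synth1"` or `"sacCer3"`.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp;
#'   all lengths must be positive and names unique.
#' @param reference_size genome size (bp) of the reference used as the
#'   denominator of the size multiple. Defaults to [YEAST_GENOME_SIZE].
#' @return an object of class `genome_assembly` with fields `name`,
#'   `chrom_sizes`, `genome_size` and `size_multiple_n`.
#' @examples
#' asm <- genome_assembly("toy", c(chr1 = 1e6, chr2 = 5e5))
#' asm$genome_size
#' @export
genome_assembly <- function(name, chrom_sizes,
                            reference_size = YEAST_GENOME_SIZE) {
  if (length(chrom_sizes) == 0L) stop("chrom_sizes must be non-empty")
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
      any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector")
  }
  if (anyDuplicated(names(chrom_sizes))) {
    stop("duplicate chromosome names in chrom_sizes")
  }
  chrom_sizes <- stats::setNames(as.numeric(chrom_sizes),
                                 names(chrom_sizes))
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  if (reference_size <= 0) stop("reference_size must be positive")
  genome_size <- sum(chrom_sizes)
  structure(
    list(
      name = as.character(name),
      chrom_sizes = chrom_sizes,
      genome_size = genome_size,
      size_multiple_n = genome_size / reference_size
    ),
    class = "genome_assembly"
  )
}

#' Total length of the sacCer3 yeast assembly in bp
#'
#' Used as the default reference genome size when computing the
#' genome-size multiple `N` of an assembly.
#' @export
YEAST_GENOME_SIZE <- 12157105

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf(
    "genome_assembly '%s': %d chromosome(s), %.0f bp (N = %.3g vs reference)\n",
    x$name, length(x$chrom_sizes), x$genome_size, x$size_multiple_n
  ))
  invisible(x)
}

#' Read a two-column chrom.sizes table into a genome assembly
#'
#' @param path tab-separated file with columns chrom name and length,
#'   no header (the UCSC `chrom.sizes` layout).
#' @inheritParams genome_assembly
#' @param name assembly name; defaults to the file name without extension.
#' @return a [genome_assembly()].
#' @export
read_chrom_sizes <- function(path, name = NULL,
                             reference_size = YEAST_GENOME_SIZE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0L) stop("empty chrom.sizes file: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  genome_assembly(name, stats::setNames(df$size, df$chrom),
                  reference_size = reference_size)
}

#' Write a genome assembly as a chrom.sizes file
#' @param assembly a [genome_assembly()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  utils::write.table(
    data.frame(chrom = names(assembly$chrom_sizes),
               size = format(assembly$chrom_sizes, scientific = FALSE,
                             trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Seqinfo for GRanges construction from an assembly.
assembly_seqinfo <- function(assembly) {
  GenomeInfoDb::Seqinfo(
    seqnames = names(assembly$chrom_sizes),
    seqlengths = as.integer(assembly$chrom_sizes),
    genome = assembly$name
  )
}

# Validate that every chromosome in `gr` exists in the assembly.
check_chroms <- function(gr, assembly, what = "interval") {
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                 names(assembly$chrom_sizes))
  if (length(bad)) {
    stop(sprintf("%s chromosome(s) absent from assembly '%s': %s",
                 what, assembly$name, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}
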