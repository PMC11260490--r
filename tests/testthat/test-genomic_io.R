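test_that("FIMO reading filters on p-value and converts coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("motif_id", "motif_alt_id", "sequence_name", "start", "stop",
            "strand", "score", "p-value", "q-value", "matched_sequence"),
          collapse = "\t"),
    "M1\tFAM1\tchr1\t101\t110\t+\t12.3\t1e-6\t0.01\tACGTACGTAC",
    "M2\tFAM2\tchr1\t201\t210\t-\t8.1\t2e-5\t0.2\tACGTACGTAC"
  ), f)
  hits <- read_motif_hits(f, "fimo_tsv", p_threshold = 1e-5)
  expect_length(hits, 1L)                    # 2e-5 fails the filter
  expect_equal(start(hits), 101)
  expect_equal(end(hits), 110)
  expect_equal(hits$tf_family, "FAM1")
  # midpoint: floor of the 0-based midpoint, on the 1-based grid
  expect_equal(hits$center, floor((100 + 110) / 2) + 1)
  # looser threshold keeps both
  expect_length(read_motif_hits(f, "fimo_tsv", p_threshold = 1e-4), 2L)
})

test_that("malformed FIMO rows raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "M1\tFAM1\tchr1\t101\t110\t+\t12.3\t1e-6\t0.01\tAC",
    "M2\tFAM2\tchr1\tBAD",
    "M3\tFAM3\tchr1\t301\t310\t+\t9\t1e-6\t0.01\tAC"
  ), f)
  expect_error(read_motif_hits(f, "fimo_tsv"), "line 2")
})

test_that("BED motif hits convert from 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t110\tM1\t10\t+\tFAM1\t1e-6", f)
  hits <- read_motif_hits(f, "bed")
  expect_equal(start(hits), 101)
  expect_equal(end(hits), 110)
  expect_equal(width(hits), 10)
})

test_that("hit/peak intersection follows the 1 bp overlap rule", {
  # [100,110) vs [105,200) in 0-based => kept; adjacency is no overlap
  h <- mk_hits(c(105))                        # spans 101..110 (1-based)
  expect_length(intersect_hits_with_peaks(h, gr("chr1", 106, 200)), 1L)
  expect_length(intersect_hits_with_peaks(h, gr("chr1", 111, 200)), 0L)
})

test_that("hit/peak intersection matches a brute-force pairwise check", {
  withr::local_seed(7)
  for (rep in 1:5) {
    hits <- mk_hits(sample(1000:9000, 10))
    peaks <- gr("chr1", s <- sort(sample(1000:9000, 2)), s + 400)
    kept <- intersect_hits_with_peaks(hits, peaks)
    manual <- vapply(seq_along(hits), function(i) {
      any(start(hits)[i] <= end(peaks) & end(hits)[i] >= start(peaks))
    }, logical(1))
    expect_equal(hits$motif_id[manual], kept$motif_id)
  }
})

test_that("intersection rejects chromosomes absent from the assembly", {
  asm <- genome_assembly("toy", c(chr1 = 1e6))
  h <- mk_hits(500, chrom = "chr9")
  expect_error(intersect_hits_with_peaks(h, gr("chr1", 1, 100), asm),
               "chr9")
})

test_that("shuffle preserves chromosome, length and seed determinism", {
  asm <- genome_assembly("toy", c(chr1 = 1e6, chr2 = 5e5))
  items <- gr(c("chr1", "chr2", "chr1"), c(100, 1000, 5000),
              c(599, 1999, 5009))
  s1 <- shuffle_intervals(items, asm, seed = 11)
  s2 <- shuffle_intervals(items, asm, seed = 11)
  s3 <- shuffle_intervals(items, asm, seed = 12)
  expect_identical(width(s1), width(items))
  expect_identical(as.character(seqnames(s1)), as.character(seqnames(items)))
  expect_identical(s1, s2)
  expect_false(identical(start(s1), start(s3)))
  expect_true(all(start(s1) >= 1 & end(s1) <= c(1e6, 5e5, 1e6)))
  # per-chromosome length multiset is preserved on random inputs
  withr::local_seed(3)
  items2 <- gr(sample(c("chr1", "chr2"), 50, TRUE),
               st <- sample(1e4, 50), st + sample(50:500, 50))
  sh <- shuffle_intervals(items2, asm, seed = 4)
  for (ch in c("chr1", "chr2")) {
    expect_equal(sort(width(sh)[as.character(seqnames(sh)) == ch]),
                 sort(width(items2)[as.character(seqnames(items2)) == ch]))
  }
  expect_error(
    shuffle_intervals(gr("chr2", 1, 6e5), asm, seed = 1),
    "longer than its chromosome")
})

test_that("shuffled starts are uniform over valid positions", {
  asm <- genome_assembly("toy", c(chr1 = 1e6))
  item <- gr("chr1", 1, 500)
  starts <- vapply(1:10000, function(i) {
    start(shuffle_intervals(item, asm, seed = i))
  }, numeric(1))
  # chi-square against uniform over 10 equal bins of the valid range
  bins <- cut(starts, breaks = seq(1, 1e6 - 500 + 2, length.out = 11),
              include.lowest = TRUE)
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})

test_that("TFCR BED round-trips exactly", {
  tf <- mk_tfcrs(c(100, 5000, 9000), complexity = c(1, 3, 7),
                 strength = c(1, 2.718281828459045, 7.25))
  tf <- assign_decile_groups(c(tf, mk_tfcrs(20000 + 400 * (1:7),
                                            complexity = 2:8)))
  f <- withr::local_tempfile(fileext = ".bed")
  write_tfcrs_bed(tf, f)
  back <- read_tfcrs_bed(f)
  expect_equal(start(back), start(tf))
  expect_equal(end(back), end(tf))
  expect_identical(back$tfcr_id, tf$tfcr_id)
  expect_identical(back$summit, tf$summit)
  expect_identical(back$complexity, tf$complexity)
  expect_identical(back$decile_group, tf$decile_group)
  expect_equal(back$strength, tf$strength) # full-precision column
})

test_that("gene model reading applies the strand rule and rejects dups", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               "gA\tchr1\t3000\t5000\t-",
               "gB\tchr1\t9000\t9800\t+"), f)
  g <- read_gene_models(f)
  expect_equal(g$tss, c(5000, 9000))          # '-' strand: TSS = end
  expect_equal(start(g$promoter), c(3000, 7000))
  expect_equal(width(g$promoter), c(4000, 4000))
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               "gA\tchr1\t1\t10\t+", "gA\tchr1\t5\t20\t+"), f)
  expect_error(read_gene_models(f), "duplicate gene ids")
})

test_that("GTF-lite gene lines parse", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "#comment",
    paste("chr1", "src", "gene", "100", "900", ".", "+", ".",
          'gene_id "gX"; gene_name "X";', sep = "\t"),
    paste("chr1", "src", "exon", "100", "300", ".", "+", ".",
          'gene_id "gX";', sep = "\t")
  ), f)
  g <- read_gene_models(f, format = "gtf")
  expect_equal(g$gene_id, "gX")
  expect_equal(g$tss, 100)
})

test_that("expression and homolog tables read with validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\texpression", "g1\t5.5", "g2\t0"), f)
  e <- read_expression(f, stage_id = "s1")
  expect_equal(unname(e$values["g1"]), 5.5)
  writeLines(c("gene_id\texpression", "g1\t-1"), f)
  expect_error(read_expression(f), "negative")
  writeLines(c("human\tmouse", "hA\tmA", "hB\tmB"), f)
  hm <- read_homolog_map(f)
  expect_equal(nrow(hm), 2L)
  expect_named(hm, c("human", "mouse"))
})

test_that("chrom.sizes round-trips and computes the size multiple", {
  asm <- genome_assembly("toy", c(chr1 = 2e6, chr2 = 1e6))
  expect_equal(asm$genome_size, 3e6)
  f <- withr::local_tempfile()
  write_chrom_sizes(asm, f)
  back <- read_chrom_sizes(f, name = "toy")
  expect_equal(back$chrom_sizes, asm$chrom_sizes)
  # N relative to a custom reference
  asm2 <- genome_assembly("big", c(c1 = 5e6), reference_size = 1e6)
  expect_equal(asm2$size_multiple_n, 5)
  expect_error(genome_assembly("bad", c(chr1 = 0)), "positive")
  expect_error(genome_assembly("bad", c(1e6)), "named")
})
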