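test_that("same-family overlapping hits merge; different families do not", {
  # same family, overlapping: [101..110] + [106..115] -> [101..115]
  h <- gr("chr1", c(101, 106, 501, 501), c(110, 115, 510, 510),
          motif_id = sprintf("M%03d", 1:4),
          tf_family = c("F1", "F1", "F1", "F2"),
          score = rep(10, 4), p_value = rep(1e-6, 4))
  m <- merge_family_overlaps(h)
  merged <- m[start(m) == 101]
  expect_length(merged, 1L)
  expect_equal(end(merged), 115)
  expect_equal(merged$motif_id, "M001,M002")
  # different families at identical coordinates: both retained
  expect_length(m[start(m) == 501], 2L)
})

test_that("family merging is transitive over overlap chains", {
  # chain: 101..110, 108..117, 115..124 pairwise-overlapping, one family
  h <- gr("chr1", c(101, 108, 115), c(110, 117, 124),
          motif_id = sprintf("M%03d", 1:3), tf_family = rep("F1", 3),
          score = rep(10, 3), p_value = rep(1e-6, 3))
  m <- merge_family_overlaps(h)
  expect_length(m, 1L)
  expect_equal(c(start(m), end(m)), c(101, 124))
  # oracle: transitive closure via interval union
  expect_equal(width(m), width(reduce(h)))
})

test_that("density profile matches single- and two-kernel closed forms", {
  p <- caller_params()
  d <- density_profile(1000, p, from = 1000, to = 1300)
  expect_equal(d$density[d$pos == 1000], 1.0)
  expect_equal(d$density[d$pos == 1300], exp(-0.5))
  # additivity: two coincident centers
  d2 <- density_profile(c(1000, 1000), p, from = 1000, to = 1000)
  expect_equal(d2$density, 2.0)
  # empty input
  expect_equal(nrow(density_profile(numeric(0), p)), 0L)
})

test_that("density profile equals the brute-force per-bp oracle", {
  withr::local_seed(5)
  p <- caller_params()
  for (rep in 1:8) {
    centers <- sort(sample(10000:12000, sample(2:20, 1)))
    prof <- density_profile(centers, p)
    expect_lt(max(abs(prof$density -
                        bf_density(centers, prof$pos, 300))), 1e-9)
  }
})

test_that("two hits 400 bp apart give one TFCR of complexity 2", {
  tf <- call_tfcrs(mk_hits(c(1000, 1400)))
  expect_length(tf, 1L)
  expect_equal(tf$summit, 1200)              # midpoint summit
  expect_equal(tf$strength, 2 * exp(-200^2 / (2 * 300^2)),
               tolerance = 1e-12)
  expect_equal(tf$complexity, 2L)
  expect_equal(sort(unlist(tf$contributors)), c(1L, 2L))
  # interval spans the contributors, summit inside
  expect_equal(c(start(tf), end(tf)), c(995, 1404))
})

test_that("two hits 5 kb apart give two TFCRs of complexity 1", {
  tf <- call_tfcrs(mk_hits(c(1000, 6000)))
  expect_length(tf, 2L)
  expect_equal(tf$summit, c(1000, 6000))
  expect_equal(tf$complexity, c(1L, 1L))
  expect_equal(tf$strength, c(1, 1))
  # cross-contribution exp(-5000^2/(2*300^2)) is far below 0.1
  expect_identical(as.list(tf$contributors), list(1L, 2L))
})

test_that("an isolated hit yields complexity 1, strength 1", {
  tf <- call_tfcrs(mk_hits(500000))
  expect_length(tf, 1L)
  expect_equal(tf$complexity, 1L)
  expect_equal(tf$strength, 1.0)
})

test_that("flat summits collapse to the floor of their midpoint", {
  # centers 401 bp apart: the two central grid points tie exactly
  tf <- call_tfcrs(mk_hits(c(1000, 1401)))
  expect_length(tf, 1L)
  expect_equal(tf$summit, 1200)
})

test_that("caller agrees with the brute-force oracle on random instances", {
  withr::local_seed(11)
  p <- caller_params()
  for (rep in 1:10) {
    n <- sample(2:50, 1)
    span <- sample(c(3000, 8000), 1)         # single- and multi-island
    centers <- sort(sample(seq(50000, 50000 + span), n))
    hits <- mk_hits(centers)
    tf <- call_tfcrs(hits, p)
    pos <- seq(min(centers), max(centers))
    dens <- bf_density(centers, pos, 300)
    pk <- bf_peaks(dens)
    keep <- vapply(pk, function(i) {
      any(exp(-(centers - pos[i])^2 / (2 * 300^2)) >= 0.1)
    }, logical(1))
    pk <- pk[keep]
    expect_equal(tf$summit, pos[pk])
    expect_equal(tf$strength, dens[pk], tolerance = 1e-9)
    for (j in seq_along(pk)) {
      contrib <- which(exp(-(centers - pos[pk[j]])^2 / (2 * 300^2)) >= 0.1)
      expect_equal(sort(unlist(tf$contributors[[j]])), contrib)
    }
  }
})

test_that("complexity does not decrease when a hit lands near a summit", {
  withr::local_seed(21)
  for (rep in 1:5) {
    centers <- sort(sample(10000:13000, 8))
    tf1 <- call_tfcrs(mk_hits(centers))
    s <- tf1$summit[1L]
    tf2 <- call_tfcrs(mk_hits(sort(c(centers, s + 100))))
    near1 <- tf1[abs(tf1$summit - s) <= 200]
    near2 <- tf2[abs(tf2$summit - s) <= 200]
    expect_gte(max(near2$complexity), max(near1$complexity))
  }
})

test_that("synthetic single clusters recover complexity = cluster size", {
  cfg <- synth_config(seed = 3, n_chroms = 1, chrom_length = 1e5,
                      n_genes = 5, n_clusters = 1,
                      promoter_cluster_prob = 1,
                      cluster_size_dist = list(type = "fixed", k = 10),
                      background_rate = 0, n_stages = 1,
                      zga_stage_index = NA)
  ds <- make_dataset(cfg, make_sequence = FALSE)
  tf <- call_tfcrs(ds$stages[[1L]]$hits)
  expect_length(tf, 1L)
  expect_equal(tf$complexity, 10L)
})

test_that("decile groups are equal-sized and ordered by complexity", {
  tf <- mk_tfcrs(1000 * (1:100), complexity = sample(1:100))
  g <- assign_decile_groups(tf)
  expect_equal(as.vector(table(g$decile_group)), rep(10L, 10))
  expect_equal(g$decile_group[which.max(g$complexity)], 9L)
  expect_equal(g$decile_group[which.min(g$complexity)], 0L)
  # all-tied complexities still split evenly via deterministic tie-break
  tf2 <- mk_tfcrs(1000 * (1:95), complexity = rep(3L, 95))
  g2 <- assign_decile_groups(tf2)
  expect_true(all(table(g2$decile_group) %in% c(9L, 10L)))
  g2b <- assign_decile_groups(tf2)
  expect_identical(g2$decile_group, g2b$decile_group)
  expect_error(assign_decile_groups(mk_tfcrs(1:5 * 1000)), "at least 10")
})

test_that("overlap comparison uses the strict 50% shared-base rule", {
  a <- mk_tfcrs(1, widths = 100L)             # 1..100
  expect_equal(overlap_compare(a, a), 1.0)
  expect_equal(overlap_compare(a, mk_tfcrs(61, widths = 100L)), 0.0) # 40 bp
  expect_equal(overlap_compare(a, mk_tfcrs(41, widths = 120L)), 1.0) # 60 bp
  # exactly half is NOT over 50%
  expect_equal(overlap_compare(a, mk_tfcrs(51, widths = 100L)), 0.0)
  # shared bases accumulate across several b intervals
  b <- c(mk_tfcrs(1, widths = 30L), mk_tfcrs(41, widths = 30L))
  expect_equal(overlap_compare(a, b), 1.0)    # 60 of 100 bp
  expect_error(overlap_compare(a[0], a), "non-empty")
})

test_that("caller parameters are validated", {
  expect_error(caller_params(bandwidth_h = 0), "positive")
  expect_error(caller_params(contribution_threshold = 1.5), "in \\(0, 1\\)")
})
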