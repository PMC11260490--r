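#' Classify TFCR dynamics across consecutive developmental stages
#'
#' At stage t a TFCR is *gained* when it shares no base with any TFCR
#' of stage t-1, *lost* when it shares no base with any TFCR of stage
#' t+1, and *stable* otherwise (the 1 bp-overlap rule). The first stage
#' has no gained status and the last no lost status. A TFCR can be both
#' gained and lost; the summary `label` reports gained first, then
#' lost, then stable.
#'
#' @param series named list (>= 2 elements) of per-stage TFCR `GRanges`,
#'   in developmental order.
#' @return data.frame with columns `stage`, `tfcr_id`, `gained`
#'   (logical, `NA` at the first stage), `lost` (logical, `NA` at the
#'   last stage) and `label`.
#' @export
classify_dynamics <- function(series) {
  if (length(series) < 2L) stop("need at least 2 stages")
  stage_names <- names(series)
  if (is.null(stage_names)) stage_names <- sprintf("stage%02d",
                                                   seq_along(series))
  out <- vector("list", length(series))
  for (t in seq_along(series)) {
    cur <- series[[t]]
    gained <- if (t == 1L) rep(NA, length(cur)) else {
      !IRanges::overlapsAny(cur, series[[t - 1L]], minoverlap = 1L,
                            ignore.strand = TRUE)
    }
    lost <- if (t == length(series)) rep(NA, length(cur)) else {
      !IRanges::overlapsAny(cur, series[[t + 1L]], minoverlap = 1L,
                            ignore.strand = TRUE)
    }
    label <- ifelse(!is.na(gained) & gained, "gained",
                    ifelse(!is.na(lost) & lost, "lost", "stable"))
    ids <- if (!is.null(cur$tfcr_id)) cur$tfcr_id else
      sprintf("%s_%d", stage_names[t], seq_along(cur))
    out[[t]] <- data.frame(stage = stage_names[t], tfcr_id = ids,
                           gained = gained, lost = lost, label = label,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fraction of a stage's TFCRs gained since the previous stage
#'
#' @param series as in [classify_dynamics()].
#' @param stage stage index (>= 2) or name.
#' @return `|gained at stage| / |TFCRs at stage|`.
#' @export
gained_fraction <- function(series, stage) {
  if (is.character(stage)) stage <- match(stage, names(series))
  if (is.na(stage) || stage < 2L || stage > length(series)) {
    stop("stage must have a predecessor")
  }
  cur <- series[[stage]]
  if (length(cur) == 0L) stop("no TFCRs at stage ", stage)
  mean(!IRanges::overlapsAny(cur, series[[stage - 1L]], minoverlap = 1L,
                             ignore.strand = TRUE))
}

#' Fraction of a stage's TFCRs lost before the next stage
#' @param series as in [classify_dynamics()].
#' @param stage stage index (<= length - 1) or name.
#' @return `|lost at stage| / |TFCRs at stage|`.
#' @export
lost_fraction <- function(series, stage) {
  if (is.character(stage)) stage <- match(stage, names(series))
  if (is.na(stage) || stage < 1L || stage >= length(series)) {
    stop("stage must have a successor")
  }
  cur <- series[[stage]]
  if (length(cur) == 0L) stop("no TFCRs at stage ", stage)
  mean(!IRanges::overlapsAny(cur, series[[stage + 1L]], minoverlap = 1L,
                             ignore.strand = TRUE))
}

#' Permutation test: are stable TFCRs more often in promoters?
#'
#' One-sided test of the directional claim that stable TFCRs sit in
#' promoters more often than dynamic (gained or lost) TFCRs. The
#' statistic is the difference of promoter fractions; the null is built
#' by shuffling the stable/dynamic labels over the pooled set, and the
#' p-value uses add-one smoothing:
#' `p = (1 + #[null >= observed]) / (n_perm + 1)`.
#'
#' @param stable_set,dynamic_set TFCR `GRanges`, both non-empty.
#' @param genes annotated gene `GRanges`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` difference, and the vector
#'   of `null` differences.
#' @export
permutation_test_promoter_fraction <- function(stable_set, dynamic_set,
                                               genes, n_perm = 999L,
                                               seed = 1L) {
  if (length(stable_set) == 0L || length(dynamic_set) == 0L) {
    stop("both TFCR sets must be non-empty")
  }
  if (n_perm < 100L) stop("n_perm must be at least 100")
  proms <- promoter_ranges(genes)
  ind <- c(IRanges::overlapsAny(stable_set, proms, ignore.strand = TRUE),
           IRanges::overlapsAny(dynamic_set, proms, ignore.strand = TRUE))
  n_stable <- length(stable_set)
  n_total <- length(ind)
  observed <- mean(ind[seq_len(n_stable)]) - mean(ind[-seq_len(n_stable)])
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample.int(n_total, n_stable)
      mean(ind[lab]) - mean(ind[-lab])
    }, numeric(1))
  })
  list(
    p_value = (1 + sum(null >= observed)) / (n_perm + 1),
    observed = observed,
    null = null
  )
}
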