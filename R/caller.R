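#' Parameters of the kernel-density TFCR caller
#'
#' TFCRs are peaks of an unnormalised Gaussian kernel density computed
#' over motif-hit centers. Each hit contributes
#' `K(d) = exp(-d^2 / (2 h^2))` to the density `d` bp away, so an
#' isolated hit has density exactly 1 at its own center. A hit is a
#' *contributor* of a peak iff its kernel value at the summit is at
#' least `contribution_threshold`; with the defaults (h = 300 bp,
#' threshold 0.1) that is every hit within `300 * sqrt(2 * ln 10)`,
#' about 644 bp, of the summit.
#'
#' @param bandwidth_h Gaussian kernel bandwidth in bp (default 300).
#' @param contribution_threshold minimum kernel value at the summit for
#'   a hit to count towards complexity (default 0.1).
#' @param grid_step density evaluation step in bp (default 1).
#' @return a `caller_params` list.
#' @export
caller_params <- function(bandwidth_h = 300, contribution_threshold = 0.1,
                          grid_step = 1) {
  if (bandwidth_h <= 0) stop("bandwidth_h must be positive")
  if (contribution_threshold <= 0 || contribution_threshold >= 1) {
    stop("contribution_threshold must be in (0, 1)")
  }
  if (grid_step < 1) stop("grid_step must be >= 1")
  structure(list(bandwidth_h = bandwidth_h,
                 contribution_threshold = contribution_threshold,
                 grid_step = grid_step),
            class = "caller_params")
}

# Kernel truncation radius, in bandwidths. exp(-8^2/2) ~ 1.3e-14 per
# kernel, so truncation error stays below 1e-9 even for thousands of
# hits; density is treated as exactly zero farther away.
KERNEL_CUTOFF_BW <- 8

#' Merge overlapping motif hits of the same TF family
#'
#' Overlapping binding sites for factors of one family are usually the
#' same biological signal reported under several motif ids; counting
#' them separately would inflate TFCR complexity. Hits of the same
#' family sharing at least 1 bp are merged transitively into one hit
#' spanning their union; hits of different families are never merged.
#'
#' @param hits motif-hit `GRanges` (needs a `tf_family` column).
#' @return merged `GRanges`; `motif_id` of a merged hit joins its
#'   members' ids with `,`, `score` is their maximum, `p_value` their
#'   minimum, `center` is recomputed from the merged interval.
#' @export
merge_family_overlaps <- function(hits) {
  if (length(hits) == 0L) return(hits)
  fam <- hits$tf_family
  out <- lapply(split(seq_along(hits), fam), function(idx) {
    sub <- hits[idx]
    red <- GenomicRanges::reduce(sub, min.gapwidth = 0L, with.revmap = TRUE,
                                 ignore.strand = TRUE)
    members <- red$revmap
    red$revmap <- NULL
    red$motif_id <- vapply(members, function(m)
      paste(sub$motif_id[m], collapse = ","), character(1))
    red$tf_family <- rep(sub$tf_family[[1L]], length(red))
    red$score <- vapply(members, function(m) max(sub$score[m]), numeric(1))
    red$p_value <- vapply(members, function(m) min(sub$p_value[m]), numeric(1))
    red
  })
  merged <- do.call(c, unname(out))
  merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
  merged$center <- hit_centers(merged)
  merged
}

#' Gaussian kernel density profile over hit centers
#'
#' Evaluates the unnormalised density
#' `f(x) = sum_i exp(-(x - c_i)^2 / (2 h^2))` on an integer-bp grid.
#' Kernels are truncated at 8 bandwidths (error < 1.3e-14 per hit).
#'
#' @param centers numeric vector of hit center positions (one
#'   chromosome).
#' @param params [caller_params()].
#' @param from,to grid bounds; default to the span of `centers`.
#' @return data.frame with columns `pos` and `density`; zero rows for
#'   empty input.
#' @export
density_profile <- function(centers, params = caller_params(),
                            from = NULL, to = NULL) {
  if (length(centers) == 0L) {
    return(data.frame(pos = numeric(0), density = numeric(0)))
  }
  h <- params$bandwidth_h
  if (is.null(from)) from <- min(centers)
  if (is.null(to)) to <- max(centers)
  pos <- seq(from, to, by = params$grid_step)
  dens <- kde_profile_cpp(sort(as.numeric(centers)), from, to,
                          params$grid_step, h, KERNEL_CUTOFF_BW * h)
  data.frame(pos = pos, density = dens)
}

# Strict local maxima of a density vector, with flat summits collapsed
# to the floor of their midpoint. Returns indices into the vector.
profile_peak_indices <- function(dens) {
  n <- length(dens)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  # run-length encode so plateaus act as single points
  r <- rle(dens)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_peak <- vapply(seq_len(k), function(j) {
    left_ok <- j == 1L || r$values[j - 1L] < r$values[j]
    right_ok <- j == k || r$values[j + 1L] < r$values[j]
    left_ok && right_ok
  }, logical(1))
  as.integer(floor((starts[is_peak] + ends[is_peak]) / 2))
}

#' Call TFCRs from motif hits
#'
#' Runs the Gaussian KDE over hit centers chromosome by chromosome and
#' reports one TFCR per strict local maximum of the density profile.
#' For each summit, the contributors are the hits whose kernel value at
#' the summit reaches `contribution_threshold`; complexity is the
#' contributor count, strength the density at the summit, and the TFCR
#' interval spans all contributor intervals. A hit may contribute to
#' two adjacent peaks.
#'
#' Hits should already be family-merged (see [merge_family_overlaps()])
#' if same-family duplicates are to be collapsed; set
#' `merge_families = TRUE` to do it here.
#'
#' @param hits motif-hit `GRanges`.
#' @param params [caller_params()].
#' @param merge_families merge same-family overlapping hits first.
#' @return `GRanges` of TFCRs with metadata columns `tfcr_id`, `summit`,
#'   `strength`, `complexity` and `contributors` (an `IntegerList` of
#'   indices into the family-merged hit set, which is returned as the
#'   `hits` attribute of the result's metadata).
#' @export
call_tfcrs <- function(hits, params = caller_params(),
                       merge_families = FALSE) {
  if (merge_families) hits <- merge_family_overlaps(hits)
  if (length(hits) == 0L) {
    out <- GenomicRanges::GRanges()
    out$tfcr_id <- character(0)
    out$summit <- integer(0)
    out$strength <- numeric(0)
    out$complexity <- integer(0)
    out$contributors <- IRanges::IntegerList()
    return(out)
  }
  h <- params$bandwidth_h
  thr <- params$contribution_threshold
  cutoff <- KERNEL_CUTOFF_BW * h
  if (is.null(hits$center)) hits$center <- hit_centers(hits)
  chroms <- as.character(GenomicRanges::seqnames(hits))
  hit_start <- GenomicRanges::start(hits)
  hit_end <- GenomicRanges::end(hits)
  per_chrom <- split(seq_along(hits), chroms)
  res <- list()
  for (chrom in names(per_chrom)) {
    idx <- per_chrom[[chrom]]
    centers <- as.numeric(hits$center[idx])
    ord <- order(centers)
    idx <- idx[ord]
    centers <- centers[ord]
    # hits separated by more than the truncation radius cannot reach
    # each other's grid span [min(c), max(c)], so such islands are
    # exactly independent under the truncated kernel
    gaps <- which(diff(centers) > cutoff)
    island_start <- c(1L, gaps + 1L)
    island_end <- c(gaps, length(centers))
    for (s in seq_along(island_start)) {
      ii <- island_start[s]:island_end[s]
      ic <- centers[ii]
      ihit <- idx[ii]
      dens <- kde_profile_cpp(ic, min(ic), max(ic), params$grid_step,
                              h, cutoff)
      pos <- seq(min(ic), max(ic), by = params$grid_step)
      peaks <- profile_peak_indices(dens)
      for (p in peaks) {
        xs <- pos[p]
        contrib <- exp(-(ic - xs)^2 / (2 * h^2))
        keep <- contrib >= thr
        # a strict maximum with no contributing hit is a numerical
        # artifact of kernel truncation (density ~1e-14); drop it
        if (!any(keep)) next
        members <- ihit[keep]
        res[[length(res) + 1L]] <- list(
          chrom = chrom,
          start = min(hit_start[members]),
          end = max(hit_end[members]),
          summit = xs,
          strength = dens[p],
          complexity = sum(keep),
          members = members
        )
      }
    }
  }
  chrom_v <- vapply(res, `[[`, character(1), "chrom")
  start_v <- vapply(res, `[[`, numeric(1), "start")
  out <- GenomicRanges::GRanges(
    seqnames = chrom_v,
    ranges = IRanges::IRanges(
      start = start_v,
      end = vapply(res, `[[`, numeric(1), "end")
    ),
    strand = "*"
  )
  out$summit <- as.integer(vapply(res, `[[`, numeric(1), "summit"))
  out$strength <- vapply(res, `[[`, numeric(1), "strength")
  out$complexity <- as.integer(vapply(res, `[[`, numeric(1), "complexity"))
  out$contributors <- IRanges::IntegerList(lapply(res, `[[`, "members"))
  ord <- order(chrom_v, out$summit)
  out <- out[ord]
  out$tfcr_id <- sprintf("TFCR_%05d", seq_along(out))
  out
}

#' Assign complexity decile groups TFCR0..TFCR9
#'
#' Splits TFCRs into 10 equal-count groups by complexity, lowest
#' complexity in group 0 and highest in group 9. Ties are broken
#' deterministically by strength, then chromosome, then start, so group
#' sizes differ by at most one even when complexities repeat.
#'
#' @param tfcrs TFCR `GRanges` (at least 10).
#' @return the input with a `decile_group` integer column in 0..9.
#' @export
assign_decile_groups <- function(tfcrs) {
  n <- length(tfcrs)
  if (n < 10L) stop("need at least 10 TFCRs to form decile groups, got ", n)
  ord <- order(tfcrs$complexity, tfcrs$strength,
               as.character(GenomicRanges::seqnames(tfcrs)),
               GenomicRanges::start(tfcrs))
  grp <- integer(n)
  grp[ord] <- as.integer(floor((seq_len(n) - 1L) * 10 / n))
  tfcrs$decile_group <- grp
  tfcrs
}

#' Fraction of one TFCR set recovered in another
#'
#' A TFCR of `set_a` counts as overlapped when more than
#' `min_shared_frac` of its own bases are covered by `set_b` (the
#' "share over 50% base pairs" criterion used to compare calls from
#' different motif libraries).
#'
#' @param set_a,set_b TFCR `GRanges`.
#' @param min_shared_frac required shared-base fraction (strict `>`).
#' @return `|overlapped| / |set_a|`.
#' @export
overlap_compare <- function(set_a, set_b, min_shared_frac = 0.5) {
  if (length(set_a) == 0L) stop("set_a must be non-empty")
  if (length(set_b) == 0L) return(0)
  b <- GenomicRanges::reduce(set_b, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(set_a, b, ignore.strand = TRUE)
  shared <- numeric(length(set_a))
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    inter <- GenomicRanges::pintersect(set_a[qi], b[S4Vectors::subjectHits(ov)],
                                       ignore.strand = TRUE)
    w <- GenomicRanges::width(inter)
    agg <- tapply(w, qi, sum)
    shared[as.integer(names(agg))] <- as.numeric(agg)
  }
  mean(shared / GenomicRanges::width(set_a) > min_shared_frac)
}
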