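# Candidate introgression blocks: runs of adjacent lowly divergent SGs on
# the framework genome, with a permutation test for non-random clustering.

#' Mask of lowly divergent SGs
#'
#' Strict inequality (`hdg < threshold`); `NA` HDG values are never low
#' (they keep their position in the track but cannot extend a block).
#'
#' @param track An `hdg_track`.
#' @param threshold Divergence cutoff.
#' @return Logical vector aligned to the track rows.
#' @export
low_hdg_mask <- function(track, threshold = 0.5) {
  !is.na(track$hdg) & track$hdg < threshold
}

#' Merge adjacent lowly divergent SGs into candidate introgression blocks
#'
#' Maximal runs of consecutive low SGs within a chromosome become blocks
#' (a single non-low SG breaks a run unless `max_gap` allows it); runs of
#' fewer than `min_block_sgs` SGs are dropped. Block ids are assigned per
#' chromosome in descending bp length as `"chrom#k"`.
#'
#' @param mask Logical vector from [low_hdg_mask()], aligned to `track`.
#' @param track The `hdg_track` the mask was computed from.
#' @param min_block_sgs Minimum number of SGs per block.
#' @param max_gap Number of consecutive non-low SGs tolerated inside a
#'   block (default 0: strictly consecutive).
#' @return data.frame of blocks: `block_id`, `chrom`, `start`, `end`,
#'   `n_sgs`, `mean_hdg`, `idx_start`/`idx_end` (SG indices within the
#'   chromosome's track), and `sg_ids` (comma-joined).
#' @export
merge_blocks <- function(mask, track, min_block_sgs = 10L, max_gap = 0L) {
  stopifnot(length(mask) == nrow(track))
  out <- list()
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch)
    m <- mask[rows]
    if (!any(m)) next
    # close gaps of up to max_gap non-low SGs flanked by low SGs
    if (max_gap > 0L) {
      r <- rle(m)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$lengths)) {
        if (!r$values[k] && r$lengths[k] <= max_gap &&
            k > 1L && k < length(r$lengths)) {
          m[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
        }
      }
    }
    r <- rle(m)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_block_sgs)) {
      idx <- rows[lo[k]:hi[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = min(track$start[idx]), end = max(track$end[idx]),
        n_sgs = length(idx),
        mean_hdg = mean(track$hdg[idx], na.rm = TRUE),
        idx_start = lo[k], idx_end = hi[k],
        sg_ids = paste(track$sg_id[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(block_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_sgs = integer(),
                      mean_hdg = numeric(), idx_start = integer(),
                      idx_end = integer(), sg_ids = character(),
                      stringsAsFactors = FALSE))
  }
  blocks <- do.call(rbind, out)
  # ids per chromosome by descending genomic length
  blocks$block_id <- NA_character_
  for (ch in unique(blocks$chrom)) {
    i <- which(blocks$chrom == ch)
    o <- i[order(-(blocks$end[i] - blocks$start[i]), blocks$start[i])]
    blocks$block_id[o] <- paste0(ch, "#", seq_along(o))
  }
  blocks[, c("block_id", "chrom", "start", "end", "n_sgs", "mean_hdg",
             "idx_start", "idx_end", "sg_ids")]
}

#' Permutation test for clustering of lowly divergent SGs
#'
#' Per replicate, the same number of SGs as observed low SGs is sampled
#' uniformly without replacement from the chromosome's SG positions; for
#' each sliding window of `window` consecutive SGs, the empirical P value
#' is the fraction of replicates whose sampled count in the window strictly
#' exceeds the observed count (optionally with a `(r + 1) / (n + 1)`
#' pseudocount correction).
#'
#' @param n_sgs Number of SG positions on the chromosome.
#' @param low_idx Integer indices (1-based) of the observed low SGs.
#' @param window Window width in SGs.
#' @param step Window step in SGs.
#' @param n_reps Number of random samplings.
#' @param seed Optional RNG seed.
#' @param pseudocount Use the `(r + 1) / (n + 1)` small-sample correction.
#' @param inclusive Count replicates tying the observed count as well
#'   (`P(X >= obs)`). The default strict rule counts only replicates whose
#'   density is higher than the observed one; note that the strict rule is
#'   anti-conservative under sparse nulls (a window tying the discrete
#'   rejection boundary is called significant), whereas the inclusive rule
#'   guarantees `P(p < alpha) <= alpha` under the null.
#' @return A `cluster_test` data.frame: `win_start`, `win_end` (inclusive
#'   SG indices), `observed`, `p`; attribute `n_reps`.
#' @export
cluster_test <- function(n_sgs, low_idx, window = 10L, step = 1L,
                         n_reps = 100000L, seed = NULL,
                         pseudocount = FALSE, inclusive = FALSE) {
  stopifnot(n_reps >= 1L, window >= 1L, step >= 1L)
  low_idx <- unique(as.integer(low_idx))
  k <- length(low_idx)
  if (k > n_sgs) stop("more low SGs than SG positions on the chromosome")
  if (any(low_idx < 1L | low_idx > n_sgs)) {
    stop("low SG indices outside the chromosome's SG range")
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_sgs <= window) {
    ws <- 1L
  } else {
    ws <- seq.int(1L, n_sgs - window + 1L, by = step)
  }
  we <- pmin(ws + window - 1L, n_sgs)
  pres <- tabulate(low_idx, n_sgs)
  cs <- cumsum(pres)
  obs <- cs[we] - c(0L, cs)[ws]
  exceed <- if (k == 0L && !inclusive) rep(0L, length(ws)) else
    .perm_window_test(n_sgs, k, as.integer(ws), as.integer(we),
                      as.integer(obs), as.integer(n_reps), inclusive)
  p <- if (pseudocount) (exceed + 1) / (n_reps + 1) else exceed / n_reps
  out <- data.frame(win_start = ws, win_end = we, observed = as.integer(obs),
                    p = p)
  attr(out, "n_reps") <- n_reps
  class(out) <- c("cluster_test", class(out))
  out
}

#' Cluster tests for every chromosome of an HDG track
#'
#' @param track An `hdg_track`.
#' @param mask Logical low mask from [low_hdg_mask()].
#' @inheritParams cluster_test
#' @return Named list (by chromosome) of `cluster_test` results.
#' @export
cluster_test_track <- function(track, mask, window = 10L, step = 1L,
                               n_reps = 100000L, seed = NULL,
                               pseudocount = FALSE, inclusive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(track$chrom)
  out <- lapply(chroms, function(ch) {
    rows <- which(track$chrom == ch)
    cluster_test(length(rows), which(mask[rows]), window = window,
                 step = step, n_reps = n_reps, pseudocount = pseudocount,
                 inclusive = inclusive)
  })
  stats::setNames(out, chroms)
}

#' Filter blocks by permutation-test significance
#'
#' A block is kept when at least one sliding window overlapping its SG
#' index range has `P <= alpha` (inclusive); the minimum overlapping-window
#' P value is annotated as `min_window_p`.
#'
#' @param blocks data.frame from [merge_blocks()].
#' @param tests Named list of `cluster_test` results per chromosome (see
#'   [cluster_test_track()]).
#' @param alpha Significance cutoff.
#' @return The kept blocks with a `min_window_p` column.
#' @export
significant_blocks <- function(blocks, tests, alpha = 0.01) {
  if (!nrow(blocks)) {
    blocks$min_window_p <- numeric(0)
    return(blocks)
  }
  blocks$min_window_p <- vapply(seq_len(nrow(blocks)), function(i) {
    tt <- tests[[blocks$chrom[i]]]
    if (is.null(tt)) stop("no cluster test for chromosome ", blocks$chrom[i])
    ov <- tt$win_start <= blocks$idx_end[i] & tt$win_end >= blocks$idx_start[i]
    if (!any(ov)) NA_real_ else min(tt$p[ov])
  }, numeric(1L))
  blocks[!is.na(blocks$min_window_p) & blocks$min_window_p <= alpha, ,
         drop = FALSE]
}

#' Summary of introgression blocks
#'
#' @param blocks data.frame of blocks.
#' @param framework_length Total framework assembly length in bp (e.g. from
#'   [annotation_span()]).
#' @return List with `n_blocks`, `total_bp` and `fraction` of the framework
#'   genome covered.
#' @export
block_summary <- function(blocks, framework_length) {
  total <- if (nrow(blocks)) sum(blocks$end - blocks$start) else 0
  list(n_blocks = nrow(blocks), total_bp = total,
       fraction = if (framework_length > 0) total / framework_length else 0)
}

#' Approximate assembly span of an annotation
#'
#' Sum over chromosomes of the maximum gene end coordinate; a proxy for
#' assembly length when only gene models are available.
#'
#' @param annotation A [genome_annotation()].
#' @return Total bp.
#' @export
annotation_span <- function(annotation) {
  g <- annotation$genes
  if (!nrow(g)) return(0)
  sum(tapply(g$end, g$chrom, max))
}
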