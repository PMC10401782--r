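# End-to-end driver: tandem collapsing, pairwise syntelog calling,
# pan-genome merge, haplotypes, HDG and introgression blocks.

reverse_hits <- function(h) {
  data.frame(query = h$subject, subject = h$query, pident = h$pident,
             length = h$length, mismatch = h$mismatch, gapopen = h$gapopen,
             qstart = h$sstart, qend = h$send, sstart = h$qstart,
             send = h$qend, evalue = h$evalue, bitscore = h$bitscore,
             stringsAsFactors = FALSE)
}

get_pair_hits <- function(hits, a, b) {
  k1 <- paste(a, b, sep = "|"); k2 <- paste(b, a, sep = "|")
  if (!is.null(hits[[k1]])) return(hits[[k1]])
  if (!is.null(hits[[k2]])) return(reverse_hits(hits[[k2]]))
  NULL
}

#' Run the full syntelog pan-genome pipeline
#'
#' Collapses individual-specific tandem duplicates (each genome is
#' collapsed against every partner genome in turn, so a duplicate absent
#' from at least one partner is reduced to its representative), calls
#' pairwise syntelogs for every genome pair by best-hit chaining, merges
#' them iteratively onto the framework genome, classifies occupancy,
#' builds haplotype catalogs and ancestral labels, computes the HDG track
#' between two populations, and detects permutation-supported candidate
#' introgression blocks.
#'
#' @param annotations Named list of [genome_annotation()]s with proteins.
#' @param hits Named list of hit tables, `"A|B"` = queries in A; either
#'   orientation per pair suffices.
#' @param groups A `group_config`.
#' @param order Merge order; defaults to `names(annotations)` with the
#'   first genome as framework.
#' @param params [chain_params()].
#' @param collapse Collapse tandem duplicates before chaining.
#' @param max_tandem_gap See [collapse_tandem()].
#' @param best_mode See [best_hits()].
#' @param soft_core_frac See [classify_occupancy()].
#' @param min_dominant_freq See [assign_ancestral()].
#' @param min_presence_total See [hdg()].
#' @param pop_a_labels,pop_b_labels Group labels of the two populations
#'   contrasted in the HDG track; default: first priority group versus all
#'   other groups. (In a GJ-vs-XI style contrast, drop divergent groups
#'   such as aus from `pop_b_labels`.)
#' @param hdg_threshold Low-divergence cutoff (strict `<`).
#' @param min_block_sgs Minimum SGs per block.
#' @param window,step,n_reps,alpha Clustering-test parameters, see
#'   [cluster_test()] and [significant_blocks()].
#' @param seed RNG seed for the permutation test.
#' @return List with `collapsed` annotations, `clusters`, `pair_sets`,
#'   `pan`, `occupancy`, `catalogs`, `assignments`, `track`, `mask`,
#'   `blocks` (candidates), `tests`, `sig_blocks`, `summary`, and the
#'   parameters used (`params_used`).
#' @export
run_pipeline <- function(annotations, hits, groups,
                         order = names(annotations),
                         params = chain_params(),
                         collapse = TRUE, max_tandem_gap = 1L,
                         best_mode = "per_query",
                         soft_core_frac = 0.90,
                         min_dominant_freq = 3L,
                         min_presence_total = 10L,
                         pop_a_labels = groups$priority[1L],
                         pop_b_labels = setdiff(unique(groups$assignment),
                                                groups$priority[1L]),
                         hdg_threshold = 0.5,
                         min_block_sgs = 10L,
                         window = 10L, step = 1L, n_reps = 100000L,
                         alpha = 0.01, seed = NULL) {
  stopifnot(all(order %in% names(annotations)))
  annotations <- annotations[order]

  clusters <- empty_tandem_clusters()
  if (collapse) {
    for (g in order) {
      for (m in setdiff(order, g)) {
        h <- get_pair_hits(hits, g, m)
        if (is.null(h) || !nrow(h)) next
        res <- collapse_tandem(annotations[[g]], best_hits(h, "per_query"),
                               max_tandem_gap = max_tandem_gap)
        annotations[[g]] <- res$annotation
        clusters <- rbind(clusters, res$clusters)
      }
    }
  }

  pair_sets <- list()
  n <- length(order)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- order[i]; b <- order[j]
      h <- get_pair_hits(hits, a, b)
      if (is.null(h)) next
      # restrict to surviving representatives on both sides
      h <- h[h$query %in% annotations[[a]]$genes$gene_id &
               h$subject %in% annotations[[b]]$genes$gene_id, , drop = FALSE]
      pair_sets[[paste(a, b, sep = "|")]] <-
        pair_syntelogs(annotations[[a]], annotations[[b]], h,
                       params = params, mode = best_mode)
    }
  }

  pan <- merge_pairwise(annotations, pair_sets, order)
  occupancy <- classify_occupancy(pan, soft_core_frac)
  catalogs <- build_catalogs(pan, annotations)
  assignments <- assign_ancestral_all(catalogs, groups, min_dominant_freq)

  pop_a <- group_members(groups, pop_a_labels)
  pop_b <- group_members(groups, pop_b_labels)
  track <- hdg_track(pan, catalogs, pop_a, pop_b, min_presence_total)
  mask <- low_hdg_mask(track, hdg_threshold)
  blocks <- merge_blocks(mask, track, min_block_sgs)
  tests <- cluster_test_track(track, mask, window = window, step = step,
                              n_reps = n_reps, seed = seed)
  sig <- significant_blocks(blocks, tests, alpha)
  framework_len <- annotation_span(annotations[[order[1L]]])
  list(collapsed = annotations, clusters = clusters, pair_sets = pair_sets,
       pan = pan, occupancy = occupancy, catalogs = catalogs,
       assignments = assignments, track = track, mask = mask,
       blocks = blocks, tests = tests, sig_blocks = sig,
       summary = block_summary(sig, framework_len),
       params_used = list(
         chain = params, soft_core_frac = soft_core_frac,
         min_dominant_freq = min_dominant_freq,
         min_presence_total = min_presence_total,
         pop_a_labels = pop_a_labels, pop_b_labels = pop_b_labels,
         hdg_threshold = hdg_threshold, min_block_sgs = min_block_sgs,
         window = window, step = step, n_reps = n_reps, alpha = alpha,
         seed = seed))
}
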