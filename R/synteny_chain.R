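# Chaining anchor pairs into collinear syntenic blocks by dynamic
# programming, syntelog calling, and synteny kinship.

#' Chaining parameters
#'
#' Defaults mirror the reference configuration: match-score cap `Z = 12`,
#' maximum inter-anchor distance `D = 200000` bp (measured between gene
#' midpoints on both genomes), gap penalty `g = 1` per skipped gene, and a
#' minimum of `A = 5` aligned anchor pairs per accepted chain.
#'
#' @param Z Maximum per-anchor match score (scores are capped at `Z`).
#' @param D Maximum bp distance between consecutive chained anchors,
#'   enforced on both genomes.
#' @param g Gap penalty per intervening (skipped) gene on either genome.
#' @param A Minimum number of anchors in an accepted chain.
#' @return A `chain_params` list.
#' @export
chain_params <- function(Z = 12, D = 200000L, g = 1, A = 5L) {
  stopifnot(Z > 0, D > 0, g >= 0, A >= 2)
  structure(list(Z = Z, D = as.numeric(D), g = g, A = as.integer(A)),
            class = "chain_params")
}

#' Chain anchors of one chromosome pair into syntenic blocks
#'
#' Finds highest-scoring collinear paths through the anchor DAG. Per-anchor
#' match scores are capped at `params$Z`; transitions are allowed only when
#' the midpoint distance between consecutive anchors is at most `params$D`
#' on both genomes, and cost `params$g` per skipped gene on either genome.
#' Both ascending and descending (inversion) orientations of genome B are
#' searched. Chains are extracted greedily by descending score into
#' anchor-disjoint sets; extraction stops once the best remaining chain has
#' fewer than `params$A` anchors, and shorter chains are discarded.
#'
#' @param anchors data.frame from [make_anchors()], restricted to a single
#'   (chrom_a, chrom_b) pair.
#' @param params A [chain_params()].
#' @return List of `synteny_chain` objects, each a list with `chrom_a`,
#'   `chrom_b`, `orientation` (`"ascending"`/`"descending"`), `anchors`
#'   (data.frame rows in chain order) and `score`. Ordered by descending
#'   score.
#' @export
chain_anchors <- function(anchors, params = chain_params()) {
  if (length(unique(anchors$chrom_a)) > 1L ||
      length(unique(anchors$chrom_b)) > 1L) {
    stop("chain_anchors() expects anchors from a single chromosome pair")
  }
  if (!nrow(anchors)) return(list())
  a <- anchors[order(anchors$rank_a, anchors$rank_b), , drop = FALSE]
  a$score_capped <- pmin(a$score, params$Z)
  used <- rep(FALSE, nrow(a))
  chains <- list()
  repeat {
    avail <- which(!used)
    if (!length(avail)) break
    sub <- a[avail, , drop = FALSE]
    best <- best_chain_path(sub, params)
    if (is.null(best)) break
    if (length(best$path) < params$A) break
    idx <- avail[best$path]
    used[idx] <- TRUE
    ch <- structure(
      list(chrom_a = a$chrom_a[1L], chrom_b = a$chrom_b[1L],
           orientation = best$orientation,
           anchors = a[idx, setdiff(names(a), "score_capped"), drop = FALSE],
           score = best$score),
      class = "synteny_chain")
    chains[[length(chains) + 1L]] <- ch
  }
  chains[order(-vapply(chains, `[[`, numeric(1L), "score"))]
}

# Best single chain over the given (sorted) anchors; both orientations.
# Ties broken toward ascending orientation, then smallest terminal index
# (leftmost on genome A).
best_chain_path <- function(a, params) {
  if (!nrow(a)) return(NULL)
  res <- NULL
  for (orient in c("ascending", "descending")) {
    dp <- .chain_dp(as.integer(a$rank_a), as.integer(a$rank_b),
                    as.numeric(a$mid_a), as.numeric(a$mid_b),
                    as.numeric(a$score_capped),
                    params$D, params$g, orient == "descending")
    i <- which.max(dp$score)
    sc <- dp$score[i]
    if (is.null(res) || sc > res$score) {
      path <- integer()
      j <- i
      while (j > 0L) {
        path <- c(j, path)
        j <- dp$prev[j] + 1L  # C++ 0-based -> R 1-based; -1 -> 0 terminates
      }
      res <- list(score = sc, path = path, orientation = orient)
    }
  }
  res
}

#' @export
print.synteny_chain <- function(x, ...) {
  cat(sprintf("<synteny_chain> %s~%s %s: %d anchors, score %.2f\n",
              x$chrom_a, x$chrom_b, x$orientation, nrow(x$anchors), x$score))
  invisible(x)
}

#' Call syntelog pairs from accepted chains
#'
#' Takes the union of anchors over accepted chains of one genome pair and
#' enforces one-to-one pairing: a gene claimed by two chains is assigned to
#' the higher-scoring chain.
#'
#' @param chains List of `synteny_chain` objects for one genome pair (may
#'   span several chromosome pairs).
#' @param genome_a,genome_b Genome ids recorded on the result.
#' @return A `syntelog_pairs` object: data.frame with columns `gene_a`,
#'   `gene_b` and attributes `genome_a`, `genome_b`.
#' @export
call_syntelogs <- function(chains, genome_a = NA_character_,
                           genome_b = NA_character_) {
  used_a <- new.env(parent = emptyenv())
  used_b <- new.env(parent = emptyenv())
  ord <- order(-vapply(chains, `[[`, numeric(1L), "score"))
  ga <- character(); gb <- character()
  for (ch in chains[ord]) {
    for (k in seq_len(nrow(ch$anchors))) {
      a <- ch$anchors$gene_a[k]; b <- ch$anchors$gene_b[k]
      if (is.null(used_a[[a]]) && is.null(used_b[[b]])) {
        used_a[[a]] <- TRUE; used_b[[b]] <- TRUE
        ga <- c(ga, a); gb <- c(gb, b)
      }
    }
  }
  pairs <- data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
  attr(pairs, "genome_a") <- genome_a
  attr(pairs, "genome_b") <- genome_b
  class(pairs) <- c("syntelog_pairs", class(pairs))
  pairs
}

#' Synteny kinship of a genome pair
#'
#' The proportion of the reference genome's annotated genes that participate
#' in a syntelog pair.
#'
#' @param pairs A `syntelog_pairs` object with the reference as genome A.
#' @param ref_annotation The reference [genome_annotation()].
#' @return A number in `[0, 1]`.
#' @export
synteny_kinship <- function(pairs, ref_annotation) {
  n_ref <- nrow(ref_annotation$genes)
  if (!n_ref) stop("reference annotation has no genes")
  length(unique(intersect(pairs$gene_a, ref_annotation$genes$gene_id))) / n_ref
}

#' Pairwise syntelogs for one genome pair
#'
#' Convenience wrapper running the full per-pair pipeline: best hits,
#' anchors, chaining per chromosome pair, and one-to-one syntelog calling.
#'
#' @param ann_a,ann_b [genome_annotation()]s (tandem-collapsed if desired).
#' @param hits Hit table with queries in `ann_a`.
#' @param params A [chain_params()].
#' @param mode Best-hit mode, see [best_hits()].
#' @return A `syntelog_pairs` object.
#' @export
pair_syntelogs <- function(ann_a, ann_b, hits, params = chain_params(),
                           mode = "per_query") {
  anchors <- make_anchors(ann_a, ann_b, best_hits(hits, mode), Z = params$Z)
  chains <- list()
  if (nrow(anchors)) {
    key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
    for (grp in split(anchors, key)) {
      chains <- c(chains, chain_anchors(grp, params))
    }
  }
  call_syntelogs(chains, ann_a$genome_id, ann_b$genome_id)
}
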