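# From raw similarity hits to clean anchor pairs: best-hit filtering and
# collapsing of individual-specific tandem duplicates.

#' Filter a hit table to best hits
#'
#' `per_query` keeps, for each query gene, the hit(s) with maximal bitscore
#' (ties all kept). `reciprocal` additionally requires the pair to be best in
#' both directions, i.e. the hit must also carry the maximal bitscore among
#' all hits to its subject.
#'
#' @param hits data.frame from [read_hits()].
#' @param mode `"per_query"` or `"reciprocal"`.
#' @return Filtered data.frame of hits.
#' @export
best_hits <- function(hits, mode = c("per_query", "reciprocal")) {
  mode <- match.arg(mode)
  if (!nrow(hits)) return(hits)
  qmax <- tapply(hits$bitscore, hits$query, max)
  keep <- hits$bitscore >= qmax[hits$query]
  if (mode == "reciprocal") {
    smax <- tapply(hits$bitscore, hits$subject, max)
    keep <- keep & hits$bitscore >= smax[hits$subject]
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse individual-specific tandem duplicates
#'
#' Runs of same-chromosome genes lying within `max_tandem_gap` ranks of each
#' other and sharing the same best-hit subject in the partner genome are
#' replaced by a single representative: the member with the highest best-hit
#' bitscore (ties broken by smallest rank). Ranks are recomputed on the
#' collapsed annotation. Genes without a best hit are never collapsed.
#'
#' @param annotation A [genome_annotation()].
#' @param best Best-hit table for this genome's genes as queries (see
#'   [best_hits()]).
#' @param max_tandem_gap Maximum rank gap (in genes) between consecutive
#'   members of a tandem run.
#' @return List with `annotation` (collapsed, ranks recomputed) and
#'   `clusters`, a data.frame with one row per multi-member tandem cluster
#'   (`genome_id`, `chrom`, `representative`, and `members` as a
#'   comma-joined string).
#' @export
collapse_tandem <- function(annotation, best, max_tandem_gap = 1L) {
  g <- annotation$genes
  if (!nrow(g) || !nrow(best)) {
    return(list(annotation = annotation,
                clusters = empty_tandem_clusters()))
  }
  # deterministic single best subject per query: max bitscore, then
  # lexicographically smallest subject
  o <- order(best$query, -best$bitscore, best$subject)
  b1 <- best[o, , drop = FALSE]
  b1 <- b1[!duplicated(b1$query), , drop = FALSE]
  subj <- stats::setNames(b1$subject, b1$query)
  bits <- stats::setNames(b1$bitscore, b1$query)

  g <- g[order(g$chrom, g$rank), , drop = FALSE]
  g$subject <- unname(subj[g$gene_id])
  n <- nrow(g)
  # new run when chrom changes, subject missing/differs, or rank gap exceeded
  new_run <- rep(TRUE, n)
  if (n > 1L) {
    same <- g$chrom[-1L] == g$chrom[-n] &
      !is.na(g$subject[-1L]) & !is.na(g$subject[-n]) &
      g$subject[-1L] == g$subject[-n] &
      (g$rank[-1L] - g$rank[-n]) <= max_tandem_gap + 0L
    new_run[-1L] <- !same
  }
  run <- cumsum(new_run)
  sizes <- tabulate(run)
  rep_of <- character(max(run))
  for (r in which(sizes > 1L)) {
    members <- g$gene_id[run == r]
    mb <- bits[members]
    best_m <- members[order(-mb, match(members, g$gene_id))][1L]
    rep_of[r] <- best_m
  }
  drop <- sizes[run] > 1L & g$gene_id != rep_of[run]
  kept <- g[!drop, c("gene_id", "chrom", "start", "end", "strand")]
  clusters <- if (any(sizes > 1L)) {
    data.frame(
      genome_id = annotation$genome_id,
      chrom = vapply(which(sizes > 1L), function(r) g$chrom[run == r][1L], ""),
      representative = rep_of[sizes > 1L],
      members = vapply(which(sizes > 1L),
                       function(r) paste(g$gene_id[run == r], collapse = ","),
                       ""),
      stringsAsFactors = FALSE)
  } else {
    empty_tandem_clusters()
  }
  list(annotation = genome_annotation(annotation$genome_id, kept,
                                      annotation$proteins),
       clusters = clusters)
}

empty_tandem_clusters <- function() {
  data.frame(genome_id = character(), chrom = character(),
             representative = character(), members = character(),
             stringsAsFactors = FALSE)
}

#' Build anchor pairs from best hits and two annotations
#'
#' Joins a best-hit table to gene ranks and base-pair midpoints in both
#' genomes. The anchor match score is bitscore-derived and saturates at the
#' chaining cap `Z` for a (near-)self hit: `score = Z * bitscore /
#' (2 * align_len)`, since a full-length identical protein alignment has a
#' bitscore of about twice its length.
#'
#' @param ann_a,ann_b [genome_annotation()]s for the query and subject
#'   genomes.
#' @param best Best-hit table with queries in `ann_a`, subjects in `ann_b`;
#'   hits whose genes are missing from either annotation are dropped.
#' @param Z Score cap used for saturation scaling (see [chain_params()]).
#' @return data.frame of anchors: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `mid_a`, `mid_b`, `score`.
#' @export
make_anchors <- function(ann_a, ann_b, best, Z = 12) {
  ga <- ann_a$genes
  gb <- ann_b$genes
  ia <- match(best$query, ga$gene_id)
  ib <- match(best$subject, gb$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]; b <- best[keep, , drop = FALSE]
  anchors <- data.frame(
    gene_a = ga$gene_id[ia], gene_b = gb$gene_id[ib],
    chrom_a = ga$chrom[ia], chrom_b = gb$chrom[ib],
    rank_a = ga$rank[ia], rank_b = gb$rank[ib],
    mid_a = (ga$start[ia] + ga$end[ia]) / 2,
    mid_b = (gb$start[ib] + gb$end[ib]) / 2,
    score = Z * b$bitscore / (2 * pmax(b$length, 1L)),
    stringsAsFactors = FALSE)
  # one anchor per retained (gene_a, gene_b)
  key <- paste(anchors$gene_a, anchors$gene_b, sep = "\r")
  o <- order(key, -anchors$score)
  anchors <- anchors[o, , drop = FALSE]
  anchors <- anchors[!duplicated(key[o]), , drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}
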