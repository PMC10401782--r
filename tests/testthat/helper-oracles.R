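# Independent oracles and small fixture builders shared across tests.

# Exhaustive best chain score: maximum over every non-empty anchor subset
# that forms a strictly monotone (ascending or descending in rank_b),
# D-feasible sequence; score = sum of capped match scores minus gap
# penalties. Brute force, for instances with <= ~12 anchors.
exhaustive_chain_score <- function(anchors, params) {
  n <- nrow(anchors)
  s <- pmin(anchors$score, params$Z)
  best <- -Inf
  for (bits in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L)
    a <- anchors[idx, , drop = FALSE]
    o <- order(a$rank_a)
    a <- a[o, , drop = FALSE]
    if (anyDuplicated(a$rank_a)) next
    db <- diff(a$rank_b)
    if (length(db) && !(all(db > 0) || all(db < 0))) next
    if (length(db)) {
      if (any(abs(diff(a$mid_a)) > params$D)) next
      if (any(abs(diff(a$mid_b)) > params$D)) next
    }
    pen <- if (length(db)) {
      params$g * sum((diff(a$rank_a) - 1L) + (abs(db) - 1L))
    } else 0
    sc <- sum(pmin(a$score, params$Z)) - pen
    if (sc > best) best <- sc
  }
  best
}

random_anchor_instance <- function(n, span = 1e6) {
  data.frame(
    gene_a = paste0("a", seq_len(n)), gene_b = paste0("b", seq_len(n)),
    chrom_a = "c1", chrom_b = "c1",
    rank_a = sample.int(3L * n, n), rank_b = sample.int(3L * n, n),
    mid_a = runif(n, 0, span), mid_b = runif(n, 0, span),
    score = runif(n, 1, 30), stringsAsFactors = FALSE)
}

# Pairwise-enumeration HDG oracle: mean over all cross-population pairs of
# the indicator that two genomes carry different keys.
brute_hdg <- function(keys_a, keys_b) {
  if (!length(keys_a) || !length(keys_b)) return(NA_real_)
  mean(outer(keys_a, keys_b, `!=`))
}

random_catalog <- function(n_a, n_b, n_keys = 4L, sg_id = "SGx") {
  genomes <- c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b)))
  seqs <- vapply(seq_len(n_keys),
                 function(i) paste(sample(LETTERS[1:20], 20, TRUE),
                                   collapse = ""),
                 character(1L))
  keys <- sample.int(n_keys, n_a + n_b, replace = TRUE)
  structure(list(sg_id = sg_id,
                 keys = stats::setNames(keys, genomes), seqs = seqs),
            class = "haplotype_catalog")
}

# Exact window P by complete enumeration of all C(n, k) placements of the
# low SGs: per window, the fraction of placements whose in-window count
# strictly exceeds the observed count.
exact_window_p <- function(n, low_idx, window = 10L, step = 1L) {
  k <- length(low_idx)
  ws <- if (n <= window) 1L else seq.int(1L, n - window + 1L, by = step)
  we <- pmin(ws + window - 1L, n)
  obs <- vapply(seq_along(ws),
                function(w) sum(low_idx >= ws[w] & low_idx <= we[w]),
                integer(1L))
  combos <- utils::combn(n, k)
  vapply(seq_along(ws), function(w) {
    cnt <- colSums(combos >= ws[w] & combos <= we[w])
    mean(cnt > obs[w])
  }, numeric(1L))
}

# Minimal two-genome toy annotations with collinear genes, for io and
# chaining tests.
toy_annotation <- function(genome_id, n = 6L, chrom = "chr1",
                           spacing = 1000L, prefix = genome_id) {
  start <- seq(0L, by = spacing, length.out = n)
  genome_annotation(
    genome_id,
    data.frame(gene_id = sprintf("%s_g%02d", prefix, seq_len(n)),
               chrom = chrom, start = start, end = start + 300L,
               strand = "+", stringsAsFactors = FALSE))
}

hit_row <- function(q, s, bitscore, len = 100L, pident = 99) {
  data.frame(query = q, subject = s, pident = pident, length = len,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = 1e-50, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

small_planted_panel <- function(seed = 42L) {
  simulate_panel(sim_config(
    groups = c(GJ = 6L, XI = 6L), n_sgs = 120L, n_chrom = 2L,
    mixture = c(core = 0.8, soft_core = 0.2, dispensable = 0, private = 0),
    mutation_rate = 0, tandem_prob = 0.05,
    planted_blocks = data.frame(sg_start = 10L, sg_end = 40L,
                                donor = "GJ"),
    seed = seed))
}
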