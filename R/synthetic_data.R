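# Synthetic multi-genome panels with full ground truth: occupancy spectrum,
# per-population haplotype structure, tandem duplicates, planted low-HDG
# introgression blocks, and fabricated all-vs-all hit tables.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a large rice panel: the SG
#' occupancy mixture follows the published pan-genome class proportions
#' (7.9% core, 8.2% soft-core, 35.6% dispensable, 48.3% private), each
#' population carries its own dominant haplotype allele at frequency 0.9
#' (expected background HDG between two populations: 0.82), and genes are
#' spaced by a geometric distribution so the 200 kb chaining distance cap is
#' exercised.
#'
#' @param groups Named integer vector: genomes per population label.
#' @param n_sgs Number of syntelog groups.
#' @param n_chrom Number of chromosomes (SG indices split contiguously).
#' @param mixture Occupancy class proportions, in order core, soft_core,
#'   dispensable, private; must sum to 1.
#' @param dominant_freq Within-population frequency of the population's own
#'   dominant haplotype allele.
#' @param mutation_rate Per-lineage protein substitution rate
#'   (substitutions/site); adds rare private haplotypes on top of the
#'   population alleles.
#' @param tandem_prob Probability that a present gene copy gains an
#'   adjacent tandem duplicate in that genome.
#' @param mean_spacing Mean intergenic spacing in bp (geometric).
#' @param protein_len Length range (aa) of ancestral proteins.
#' @param planted_blocks Optional data.frame with columns `sg_start`,
#'   `sg_end` (global SG index range, inclusive, one chromosome each) and
#'   `donor` (population label): inside a planted block every population
#'   draws its haplotype from the donor population's allele frequencies,
#'   forcing low cross-population HDG.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(groups = c(GJ = 8L, XI = 8L),
                       n_sgs = 1000L,
                       n_chrom = 2L,
                       mixture = c(core = 0.079, soft_core = 0.082,
                                   dispensable = 0.356, private = 0.483),
                       dominant_freq = 0.9,
                       mutation_rate = 0.001,
                       tandem_prob = 0.02,
                       mean_spacing = 5000,
                       protein_len = c(100L, 500L),
                       planted_blocks = NULL,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(groups) >= 1L, all(groups >= 1L),
            abs(sum(mixture) - 1) < 1e-8, n_sgs >= 1L, n_chrom >= 1L,
            dominant_freq > 0, dominant_freq <= 1,
            mutation_rate >= 0, tandem_prob >= 0, tandem_prob <= 1)
  if (!is.null(planted_blocks)) {
    pb <- planted_blocks
    stopifnot(all(c("sg_start", "sg_end", "donor") %in% names(pb)))
    if (any(pb$sg_start > pb$sg_end) || any(pb$sg_end > n_sgs) ||
        any(pb$sg_start < 1L)) {
      stop("planted block range outside 1..n_sgs")
    }
    o <- order(pb$sg_start)
    if (nrow(pb) > 1L && any(pb$sg_start[o][-1L] <= pb$sg_end[o][-nrow(pb)])) {
      stop("planted block ranges overlap")
    }
    if (!all(pb$donor %in% names(groups))) stop("unknown donor population")
  }
  structure(list(groups = groups, n_sgs = as.integer(n_sgs),
                 n_chrom = as.integer(n_chrom), mixture = mixture,
                 dominant_freq = dominant_freq,
                 mutation_rate = mutation_rate, tandem_prob = tandem_prob,
                 mean_spacing = mean_spacing,
                 protein_len = as.integer(protein_len),
                 planted_blocks = planted_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

random_protein <- function(len) paste(sample(AA, len, replace = TRUE),
                                      collapse = "")

substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(AA, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a multi-genome panel with ground truth
#'
#' Generates an ancestral proteome (random sequences), draws per-SG
#' occupancy from the configured mixture, assigns per-population haplotype
#' alleles (allele k differs from the ancestral sequence at position k, so
#' alleles are distinct strings), applies per-lineage substitutions,
#' inserts tandem duplicates, and lays out gene coordinates with geometric
#' spacing. Inside planted blocks all populations draw from the donor
#' population's allele frequencies. The first genome of the first group is
#' the intended framework genome and always carries every core SG.
#'
#' @param config A [sim_config()].
#' @return List with `annotations` (named list of [genome_annotation()]s,
#'   proteins included), `groups` (a `group_config`), `truth` (list with
#'   `genes`, `sgs`, `planted`), and `config`.
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  labels <- names(config$groups)
  genome_ids <- unlist(lapply(labels, function(l) {
    sprintf("%s_%02d", l, seq_len(config$groups[[l]]))
  }))
  pop_of <- stats::setNames(
    rep(labels, times = config$groups), genome_ids)
  n_gen <- length(genome_ids)
  framework <- genome_ids[1L]
  n_pop <- length(labels)
  n_alleles <- max(n_pop, 2L)

  # SG layout: contiguous chromosome ranges
  chrom_of <- paste0("chr", ceiling(seq_len(config$n_sgs) *
                                      config$n_chrom / config$n_sgs))

  # occupancy classes
  cls <- sample(names(config$mixture), config$n_sgs, replace = TRUE,
                prob = config$mixture)
  soft_lo <- min(ceiling(0.9 * n_gen), n_gen - 1L)
  occ <- integer(config$n_sgs)
  for (i in seq_len(config$n_sgs)) {
    occ[i] <- switch(cls[i],
      core = n_gen,
      soft_core = if (soft_lo >= n_gen - 1L) n_gen - 1L else
        sample(soft_lo:(n_gen - 1L), 1L),
      dispensable = if (soft_lo - 1L <= 2L) 2L else
        sample(2L:(soft_lo - 1L), 1L),
      private = 1L)
  }

  # allele frequency matrix per population (rows: population, cols: allele)
  freq_of_pop <- function(p) {
    f <- rep((1 - config$dominant_freq) / (n_alleles - 1L), n_alleles)
    f[match(p, labels)] <- config$dominant_freq
    f / sum(f)
  }
  freqs <- do.call(rbind, lapply(labels, freq_of_pop))
  rownames(freqs) <- labels

  # planted blocks: effective per-SG frequency source
  src_pop <- stats::setNames(rep(NA_character_, config$n_sgs), NULL)
  pb <- config$planted_blocks
  if (!is.null(pb)) {
    for (i in seq_len(nrow(pb))) {
      rng <- pb$sg_start[i]:pb$sg_end[i]
      if (length(unique(chrom_of[rng])) > 1L) {
        stop("planted block ", i, " spans a chromosome boundary")
      }
      src_pop[rng] <- pb$donor[i]
    }
  }

  genes_per_genome <- stats::setNames(
    rep(list(NULL), n_gen), genome_ids)
  truth_rows <- vector("list", config$n_sgs)
  exp_hdg <- rep(NA_real_, config$n_sgs)

  for (s in seq_len(config$n_sgs)) {
    len <- sample(config$protein_len[1L]:config$protein_len[2L], 1L)
    anc <- random_protein(len)
    alleles <- c(anc, vapply(seq_len(n_alleles - 1L), function(j) {
      substitute_at(anc, j)
    }, character(1L)))
    present <- if (occ[s] == n_gen) genome_ids else
      sample(genome_ids, occ[s])
    eff_pop <- function(g) if (!is.na(src_pop[s])) src_pop[s] else pop_of[[g]]
    allele_idx <- vapply(present, function(g) {
      sample.int(n_alleles, 1L, prob = freqs[eff_pop(g), ])
    }, integer(1L))
    n_mut <- rpois(length(present), nchar(anc) * config$mutation_rate)
    prot <- vapply(seq_along(present), function(i) {
      p <- alleles[allele_idx[i]]
      if (n_mut[i] > 0L) substitute_at(p, sample.int(nchar(p), n_mut[i]))
      else p
    }, character(1L))
    tand <- runif(length(present)) < config$tandem_prob
    truth_rows[[s]] <- data.frame(
      genome_id = present, sg = s, allele = unname(allele_idx),
      n_mut = n_mut, tandem = tand, protein = prot,
      stringsAsFactors = FALSE)
    if (n_pop >= 2L) {
      fa <- freqs[if (!is.na(src_pop[s])) src_pop[s] else labels[1L], ]
      fb <- freqs[if (!is.na(src_pop[s])) src_pop[s] else labels[2L], ]
      exp_hdg[s] <- 1 - sum(fa * fb)
    }
  }

  truth_genes <- do.call(rbind, truth_rows)
  truth_genes$gene_id <- sprintf("%s_g%05d", truth_genes$genome_id,
                                 truth_genes$sg)

  # per-genome layout and annotation assembly (tandem copy sits directly
  # after its parent; coordinates accumulate gap + gene length per chrom)
  annotations <- stats::setNames(vector("list", n_gen), genome_ids)
  all_rows <- list()
  for (g in genome_ids) {
    tg <- truth_genes[truth_genes$genome_id == g, , drop = FALSE]
    tg <- tg[order(tg$sg), , drop = FALSE]
    idx <- rep(seq_len(nrow(tg)), times = 1L + tg$tandem)
    dup <- duplicated(idx)
    gdf <- data.frame(
      gene_id = ifelse(dup, paste0(tg$gene_id[idx], "d"), tg$gene_id[idx]),
      chrom = chrom_of[tg$sg[idx]],
      sg = tg$sg[idx], tandem = dup, protein = tg$protein[idx],
      allele = tg$allele[idx], n_mut = tg$n_mut[idx], genome_id = g,
      stringsAsFactors = FALSE)
    glen <- 3L * nchar(gdf$protein)
    gap <- rgeom(nrow(gdf), 1 / config$mean_spacing) + 1
    gdf$strand <- sample(c("+", "-"), nrow(gdf), replace = TRUE)
    gdf$end <- stats::ave(gap + glen, gdf$chrom, FUN = cumsum)
    gdf$start <- gdf$end - glen
    all_rows[[g]] <- gdf
    annotations[[g]] <- genome_annotation(
      g, gdf[, c("gene_id", "chrom", "start", "end", "strand")],
      stats::setNames(gdf$protein, gdf$gene_id))
  }
  truth <- list(
    genes = do.call(rbind, all_rows)[, c("genome_id", "gene_id", "sg",
                                         "tandem", "allele", "n_mut")],
    sgs = data.frame(sg = seq_len(config$n_sgs), chrom = chrom_of,
                     class = cls, occupancy = occ,
                     planted = !is.na(src_pop),
                     expected_hdg = exp_hdg, stringsAsFactors = FALSE),
    planted = pb)
  rownames(truth$genes) <- NULL
  groups <- group_config(pop_of, priority = labels)
  list(annotations = annotations, groups = groups, truth = truth,
       config = config, framework = framework)
}

#' Fabricate all-vs-all hit tables from a simulated panel
#'
#' Stands in for an all-vs-all protein aligner. For every ordered genome
#' pair, each gene emits hits to every member (including tandem copies) of
#' its true SG in the subject genome, with bitscore decreasing in the
#' number of substitutions separating the two proteins
#' (`max(2 * len - 4 * d, 30)`). True hits are dropped at `fn_rate`,
#' spurious random hits added at `fp_rate` (per true hit), and cross-SG
#' paralog hits at `paralog_rate` (per gene, at ~60% of the true score).
#'
#' @param panel Result of [simulate_panel()].
#' @param fp_rate,fn_rate,paralog_rate Noise rates in `[0, 1]`.
#' @param seed Optional RNG seed (defaults to `config$seed + 1`).
#' @return Named list of hit data.frames, element `"A|B"` holding hits with
#'   queries in genome A and subjects in genome B.
#' @export
simulate_hits <- function(panel, fp_rate = 0, fn_rate = 0,
                          paralog_rate = 0, seed = NULL) {
  if (any(c(fp_rate, fn_rate, paralog_rate) < 0) ||
      any(c(fp_rate, fn_rate, paralog_rate) > 1)) {
    stop("noise rates must lie in [0, 1]")
  }
  set.seed(if (is.null(seed)) panel$config$seed + 1L else seed)
  tg <- panel$truth$genes
  tg$len <- NA_integer_
  for (g in names(panel$annotations)) {
    idx <- tg$genome_id == g
    tg$len[idx] <- unname(nchar(panel$annotations[[g]]$proteins)[
      tg$gene_id[idx]])
  }
  by_genome <- split(tg, tg$genome_id)
  genomes <- names(panel$annotations)
  out <- list()
  for (a in genomes) for (b in genomes) {
    if (a == b) next
    qa <- by_genome[[a]]
    sb <- by_genome[[b]]
    j <- merge(qa[, c("sg", "gene_id", "allele", "n_mut", "len")],
               sb[, c("sg", "gene_id", "allele", "n_mut")],
               by = "sg", suffixes = c("_q", "_s"))
    if (!nrow(j)) {
      out[[paste(a, b, sep = "|")]] <- empty_hits()
      next
    }
    # population alleles differ at <= 2 sites by construction; lineage
    # substitutions add on top -- enough for a divergence-monotone bitscore
    d <- (j$allele_q != j$allele_s) * 2 + j$n_mut_q + j$n_mut_s
    len <- j$len
    bits <- pmax(2 * len - 4 * d, 30)
    h <- data.frame(query = j$gene_id_q, subject = j$gene_id_s,
                    pident = round(100 * pmax(1 - d / len, 0), 2),
                    length = as.integer(len), mismatch = as.integer(d),
                    gapopen = 0L, qstart = 1L, qend = as.integer(len),
                    sstart = 1L, send = as.integer(len),
                    evalue = 10^(-pmin(bits / 2, 180)),
                    bitscore = bits,
                    stringsAsFactors = FALSE)
    if (fn_rate > 0) h <- h[runif(nrow(h)) >= fn_rate, , drop = FALSE]
    if (paralog_rate > 0 && nrow(sb) > 1L) {
      pq <- qa[runif(nrow(qa)) < paralog_rate, , drop = FALSE]
      if (nrow(pq)) {
        pj <- vapply(pq$sg, function(s) {
          cand <- which(sb$sg != s)
          if (length(cand)) sample(cand, 1L) else NA_integer_
        }, integer(1L))
        ok <- !is.na(pj)
        if (any(ok)) {
          plen <- pq$len[ok]
          h <- rbind(h, data.frame(
            query = pq$gene_id[ok], subject = sb$gene_id[pj[ok]],
            pident = 60, length = as.integer(plen), mismatch = 0L,
            gapopen = 0L, qstart = 1L, qend = as.integer(plen),
            sstart = 1L, send = as.integer(plen), evalue = 1e-20,
            bitscore = round(0.6 * pmax(2 * plen, 30)),
            stringsAsFactors = FALSE))
        }
      }
    }
    if (fp_rate > 0) {
      n_fp <- rbinom(1L, nrow(h), fp_rate)
      if (n_fp > 0L) {
        qi <- sample.int(nrow(qa), n_fp, replace = TRUE)
        si <- sample.int(nrow(sb), n_fp, replace = TRUE)
        flen <- qa$len[qi]
        h <- rbind(h, data.frame(
          query = qa$gene_id[qi], subject = sb$gene_id[si], pident = 40,
          length = as.integer(flen), mismatch = 0L, gapopen = 0L,
          qstart = 1L, qend = as.integer(flen), sstart = 1L,
          send = as.integer(flen), evalue = 1e-6,
          bitscore = round(runif(n_fp, 40, 70)),
          stringsAsFactors = FALSE))
      }
    }
    rownames(h) <- NULL
    out[[paste(a, b, sep = "|")]] <- h
  }
  out
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a simulated panel to disk
#'
#' One GFF3 and one protein FASTA per genome, a `groups.tsv` configuration,
#' truth tables as TSV, and (optionally) per-pair hit tables under `hits/`.
#'
#' @param panel Result of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @param hits Optional result of [simulate_hits()].
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir, hits = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(panel$annotations)) {
    ann <- panel$annotations[[g]]
    write_gff3(ann, file.path(dir, paste0(g, ".gff3")))
    write_protein_fasta(ann$proteins, file.path(dir, paste0(g, ".faa")))
  }
  write_group_config(panel$groups, file.path(dir, "groups.tsv"))
  utils::write.table(panel$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth$sgs, file.path(dir, "truth_sgs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hits)) {
    hd <- file.path(dir, "hits")
    dir.create(hd, showWarnings = FALSE)
    for (k in names(hits)) {
      write_hits(hits[[k]],
                 file.path(hd, paste0(sub("\\|", "__", k), ".tsv")))
    }
  }
  invisible(dir)
}

#' Compare a pipeline SG partition against simulation truth
#'
#' Tandem-collapsed genes are mapped to their cluster representative's SG
#' before comparison. The partitions are identical when the mapping between
#' truth SGs and pipeline SGs is one-to-one and covers every gene.
#'
#' @param pan A `pan_genome` from the pipeline.
#' @param clusters Tandem cluster table (see [collapse_tandem()];
#'   concatenated over genomes), or `NULL`.
#' @param truth The `truth` element of [simulate_panel()].
#' @return List with `identical` (logical), `n_truth_sgs`, `n_pipeline_sgs`
#'   and `n_mismatched_genes`.
#' @export
partition_vs_truth <- function(pan, clusters, truth) {
  sg_of_gene <- stats::setNames(pan$members$sg_id, pan$members$gene_id)
  if (!is.null(clusters) && nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      mem <- strsplit(clusters$members[i], ",", fixed = TRUE)[[1]]
      sg_of_gene[mem] <- sg_of_gene[[clusters$representative[i]]]
    }
  }
  tg <- truth$genes
  pipe <- unname(sg_of_gene[tg$gene_id])
  missing <- is.na(pipe)
  key <- paste(tg$sg, pipe, sep = "\r")
  agree <- !missing
  # one-to-one: every truth SG maps to one pipeline SG and vice versa
  map_t <- tapply(pipe[!missing], tg$sg[!missing],
                  function(x) length(unique(x)))
  map_p <- tapply(tg$sg[!missing], pipe[!missing],
                  function(x) length(unique(x)))
  identical <- !any(missing) && all(map_t == 1L) && all(map_p == 1L)
  # mismatched genes: genes whose (truth SG -> majority pipeline SG) vote
  # they disagree with
  n_mis <- sum(missing)
  if (any(!missing)) {
    maj <- tapply(pipe[!missing], tg$sg[!missing], function(x) {
      names(sort(table(x), decreasing = TRUE))[1L]
    })
    n_mis <- n_mis + sum(pipe[!missing] != maj[as.character(tg$sg[!missing])])
  }
  list(identical = identical,
       n_truth_sgs = length(unique(tg$sg)),
       n_pipeline_sgs = nrow(pan$sgs),
       n_mismatched_genes = as.integer(n_mis))
}
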