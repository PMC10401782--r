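# Iterative merge of pairwise syntelog sets into a pan-genome of syntelog
# groups (SGs) anchored to a framework genome; occupancy classification and
# composition analyses.

new_pan_genome <- function(sgs, members, genomes, framework_id) {
  structure(list(sgs = sgs, members = members, genomes = genomes,
                 n_genomes = length(genomes), framework_id = framework_id),
            class = "pan_genome")
}

#' @export
print.pan_genome <- function(x, ...) {
  cat(sprintf(
    "<pan_genome> %d SGs over %d genomes (framework: %s); %d clustered genes\n",
    nrow(x$sgs), x$n_genomes, x$framework_id, nrow(x$members)))
  invisible(x)
}

#' Merge pairwise syntelog sets into a pan-genome
#'
#' Starting from the framework genome (every framework gene seeds an SG in
#' coordinate order), genomes are added one by one. Each gene of the new
#' genome that links -- via any pairwise syntelog pair with an
#' already-merged genome -- to genes of exactly one existing SG joins that
#' SG; a gene linking to two or more SGs is resolved by majority link count
#' (ties to the earliest-created SG); an unlinked gene founds a new SG.
#' SGs are never retroactively fused, and an SG takes at most one member
#' per genome (a second candidate from the same genome falls through to its
#' next-best SG or founds a new one).
#'
#' @param annotations Named list of [genome_annotation()]s (tandem-collapsed
#'   representatives), covering every genome in `order`.
#' @param pair_sets Named list of `syntelog_pairs`; element `"A|B"` holds
#'   pairs with `gene_a` from genome A and `gene_b` from genome B. Either
#'   orientation of a genome pair may be supplied.
#' @param order Character vector of genome ids, framework first; merge order.
#' @return A `pan_genome` object: `sgs` (one row per SG with `sg_id`,
#'   framework `chrom`/`start`/`end`/`rank` where anchored, `occupancy`),
#'   `members` (long data.frame `sg_id`, `genome_id`, `gene_id`), `genomes`,
#'   `framework_id`. SGs are ordered by framework coordinates, with
#'   framework-absent SGs appended ordered by their earliest-merged member's
#'   coordinates.
#' @export
merge_pairwise <- function(annotations, pair_sets, order = names(annotations)) {
  stopifnot(length(order) >= 1L, all(order %in% names(annotations)))
  framework <- order[1L]

  # pair lookup oriented as (earlier genome -> later genome)
  get_pairs <- function(a, b) {
    k1 <- paste(a, b, sep = "|"); k2 <- paste(b, a, sep = "|")
    if (!is.null(pair_sets[[k1]])) return(pair_sets[[k1]])
    p <- pair_sets[[k2]]
    if (is.null(p)) return(NULL)
    data.frame(gene_a = p$gene_b, gene_b = p$gene_a, stringsAsFactors = FALSE)
  }

  sg_of <- list()       # per genome: named int vector gene -> sg index
  sg_genomes <- list()  # per sg: named chr vector genome -> gene
  n_sg <- 0L

  add_sg <- function(genome, gene) {
    n_sg <<- n_sg + 1L
    sg_genomes[[n_sg]] <<- stats::setNames(gene, genome)
    n_sg
  }

  fg <- annotations[[framework]]$genes
  sg_of[[framework]] <- stats::setNames(rep(NA_integer_, nrow(fg)),
                                        fg$gene_id)
  for (i in seq_len(nrow(fg))) {
    sg_of[[framework]][i] <- add_sg(framework, fg$gene_id[i])
  }

  for (gi in seq_along(order)[-1L]) {
    g <- order[gi]
    merged <- order[seq_len(gi - 1L)]
    genes_g <- annotations[[g]]$genes$gene_id
    # link counts: for each gene of g, SG indices reachable via pairs
    link_gene <- character(); link_sg <- integer()
    for (m in merged) {
      p <- get_pairs(m, g)
      if (is.null(p) || !nrow(p)) next
      sgm <- sg_of[[m]][p$gene_a]
      if (anyNA(sgm)) {
        stop("pair set ", m, "|", g, " references unknown gene in ", m)
      }
      ok <- p$gene_b %in% genes_g
      if (!all(ok)) {
        stop("pair set ", m, "|", g, " references unknown gene in ", g)
      }
      link_gene <- c(link_gene, p$gene_b)
      link_sg <- c(link_sg, unname(sgm))
    }
    links <- split(link_sg, link_gene)
    sg_of[[g]] <- stats::setNames(rep(NA_integer_, length(genes_g)), genes_g)
    taken <- new.env(parent = emptyenv())  # sg index -> TRUE once claimed
    for (gene in genes_g) {               # genome coordinate order
      cand <- links[[gene]]
      assigned <- NA_integer_
      if (!is.null(cand)) {
        tab <- sort(table(cand), decreasing = TRUE)
        # majority link count, tie -> earliest-created SG
        for (cnt in unique(as.integer(tab))) {
          ids <- sort(as.integer(names(tab)[as.integer(tab) == cnt]))
          for (sg in ids) {
            if (is.null(taken[[as.character(sg)]])) {
              assigned <- sg
              break
            }
          }
          if (!is.na(assigned)) break
        }
      }
      if (is.na(assigned)) assigned <- add_sg(g, gene)
      else sg_genomes[[assigned]] <- c(sg_genomes[[assigned]],
                                       stats::setNames(gene, g))
      taken[[as.character(assigned)]] <- TRUE
      sg_of[[g]][gene] <- assigned
    }
  }

  # ordering: framework-anchored SGs by framework coordinates, then the
  # rest by the coordinates of their earliest-merged member
  first_member_pos <- function(idx) {
    mem <- sg_genomes[[idx]]
    gnm <- names(mem)[which.min(match(names(mem), order))]
    ann <- annotations[[gnm]]$genes
    i <- match(mem[[gnm]], ann$gene_id)
    c(match(gnm, order), match(ann$chrom[i], unique(ann$chrom)), ann$start[i])
  }
  anchored <- vapply(seq_len(n_sg),
                     function(i) framework %in% names(sg_genomes[[i]]),
                     logical(1L))
  ford <- integer()
  if (any(anchored)) {
    fidx <- which(anchored)
    fi <- match(vapply(fidx, function(i) sg_genomes[[i]][[framework]], ""),
                fg$gene_id)
    ford <- fidx[order(fg$chrom[fi], fg$start[fi])]
  }
  rest <- which(!anchored)
  if (length(rest)) {
    pos <- t(vapply(rest, first_member_pos, numeric(3L)))
    rest <- rest[order(pos[, 1L], pos[, 2L], pos[, 3L])]
  }
  final <- c(ford, rest)
  sg_id <- sprintf("SG%06d", seq_along(final))

  fi <- match(vapply(final, function(i) {
    m <- sg_genomes[[i]]
    if (framework %in% names(m)) m[[framework]] else NA_character_
  }, ""), fg$gene_id)
  sgs <- data.frame(
    sg_id = sg_id,
    chrom = fg$chrom[fi], start = fg$start[fi], end = fg$end[fi],
    rank = fg$rank[fi],
    occupancy = vapply(final, function(i) length(sg_genomes[[i]]),
                       integer(1L)),
    created = final,  # original creation index (framework genes first)
    stringsAsFactors = FALSE)
  members <- do.call(rbind, lapply(seq_along(final), function(k) {
    m <- sg_genomes[[final[k]]]
    data.frame(sg_id = sg_id[k], genome_id = names(m), gene_id = unname(m),
               stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL
  new_pan_genome(sgs, members, genomes = order, framework_id = framework)
}

#' Presence table of a pan-genome
#'
#' @param pan A `pan_genome`.
#' @return data.frame, one row per SG (in pan order), one column per genome;
#'   cells hold the comma-joined member gene id(s) or `"."`.
#' @export
pan_presence_table <- function(pan) {
  out <- as.data.frame(
    matrix(".", nrow(pan$sgs), pan$n_genomes,
           dimnames = list(NULL, pan$genomes)),
    stringsAsFactors = FALSE, check.names = FALSE)
  m <- pan$members
  cell <- tapply(m$gene_id, list(m$sg_id, m$genome_id),
                 function(x) paste(sort(x), collapse = ","))
  ri <- match(rownames(cell), pan$sgs$sg_id)
  for (g in intersect(colnames(cell), pan$genomes)) {
    v <- cell[, g]
    ok <- !is.na(v)
    out[[g]][ri[ok]] <- v[ok]
  }
  out
}

#' Logical presence matrix (SG x genome)
#' @param pan A `pan_genome`.
#' @return Logical matrix with SG ids as rownames and genomes as columns.
#' @export
pan_presence_matrix <- function(pan) {
  m <- matrix(FALSE, nrow(pan$sgs), pan$n_genomes,
              dimnames = list(pan$sgs$sg_id, pan$genomes))
  m[cbind(match(pan$members$sg_id, pan$sgs$sg_id),
          match(pan$members$genome_id, pan$genomes))] <- TRUE
  m
}

#' Classify SG occupancy
#'
#' Core: present in all `n` genomes. Soft-core: present in at least
#' `ceil(soft_core_frac * n)` but fewer than `n`. Private: present in one
#' genome. Dispensable: everything between. At `n = 74` and the default 90%
#' rule this yields soft-core occupancies 67..73 and dispensable 2..66.
#'
#' @param pan A `pan_genome`, or an integer vector of occupancies (then `n`
#'   must be given).
#' @param soft_core_frac Soft-core lower-bound fraction.
#' @param n Number of genomes (taken from `pan` when omitted).
#' @return Factor of labels `core`, `soft-core`, `dispensable`, `private`,
#'   named by sg_id when `pan` is a `pan_genome`.
#' @export
classify_occupancy <- function(pan, soft_core_frac = 0.90, n = NULL) {
  if (inherits(pan, "pan_genome")) {
    occ <- stats::setNames(pan$sgs$occupancy, pan$sgs$sg_id)
    n <- pan$n_genomes
  } else {
    occ <- pan
    if (is.null(n)) stop("n must be given for a bare occupancy vector")
  }
  if (n < 2L) stop("occupancy classification needs n >= 2 genomes")
  soft_lo <- ceiling(soft_core_frac * n)
  lab <- ifelse(occ == n, "core",
         ifelse(occ >= soft_lo, "soft-core",
         ifelse(occ == 1L, "private", "dispensable")))
  factor(lab, levels = c("core", "soft-core", "dispensable", "private"))
}

#' Pan-genome composition within a sub-population
#'
#' Reclassifies every SG using occupancy restricted to the genomes of the
#' given group labels; SGs absent from the subset are counted separately.
#'
#' @param pan A `pan_genome`.
#' @param groups A `group_config`.
#' @param subset Character vector of group labels defining the
#'   sub-population.
#' @param soft_core_frac Soft-core fraction applied within the subset.
#' @return Named integer vector with counts for `core`, `soft-core`,
#'   `dispensable`, `private` and `absent`; sums to the number of SGs.
#' @export
subpopulation_composition <- function(pan, groups, subset,
                                      soft_core_frac = 0.90) {
  genomes <- intersect(group_members(groups, subset), pan$genomes)
  if (!length(genomes)) stop("empty sub-population subset")
  pm <- pan_presence_matrix(pan)[, genomes, drop = FALSE]
  occ <- rowSums(pm)
  present <- occ > 0
  lab <- classify_occupancy(occ[present], soft_core_frac, n = length(genomes))
  out <- c(table(lab), absent = sum(!present))
  storage.mode(out) <- "integer"
  out
}

#' Pan-genome growth curve
#'
#' For each of `n_orders` random genome orderings, the cumulative pan size
#' (union of SGs present so far) and core size (SGs present in every genome
#' so far) at each panel size k.
#'
#' @param pan A `pan_genome`.
#' @param n_orders Number of random orderings.
#' @param seed Optional RNG seed.
#' @return data.frame with columns `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`, plus attribute `"orders"` holding the per-order matrices.
#' @export
pan_growth_curve <- function(pan, n_orders = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_orders >= 1L)
  pm <- pan_presence_matrix(pan)
  n <- ncol(pm)
  pan_k <- matrix(0L, n_orders, n)
  core_k <- matrix(0L, n_orders, n)
  for (o in seq_len(n_orders)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, nrow(pm))
    allin <- rep(TRUE, nrow(pm))
    for (k in seq_len(n)) {
      col <- pm[, ord[k]]
      seen <- seen | col
      allin <- allin & col
      pan_k[o, k] <- sum(seen)
      core_k[o, k] <- sum(allin)
    }
  }
  out <- data.frame(
    k = seq_len(n),
    pan_mean = colMeans(pan_k), pan_sd = apply(pan_k, 2L, stats::sd),
    core_mean = colMeans(core_k), core_sd = apply(core_k, 2L, stats::sd))
  attr(out, "orders") <- list(pan = pan_k, core = core_k)
  out
}

#' SGs with presence-absence bias between two populations
#'
#' Presence frequency is the fraction of each group's genomes carrying the
#' SG; SGs with an absolute frequency difference of at least `min_diff`
#' (inclusive) are reported.
#'
#' @param pan A `pan_genome`.
#' @param groups A `group_config`.
#' @param gA,gB Group labels (each may be a vector of labels).
#' @param min_diff Inclusive threshold on `|freq_A - freq_B|`.
#' @return data.frame with `sg_id`, `freq_a`, `freq_b`, `diff`.
#' @export
pav_bias <- function(pan, groups, gA, gB, min_diff = 0.6) {
  ga <- intersect(group_members(groups, gA), pan$genomes)
  gb <- intersect(group_members(groups, gB), pan$genomes)
  if (!length(ga) || !length(gb)) stop("both groups must be non-empty")
  pm <- pan_presence_matrix(pan)
  fa <- rowMeans(pm[, ga, drop = FALSE])
  fb <- rowMeans(pm[, gb, drop = FALSE])
  d <- abs(fa - fb)
  keep <- d >= min_diff
  data.frame(sg_id = pan$sgs$sg_id[keep], freq_a = fa[keep],
             freq_b = fb[keep], diff = d[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
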