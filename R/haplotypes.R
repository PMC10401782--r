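# Per-SG haplotypes from protein sequences, ancestral haplotype labelling by
# group priority, and inter-population haplotype divergence (HDG).

#' Build the haplotype catalog of one SG
#'
#' A haplotype is a distinct predicted protein sequence among the SG's
#' members: two genomes share a raw haplotype key iff their member proteins
#' are identical strings (no similarity threshold). Keys are numbered by
#' descending frequency, ties by lexicographically smaller sequence.
#'
#' @param members Named character vector, genome_id -> member gene_id.
#' @param proteins Named list (by genome) of named character vectors
#'   (gene_id -> protein), or a single named character vector covering all
#'   member gene ids.
#' @param sg_id SG identifier recorded on the catalog.
#' @return A `haplotype_catalog`: list with `sg_id`, `keys` (named integer
#'   vector genome -> raw key) and `seqs` (character vector indexed by key).
#' @export
build_haplotypes <- function(members, proteins, sg_id = NA_character_) {
  if (is.list(proteins)) {
    seqs <- vapply(names(members), function(g) {
      s <- proteins[[g]][members[[g]]]
      if (is.null(s) || is.na(s)) NA_character_ else s
    }, character(1L))
  } else {
    seqs <- stats::setNames(unname(proteins[members]), names(members))
  }
  if (anyNA(seqs)) {
    stop("missing protein for present member(s): ",
         paste(names(seqs)[is.na(seqs)], collapse = ", "))
  }
  tab <- table(seqs)
  uniq <- names(tab)[order(-as.integer(tab), names(tab))]
  keys <- stats::setNames(match(seqs, uniq), names(members))
  structure(list(sg_id = sg_id, keys = keys, seqs = uniq),
            class = "haplotype_catalog")
}

#' Haplotype catalogs for every SG of a pan-genome
#'
#' @param pan A `pan_genome`.
#' @param annotations Named list of [genome_annotation()]s carrying the
#'   member protein sequences.
#' @return Named list (by sg_id, in pan order) of `haplotype_catalog`s.
#' @export
build_catalogs <- function(pan, annotations) {
  prot <- lapply(annotations, `[[`, "proteins")
  mem <- split(stats::setNames(pan$members$gene_id, pan$members$genome_id),
               pan$members$sg_id)
  mem <- mem[pan$sgs$sg_id]
  out <- lapply(pan$sgs$sg_id, function(id) {
    build_haplotypes(mem[[id]], prot, sg_id = id)
  })
  stats::setNames(out, pan$sgs$sg_id)
}

#' Assign ancestral haplotype labels by group priority
#'
#' Priority groups are visited in order; the k-th group can bind the k-th
#' label (hapI for the first, hapII for the second, up to hapV). Within a
#' group the most frequent raw key among its present members is the
#' dominant haplotype (ties to the lexicographically smallest sequence).
#' The label is bound only when the dominant key's in-group frequency
#' reaches `min_dominant_freq` and the key is not already bound to an
#' earlier label; otherwise the label is skipped (set as missing). Present
#' genomes whose key carries a bound label get that label, all other
#' present genomes get `hapR`, and absent genomes get `absent`.
#'
#' @param cat A `haplotype_catalog`.
#' @param groups A `group_config`; at most five priority groups are used
#'   for labelling.
#' @param min_dominant_freq Minimum in-group frequency of a dominant
#'   haplotype.
#' @return A `haplotype_assignment`: list with `sg_id`, `label_of` (named
#'   character vector over the configured genomes, values in
#'   `hapI..hapV`/`hapR`/`absent`) and `defined` (named integer vector,
#'   label -> raw key).
#' @export
assign_ancestral <- function(cat, groups, min_dominant_freq = 3L) {
  labels <- c("hapI", "hapII", "hapIII", "hapIV", "hapV")
  prio <- groups$priority
  if (length(prio) > length(labels)) {
    stop("at most ", length(labels), " priority groups are supported")
  }
  unknown <- setdiff(prio, groups$assignment)
  if (length(unknown)) stop("unknown group in priority: ",
                            paste(unknown, collapse = ", "))
  defined <- stats::setNames(integer(0), character(0))
  for (k in seq_along(prio)) {
    g_members <- group_members(groups, prio[k])
    keys <- cat$keys[intersect(names(cat$keys), g_members)]
    if (!length(keys)) next
    tab <- table(keys)
    top <- as.integer(names(tab))[order(-as.integer(tab),
                                        cat$seqs[as.integer(names(tab))])][1L]
    if (as.integer(tab[as.character(top)]) < min_dominant_freq) next
    if (top %in% defined) next  # defined by a former group: label skipped
    defined[labels[k]] <- top
  }
  all_genomes <- names(groups$assignment)
  label_of <- stats::setNames(rep("absent", length(all_genomes)), all_genomes)
  present <- intersect(all_genomes, names(cat$keys))
  bound <- stats::setNames(names(defined), defined)
  lab <- bound[as.character(cat$keys[present])]
  label_of[present] <- ifelse(is.na(lab), "hapR", lab)
  structure(list(sg_id = cat$sg_id, label_of = label_of, defined = defined),
            class = "haplotype_assignment")
}

#' Ancestral haplotype assignments for all SGs
#' @param catalogs Named list of `haplotype_catalog`s.
#' @inheritParams assign_ancestral
#' @return Named list of `haplotype_assignment`s.
#' @export
assign_ancestral_all <- function(catalogs, groups, min_dominant_freq = 3L) {
  lapply(catalogs, assign_ancestral, groups = groups,
         min_dominant_freq = min_dominant_freq)
}

#' Inter-population haplotype divergence (HDG) of one SG
#'
#' The mean, over all cross-population pairs of present genomes, of the
#' indicator that the two genomes carry different raw haplotype keys;
#' equivalently `1 - sum_k f_a(k) * f_b(k)` with `f` the within-population
#' key frequencies among present members. `NA` when the SG is present in
#' fewer than `min_presence_total` genomes overall (counted across all
#' genomes, not just the two populations) or either population has no
#' present member.
#'
#' @param cat A `haplotype_catalog`.
#' @param pop_a,pop_b Disjoint character vectors of genome ids.
#' @param min_presence_total Minimum overall SG occupancy for a defined
#'   value.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
hdg <- function(cat, pop_a, pop_b, min_presence_total = 10L) {
  if (length(intersect(pop_a, pop_b))) {
    stop("populations must be disjoint")
  }
  if (length(cat$keys) < min_presence_total) return(NA_real_)
  ka <- cat$keys[intersect(names(cat$keys), pop_a)]
  kb <- cat$keys[intersect(names(cat$keys), pop_b)]
  if (!length(ka) || !length(kb)) return(NA_real_)
  fa <- table(factor(ka, levels = seq_along(cat$seqs))) / length(ka)
  fb <- table(factor(kb, levels = seq_along(cat$seqs))) / length(kb)
  1 - sum(as.numeric(fa) * as.numeric(fb))
}

#' HDG track along the framework genome
#'
#' HDG per framework-anchored SG, in framework coordinate order; SGs
#' failing the presence filter keep an `NA` entry in the track.
#'
#' @param pan A `pan_genome`.
#' @param catalogs Named list of `haplotype_catalog`s (from
#'   [build_catalogs()]).
#' @param pop_a,pop_b Disjoint genome id vectors (e.g. via
#'   [group_members()]; in a GJ-vs-XI style contrast, pop_b would exclude
#'   divergent groups such as aus).
#' @param min_presence_total Presence filter, see [hdg()].
#' @return An `hdg_track` data.frame: `sg_id`, `chrom`, `start`, `end`,
#'   `hdg`, ordered by framework coordinates.
#' @export
hdg_track <- function(pan, catalogs, pop_a, pop_b,
                      min_presence_total = 10L) {
  anch <- !is.na(pan$sgs$chrom)
  sgs <- pan$sgs[anch, , drop = FALSE]
  vals <- vapply(sgs$sg_id, function(id) {
    hdg(catalogs[[id]], pop_a, pop_b, min_presence_total)
  }, numeric(1L))
  out <- data.frame(sg_id = sgs$sg_id, chrom = sgs$chrom,
                    start = sgs$start, end = sgs$end, hdg = unname(vals),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pop_a") <- pop_a
  attr(out, "pop_b") <- pop_b
  class(out) <- c("hdg_track", class(out))
  out
}
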