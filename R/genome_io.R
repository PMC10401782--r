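# Readers/writers for the formats the pipeline touches, and the internal
# data model they normalise into. Internal coordinates: 0-based half-open.

#' Construct a genome annotation
#'
#' Bundles the ordered gene models of one genome with its predicted protein
#' sequences. Genes are sorted by (chrom, start, gene_id) and assigned a
#' 0-based `rank` along each chromosome; all downstream synteny logic operates
#' on ranks, not file order.
#'
#' @param genome_id Single string naming the genome.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`).
#' @param proteins Named character vector, `gene_id` -> amino-acid sequence.
#'   May cover a subset of genes; every provided sequence must be non-empty.
#' @return An object of class `genome_annotation`: a list with `genome_id`,
#'   `genes` (with `rank` column) and `proteins`.
#' @export
genome_annotation <- function(genome_id, genes, proteins = character()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("genes must have columns: ", paste(req, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1L]
    stop("duplicate gene_id in genome '", genome_id, "': ", dup)
  }
  if (nrow(genes) && any(genes$start >= genes$end)) {
    bad <- which(genes$start >= genes$end)[1L]
    stop("gene '", genes$gene_id[bad], "': start must be < end")
  }
  if (nrow(genes) && !all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  o <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- if (nrow(genes)) {
    stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along) - 1L
  } else {
    integer()
  }
  rownames(genes) <- NULL
  if (length(proteins)) {
    if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
      stop("proteins must be a named character vector")
    }
    if (any(!nzchar(proteins))) stop("empty protein sequence")
  }
  structure(
    list(genome_id = genome_id, genes = genes,
         proteins = proteins[intersect(names(proteins), genes$gene_id)]),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes on %d chromosome(s), %d proteins\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$chrom)),
              length(x$proteins)))
  invisible(x)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 `gene` features (1-based, closed) are converted to the internal
#' 0-based half-open convention; BED (already 0-based half-open) is taken
#' verbatim. Gene identifiers come from the `ID` attribute (GFF3; fallback
#' configurable via `id_attr`) or the 4th BED column.
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or BED file; format guessed
#'   from the extension unless `format` is given.
#' @param genome_id Genome name recorded in the annotation.
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @param id_attr GFF3 attribute keys tried in order for the gene identifier.
#' @return A [genome_annotation()] (without proteins).
#' @export
read_gene_models <- function(path, genome_id,
                             format = c("auto", "gff3", "bed"),
                             feature = "gene",
                             id_attr = c("ID", "locus_tag")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    warning("no records in ", path, "; returning empty annotation")
    return(genome_annotation(genome_id,
      data.frame(gene_id = character(), chrom = character(),
                 start = numeric(), end = numeric(), strand = character())))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (format == "gff3") {
    nf <- lengths(fields)
    if (any(nf != 9L)) {
      bad <- which(nf != 9L)[1L]
      stop("malformed GFF3 line ", idx[bad], " in ", path,
           ": expected 9 tab-separated columns, got ", nf[bad])
    }
    m <- do.call(rbind, fields)
    sel <- m[, 3L] == feature
    if (!any(sel)) {
      warning("no '", feature, "' features in ", path)
    }
    m <- m[sel, , drop = FALSE]
    attrs <- m[, 9L]
    ids <- rep(NA_character_, nrow(m))
    for (key in id_attr) {
      miss <- is.na(ids)
      if (!any(miss)) break
      hit <- regmatches(attrs[miss],
                        regexpr(paste0("(?:^|;)\\s*", key, "=[^;]+"),
                                attrs[miss], perl = TRUE))
      got <- regexpr(paste0("(?:^|;)\\s*", key, "=[^;]+"), attrs[miss],
                     perl = TRUE) > 0
      ids[which(miss)[got]] <- sub(paste0("^.*", key, "="), "", hit)
    }
    if (anyNA(ids)) {
      bad <- idx[sel][which(is.na(ids))[1L]]
      stop("GFF3 line ", bad, " in ", path, ": no ",
           paste(id_attr, collapse = "/"), " attribute")
    }
    start <- as.numeric(m[, 4L]) - 1  # 1-based closed -> 0-based half-open
    end <- as.numeric(m[, 5L])
    genes <- data.frame(gene_id = ids, chrom = m[, 1L], start = start,
                        end = end, strand = m[, 7L],
                        stringsAsFactors = FALSE)
  } else {
    nf <- lengths(fields)
    if (any(nf < 6L)) {
      bad <- which(nf < 6L)[1L]
      stop("malformed BED line ", idx[bad], " in ", path,
           ": expected >= 6 columns, got ", nf[bad])
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:6))
    genes <- data.frame(gene_id = m[, 4L], chrom = m[, 1L],
                        start = as.numeric(m[, 2L]), end = as.numeric(m[, 3L]),
                        strand = m[, 6L], stringsAsFactors = FALSE)
  }
  genome_annotation(genome_id, genes)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: internal 0-based half-open coordinates
#' are emitted as 1-based closed GFF3 `gene` features with `ID` attributes.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(g)) {
    writeLines(sprintf("%s\tsyntelogr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, as.integer(g$start) + 1L, as.integer(g$end),
                       g$strand, g$gene_id), con)
  }
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The first whitespace-delimited token of each header is taken as the gene
#' id. Sequences are upper-cased and a trailing stop symbol `*` is stripped.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector, gene_id -> sequence.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header in ", path, ": ",
         ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence in ", path, ": ", ids[!nzchar(seqs)][1L])
  }
  stats::setNames(seqs, ids)
}

#' Write protein sequences as FASTA
#' @param proteins Named character vector, gene_id -> sequence.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(proteins), path, width = 80L)
  invisible(path)
}

#' Read pairwise protein similarity hits (12-column tabular format)
#'
#' Standard outfmt-6 layout: query, subject, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore. Self hits (query == subject) are dropped.
#'
#' @param path Tab-separated hits file.
#' @return data.frame of hit records.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  if (length(nf) && any(nf != 12L, na.rm = TRUE)) {
    bad <- which(nf != 12L)[1L]
    stop("malformed hits line ", bad, " in ", path,
         ": expected 12 tab-separated columns, got ", nf[bad])
  }
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(nf)) {
    h <- as.data.frame(stats::setNames(
      rep(list(character()), 12L), cols), stringsAsFactors = FALSE)
    h$pident <- numeric(); h$length <- integer(); h$evalue <- numeric()
    h$bitscore <- numeric()
    return(h)
  }
  h <- utils::read.table(path, sep = "\t", comment.char = "#", quote = "",
                         stringsAsFactors = FALSE, col.names = cols)
  h <- h[h$query != h$subject, , drop = FALSE]
  if (nrow(h) && (any(h$evalue < 0) || any(h$bitscore < 0))) {
    stop("negative evalue or bitscore in ", path)
  }
  rownames(h) <- NULL
  h
}

#' Write a hits table in the 12-column tabular format
#' @param hits data.frame as returned by [read_hits()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome-to-group configuration
#'
#' Accepts either a two-column TSV (`genome_id<TAB>group`) or a YAML file
#' with fields `assignment` (map genome -> group) and optionally `priority`
#' (ordered list of group labels used for ancestral haplotype naming).
#'
#' @param path TSV or YAML file.
#' @param priority Optional character vector overriding the priority order;
#'   defaults to groups in order of first appearance.
#' @return An object of class `group_config`: list with `assignment` (named
#'   character vector) and `priority`.
#' @export
read_group_config <- function(path, priority = NULL) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    assignment <- unlist(y$assignment)
    if (is.null(priority)) priority <- unlist(y$priority)
  } else {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("genome_id", "group"))
    assignment <- stats::setNames(d$group, d$genome_id)
  }
  group_config(assignment, priority)
}

#' Construct a genome-to-group configuration
#' @param assignment Named character vector, genome_id -> group label.
#' @param priority Ordered character vector of group labels used for
#'   ancestral haplotype naming; defaults to order of first appearance.
#' @return A `group_config` object.
#' @export
group_config <- function(assignment, priority = NULL) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    stop("assignment must map each genome_id exactly once")
  }
  if (is.null(priority)) priority <- unique(unname(assignment))
  if (!all(priority %in% assignment)) {
    stop("priority labels not among assigned groups: ",
         paste(setdiff(priority, assignment), collapse = ", "))
  }
  structure(list(assignment = assignment, priority = priority),
            class = "group_config")
}

#' Genomes belonging to a set of group labels
#' @param groups A `group_config`.
#' @param labels Character vector of group labels.
#' @return Character vector of genome ids.
#' @export
group_members <- function(groups, labels) {
  unknown <- setdiff(labels, groups$assignment)
  if (length(unknown)) stop("unknown group label(s): ",
                            paste(unknown, collapse = ", "))
  names(groups$assignment)[groups$assignment %in% labels]
}

#' Write a group configuration as TSV
#' @param groups A `group_config`.
#' @param path Output path.
#' @export
write_group_config <- function(groups, path) {
  utils::write.table(
    data.frame(genome_id = names(groups$assignment),
               group = unname(groups$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read the pan-genome presence matrix
#'
#' TSV with one SG per row: `sg_id`, framework `chrom`, `start`, `end`
#' (`.` when the SG lacks a framework anchor), then one column per genome
#' holding the comma-joined member gene id(s) or `.` for absence.
#'
#' @param pan A `pan_genome` object.
#' @param path Output path.
#' @export
write_pan_matrix <- function(pan, path) {
  wide <- pan_presence_table(pan)
  anchor <- pan$sgs
  na2dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  out <- cbind(
    data.frame(sg_id = anchor$sg_id, chrom = na2dot(anchor$chrom),
               start = na2dot(anchor$start), end = na2dot(anchor$end),
               stringsAsFactors = FALSE),
    wide)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pan_matrix
#' @param framework_id Framework genome id recorded in the reconstructed
#'   object (must be one of the matrix columns).
#' @return `read_pan_matrix()` returns a `pan_genome`.
#' @export
read_pan_matrix <- function(path, framework_id) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  fixed <- c("sg_id", "chrom", "start", "end")
  genomes <- setdiff(names(d), fixed)
  if (!framework_id %in% genomes) {
    stop("framework genome '", framework_id, "' not among matrix columns")
  }
  members <- do.call(rbind, lapply(genomes, function(g) {
    present <- d[[g]] != "."
    if (!any(present)) return(NULL)
    ids <- strsplit(d[[g]][present], ",", fixed = TRUE)
    data.frame(sg_id = rep(d$sg_id[present], lengths(ids)),
               genome_id = g, gene_id = unlist(ids),
               stringsAsFactors = FALSE)
  }))
  sgs <- data.frame(
    sg_id = d$sg_id,
    chrom = ifelse(d$chrom == ".", NA_character_, d$chrom),
    start = suppressWarnings(as.numeric(ifelse(d$start == ".", NA, d$start))),
    end = suppressWarnings(as.numeric(ifelse(d$end == ".", NA, d$end))),
    stringsAsFactors = FALSE)
  occ <- table(factor(unique(members[, c("sg_id", "genome_id")])$sg_id,
                      levels = sgs$sg_id))
  sgs$occupancy <- as.integer(occ[sgs$sg_id])
  new_pan_genome(sgs, members, genomes = genomes,
                 framework_id = framework_id)
}

#' Write introgression blocks as BED6 (+ P value column)
#'
#' Columns: chrom, start, end, block id, `round(1000 * mean_hdg)`, strand
#' `.`, and the block's minimum window P value as a seventh column.
#'
#' @param blocks data.frame of blocks (see [merge_blocks()]).
#' @param path Output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  p <- if ("min_window_p" %in% names(blocks)) blocks$min_window_p else
    rep(NA_real_, nrow(blocks))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s",
                   blocks$chrom, as.integer(blocks$start),
                   as.integer(blocks$end), blocks$block_id,
                   as.integer(round(1000 * blocks$mean_hdg)),
                   ifelse(is.na(p), ".", format(p, digits = 6)))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the ancestral haplotype label table
#'
#' TSV with one SG per row and one column per genome holding a label in
#' `hapI..hapV`, `hapR` or `absent`.
#'
#' @param assignments List of haplotype assignments (see
#'   [assign_ancestral()]), or the result of [assign_ancestral_all()].
#' @param genomes Character vector fixing the column order.
#' @param path Output path.
#' @export
write_haplotype_table <- function(assignments, genomes, path) {
  rows <- lapply(assignments, function(a) {
    lab <- a$label_of[genomes]
    lab[is.na(lab)] <- "absent"
    c(a$sg_id, unname(lab))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("sg_id", genomes)
  utils::write.table(as.data.frame(m, stringsAsFactors = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_table
#' @return `read_haplotype_table()` returns a data.frame, one row per SG,
#'   one column per genome.
#' @export
read_haplotype_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an HDG track as TSV
#' @param track An `hdg_track` data.frame (see [hdg_track()]).
#' @param path Output path.
#' @export
write_hdg_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hdg_track
#' @export
read_hdg_track <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(d) <- c("hdg_track", class(d))
  d
}
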