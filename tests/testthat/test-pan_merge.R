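# Small hand-built panels for merge logic: annotations with one chromosome
# and evenly spaced genes; pair sets written directly.
mk_pairs <- function(ga, gb) {
  data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
}

test_that("unpaired genes found their own SGs", {
  anns <- list(A = toy_annotation("A", 3L), B = toy_annotation("B", 2L))
  ps <- list("A|B" = mk_pairs(c("A_g01", "A_g02"), c("B_g01", "B_g02")))
  pan <- merge_pairwise(anns, ps, c("A", "B"))
  expect_equal(nrow(pan$sgs), 3L)
  expect_equal(sort(pan$sgs$occupancy), c(1L, 2L, 2L))
  expect_equal(nrow(pan$members), 5L)
})

test_that("a new gene linking to one SG joins it", {
  anns <- list(A = toy_annotation("A", 2L), B = toy_annotation("B", 2L),
               C = toy_annotation("C", 1L))
  ps <- list("A|B" = mk_pairs(c("A_g01", "A_g02"), c("B_g01", "B_g02")),
             "A|C" = mk_pairs("A_g01", "C_g01"))
  pan <- merge_pairwise(anns, ps, c("A", "B", "C"))
  expect_equal(nrow(pan$sgs), 2L)
  sg_c <- pan$members$sg_id[pan$members$gene_id == "C_g01"]
  sg_a1 <- pan$members$sg_id[pan$members$gene_id == "A_g01"]
  expect_equal(sg_c, sg_a1)
})

test_that("multi-SG links resolve by majority link count", {
  anns <- list(A = toy_annotation("A", 2L), B = toy_annotation("B", 2L),
               C = toy_annotation("C", 1L))
  # SG1 = {A_g01, B_g01}; SG2 = {A_g02, B_g02}
  ps <- list("A|B" = mk_pairs(c("A_g01", "A_g02"), c("B_g01", "B_g02")),
             # C_g01 links twice into SG1 (via A and B) and once into SG2
             "A|C" = mk_pairs(c("A_g01", "A_g02"), c("C_g01", "C_g01")),
             "B|C" = mk_pairs("B_g01", "C_g01"))
  pan <- merge_pairwise(anns, ps, c("A", "B", "C"))
  sg_c <- pan$members$sg_id[pan$members$gene_id == "C_g01"]
  sg_a1 <- pan$members$sg_id[pan$members$gene_id == "A_g01"]
  expect_equal(sg_c, sg_a1)
})

test_that("no gene is placed in two SGs and occupancies sum to gene count", {
  panel <- small_planted_panel()
  hits <- simulate_hits(panel)
  res <- run_pipeline(panel$annotations, hits, panel$groups,
                      n_reps = 10L, seed = 1L)
  pan <- res$pan
  expect_false(anyDuplicated(pan$members$gene_id) > 0)
  total_genes <- sum(vapply(res$collapsed,
                            function(a) nrow(a$genes), 1L))
  expect_equal(sum(pan$sgs$occupancy), total_genes)
  expect_equal(sum(pan$sgs$occupancy), nrow(pan$members))
})

test_that("occupancy classes reproduce the n = 74 boundaries", {
  lab <- classify_occupancy(1:74, n = 74)
  expect_equal(as.character(lab[74]), "core")
  expect_equal(as.character(lab[73]), "soft-core")
  expect_equal(as.character(lab[67]), "soft-core")
  expect_equal(as.character(lab[66]), "dispensable")
  expect_equal(as.character(lab[2]), "dispensable")
  expect_equal(as.character(lab[1]), "private")
  expect_equal(min(which(lab == "soft-core")), 67L)
  expect_equal(max(which(lab == "dispensable")), 66L)
})

test_that("sub-population composition partitions all SGs", {
  panel <- small_planted_panel()
  hits <- simulate_hits(panel)
  res <- run_pipeline(panel$annotations, hits, panel$groups,
                      n_reps = 10L, seed = 1L)
  comp <- subpopulation_composition(res$pan, panel$groups, "GJ")
  expect_equal(sum(comp), nrow(res$pan$sgs))
  expect_true(all(c("core", "soft-core", "dispensable", "private",
                    "absent") %in% names(comp)))
  expect_error(subpopulation_composition(res$pan, panel$groups,
                                         character()), "empty|unknown")
})

test_that("growth curve is monotone and reaches the full pan size", {
  panel <- small_planted_panel()
  hits <- simulate_hits(panel)
  res <- run_pipeline(panel$annotations, hits, panel$groups,
                      n_reps = 10L, seed = 1L)
  gc <- pan_growth_curve(res$pan, n_orders = 20L, seed = 3L)
  orders <- attr(gc, "orders")
  expect_true(all(apply(orders$pan, 1L, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(orders$core, 1L, function(x) all(diff(x) <= 0))))
  expect_true(all(orders$pan[, ncol(orders$pan)] == nrow(res$pan$sgs)))
})

test_that("PAV bias threshold is inclusive at the boundary", {
  # 5 GJ + 5 XI genomes; framework SGs engineered to frequency diffs
  # 1.0 (fixed vs absent), exactly 0.6, and 0.4
  genomes <- c(paste0("GJ_", 1:5), paste0("XI_", 1:5))
  groups <- group_config(stats::setNames(rep(c("GJ", "XI"), each = 5L),
                                         genomes))
  anns <- stats::setNames(
    lapply(genomes, function(g) toy_annotation(g, 3L, prefix = g)),
    genomes)
  in_xi <- list(character(), paste0("XI_", 1:2), paste0("XI_", 1:3))
  ps <- list()
  for (g in genomes[-1L]) {
    sel <- if (startsWith(g, "GJ")) 1:3 else
      which(vapply(in_xi, function(x) g %in% x, TRUE))
    if (length(sel)) {
      ps[[paste0("GJ_1|", g)]] <- mk_pairs(sprintf("GJ_1_g%02d", sel),
                                           sprintf("%s_g%02d", g, sel))
    }
  }
  pan <- merge_pairwise(anns, ps, genomes)
  sg_of_fg <- function(k) {
    pan$members$sg_id[pan$members$gene_id == sprintf("GJ_1_g%02d", k)]
  }
  b6 <- pav_bias(pan, groups, "GJ", "XI", min_diff = 0.6)
  expect_setequal(b6$sg_id, c(sg_of_fg(1), sg_of_fg(2)))  # 1.0 and 0.6 kept
  expect_true(any(abs(b6$diff - 0.6) < 1e-9))             # inclusive bound
  b0 <- pav_bias(pan, groups, "GJ", "XI", min_diff = 0)
  expect_equal(b0$diff[b0$sg_id == sg_of_fg(3)], 0.4)     # 0.4 excluded at .6
  expect_error(pav_bias(pan, groups, "GJ", "nope"), "unknown")
})

test_that("conflict-free partitions are invariant to merge order", {
  panel <- simulate_panel(sim_config(
    groups = c(GJ = 4L, XI = 4L), n_sgs = 80L, n_chrom = 1L,
    mixture = c(core = 0.6, soft_core = 0.2, dispensable = 0.2,
                private = 0),
    mutation_rate = 0, tandem_prob = 0, seed = 19))
  hits <- simulate_hits(panel)
  anns <- panel$annotations
  genomes <- names(anns)
  ps <- list()
  for (i in seq_along(genomes)[-length(genomes)]) {
    for (j in (i + 1L):length(genomes)) {
      a <- genomes[i]; b <- genomes[j]
      ps[[paste(a, b, sep = "|")]] <-
        pair_syntelogs(anns[[a]], anns[[b]],
                       hits[[paste(a, b, sep = "|")]])
    }
  }
  canon <- function(pan) {
    part <- split(pan$members$gene_id, pan$members$sg_id)
    unname(sort(vapply(part, function(x) paste(sort(x), collapse = ","), "")))
  }
  ref <- canon(merge_pairwise(anns, ps, genomes))
  set.seed(23)
  for (r in 1:5) {
    ord <- c(genomes[1], sample(genomes[-1]))
    expect_equal(canon(merge_pairwise(anns, ps, ord)), ref)
  }
})
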