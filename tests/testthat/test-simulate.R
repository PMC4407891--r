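test_that("generator is deterministic under a fixed seed and sensitive to it", {
  cfg <- sim_config(n_genes = 15, depth_per_sample = 5e3, seed = 42,
                    make_genome = TRUE)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$annotation$genes, d2$annotation$genes)
  expect_identical(d1$annotation$pa_truth, d2$annotation$pa_truth)
  expect_identical(d1$usage, d2$usage)
  expect_identical(d1$reads, d2$reads)
  expect_identical(as.character(d1$annotation$genome),
                   as.character(d2$annotation$genome))
  d3 <- simulate_dataset(sim_config(n_genes = 15, depth_per_sample = 5e3,
                                    seed = 43, make_genome = FALSE))
  expect_false(identical(d1$reads$position, d3$reads$position))
})

test_that("gene models are well-formed on both strands", {
  ann <- simulate_annotation(sim_config(n_genes = 60, seed = 5, make_genome = FALSE))
  g <- ann$genes
  e <- ann$exons
  expect_setequal(unique(g$strand), c("+", "-"))
  for (gid in g$gene_id) {
    gi <- g[g$gene_id == gid, ]
    ei <- e[e$gene_id == gid, ]
    ei <- ei[order(ei$start), ]
    expect_gte(nrow(ei), 1)
    expect_true(all(ei$start >= gi$start & ei$end <= gi$end))
    if (nrow(ei) > 1) expect_true(all(ei$start[-1] > ei$end[-nrow(ei)]))
  }
  ni <- table(ann$introns$gene_id)
  expect_identical(as.integer(ni[g$gene_id]), g$n_exons - 1L)
  # genes are separated by at least 2 kb of flank on each side
  go <- g[order(g$start), ]
  expect_true(all(go$start[-1] - go$end[-nrow(go)] >= 4000))
})

test_that("single-exon genes are the degenerate case: no introns, no spRNA or intronic pAs", {
  ann <- simulate_annotation(sim_config(n_genes = 10, exons_per_gene = c(1, 1),
                                        frac_intronic_pa = 1, frac_sp_pa = 1,
                                        seed = 3, make_genome = FALSE))
  expect_null(ann$introns)
  expect_false(any(ann$pa_truth$class %in% c("intron", "sp")))
  expect_true(all(table(ann$exons$gene_id) == 1))
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(intron_len = c(0, 10)), "intron")
  expect_error(sim_config(exons_per_gene = c(5, 2)), "range")
  expect_error(sim_config(frac_ua_pa = 1.2), "proportion")
  expect_error(sim_config(depth_per_sample = 0), "depth")
  expect_error(planted_effect(5, "mystery", 2), "event_class")
  expect_error(planted_effect(5, "utr3_shift", 0, "proximal_up"), "fold_change")
})

test_that("usage: no effect means exchangeable conditions; effects act on odds", {
  cfg0 <- sim_config(n_genes = 30, seed = 9, make_genome = FALSE)
  ann <- simulate_annotation(cfg0)
  u0 <- simulate_usage(ann, cfg0)
  expect_equal(u0$ctrl, u0$test)
  cfg1 <- sim_config(n_genes = 30, seed = 9, make_genome = FALSE,
                     effect_table = list(planted_effect(8, "utr3_shift", 4,
                                                        "proximal_up")))
  u1 <- simulate_usage(ann, cfg1)
  planted <- attr(u1, "planted")
  expect_equal(nrow(planted), 8)
  pa <- ann$pa_truth
  for (gid in planted$gene_id) {
    prox <- pa$pa_id[pa$gene_id == gid & pa$class == "utr3" & pa$utr3_rank == 1]
    dist <- pa$pa_id[pa$gene_id == gid & pa$class == "utr3" & pa$utr3_rank == 2]
    odds <- function(col) u1[[col]][u1$pa_id == prox] / u1[[col]][u1$pa_id == dist]
    expect_equal(odds("test") / odds("ctrl"), 4)
  }
  untouched <- setdiff(unique(u1$gene_id), planted$gene_id)
  sel <- u1$gene_id %in% untouched
  expect_equal(u1$ctrl[sel], u1$test[sel])
  sums <- tapply(u1$test, u1$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("fold_change = 1 leaves usage unchanged", {
  cfg <- sim_config(n_genes = 20, seed = 2, make_genome = FALSE,
                    effect_table = list(planted_effect(5, "utr3_shift", 1,
                                                       "distal_up")))
  ann <- simulate_annotation(cfg)
  u <- simulate_usage(ann, cfg)
  expect_equal(u$ctrl, u$test)
})

test_that("reads conserve depth, stay within jitter range, and hit the decoy rate", {
  depth <- 2e4
  cfg <- sim_config(n_genes = 25, depth_per_sample = depth, decoy_frac = 0.1,
                    seed = 17, make_genome = FALSE)
  dat <- simulate_dataset(cfg)
  expect_identical(as.integer(table(dat$reads$sample)),
                   rep(as.integer(depth), 2))
  truth_pos <- dat$annotation$pa_truth$position[
    match(dat$reads$true_pa, dat$annotation$pa_truth$pa_id)]
  expect_true(all(abs(dat$reads$position - truth_pos) <= cfg$jitter))
  frac_fail <- mean(dat$reads$unaligned_T < 2)
  se <- sqrt(0.1 * 0.9 / (2 * depth))
  expect_lt(abs(frac_fail - 0.1), 3 * se)
})

test_that("motif planting is strand-aware, probabilistic, and length-preserving", {
  genome <- random_genome(4000, seed = 8)
  pa <- data.frame(pa_id = c("p1", "p2"), chrom = "chr1",
                   position = c(1000L, 2500L), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  g0 <- as.character(genome)
  planted <- plant_motifs(genome, pa,
                          list(planted_motif("UGUA", "U100_41", "all", 1)),
                          seed = 4)
  expect_identical(Biostrings::width(planted), Biostrings::width(genome))
  win <- extract_windows(pa, planted, regions = "U100_41")
  expect_true(all(grepl("TGTA", win$seq)))
  # minus-strand insertion lands reverse-complemented on the plus strand
  minus_win <- substr(as.character(planted), 2500 + 41 + 1, 2500 + 100)
  expect_true(grepl("TACA", minus_win))
  # zero probability leaves the sequence untouched
  same <- plant_motifs(genome, pa,
                       list(planted_motif("UGUA", "U100_41", "all", 0)), seed = 4)
  expect_identical(as.character(same), g0)
})

test_that("motif planting with certainty covers every selected window", {
  ds <- make_small_dataset(n_genes = 25, depth = 1e3, seed = 33, make_genome = TRUE)
  pa <- ds$dat$annotation$pa_truth
  genome <- plant_motifs(ds$dat$annotation$genome, pa,
                         list(planted_motif("AATAAA", "U40_1", "all", 1)), seed = 6)
  win <- extract_windows(pa, genome, regions = "U40_1")
  expect_true(all(grepl("AATAAA", win$seq[!win$truncated])))
  expect_equal(sum(win$truncated), 0)
})
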