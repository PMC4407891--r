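test_that("intron ordinals follow the first/second/middle/last scheme", {
  expect_equal(assign_intron_ordinal(3, 6), "M")
  expect_equal(assign_intron_ordinal(4, 5), "-2")
  expect_equal(assign_intron_ordinal(1:4, 4), c("+1", "+2", "-2", "-1"))
  expect_equal(assign_intron_ordinal(c(1, 2, 3, 5, 6, 7), 7),
               c("+1", "+2", "M", "M", "-2", "-1"))
  expect_true(is.na(assign_intron_ordinal(2, 3)))  # < 4 introns: excluded
  expect_error(assign_intron_ordinal(5, 4), "intron_index")
})

test_that("classification handles the TSS-proximal geometry of a hand-built gene", {
  ann <- make_tiny_annotation()  # + gene, [5000,9000), exons at 5000/6000/8000
  cl <- rbind(make_clusters(8500),              # 3'-most exon
              make_clusters(6100),              # internal exon 2
              make_clusters(5500),              # intron 1, 500 nt from TSS
              make_clusters(4300, strand = "-"),   # antisense, 700 nt upstream
              make_clusters(2500, strand = "-"),   # antisense, 2.5 kb: too far
              make_clusters(7000))              # intron 2
  res <- classify_pa(cl, ann)
  expect_equal(res$pa_class,
               c("utr3", "internal_exon", "intron", "uaRNA", "intergenic", "intron"))
  expect_equal(res$gene_id[1:4], rep("G1", 4))
  expect_equal(res$utr3_len[1], 500)
  expect_equal(res$tss_distance[c(1, 3, 4)], c(3500, 500, -700))
  # spRNA flag: sense, within 2 kb of the TSS (inclusive), multi-exon host,
  # not in the 3'-most exon -- so the internal-exon cluster at 1100 nt and
  # the intron-2 cluster at exactly 2000 nt qualify too
  expect_equal(res$sp_flag, c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_true(res$ua_flag[4])
  expect_equal(res$intron_index[c(3, 6)], c(1L, 2L))
  expect_true(all(res$ordinal_excluded[c(3, 6)]))  # only 2 introns
})

test_that("classification recovers planted classes on synthetic data", {
  ds <- make_small_dataset(n_genes = 60, depth = 3e4, seed = 21,
                           frac_intronic_pa = 0.5, frac_ua_pa = 0.5,
                           frac_sp_pa = 0.4)
  truth <- ds$dat$annotation$pa_truth
  # clusters at the exact truth positions (geometry test without read noise)
  cl <- data.frame(cluster_id = truth$pa_id, chrom = truth$chrom,
                   strand = truth$strand, start = truth$position,
                   end = truth$position + 1L, position = truth$position,
                   n_positions = 1L, total_reads = 1L, stringsAsFactors = FALSE)
  res <- classify_pa(cl, ds$dat$annotation)
  expect_equal(res$pa_class[truth$class == "utr3"],
               rep("utr3", sum(truth$class == "utr3")))
  expect_equal(res$pa_class[truth$class == "intron"],
               rep("intron", sum(truth$class == "intron")))
  expect_equal(res$pa_class[truth$class == "ua"],
               rep("uaRNA", sum(truth$class == "ua")))
  expect_true(all(res$sp_flag[truth$class == "sp"]))
  expect_equal(res$gene_id, truth$gene_id)
  # classification is a partition
  expect_true(all(res$pa_class %in%
    c("utr3", "intron", "internal_exon", "uaRNA", "intergenic")))
  expect_false(anyNA(res$pa_class))
})

test_that("top-2 event construction ranks by abundance with 3'-most tie-break", {
  ann <- make_tiny_annotation()
  cl <- make_clusters(c(8100, 8600, 8900))  # three tandem 3'UTR pAs
  res <- classify_pa(cl, ann)
  counts <- matrix(c(50L, 30L, 20L, 50L, 30L, 20L), ncol = 2,
                   dimnames = list(cl$cluster_id, c("ctrl", "test")))
  ev <- build_events(res, counts, "top2_abundant")
  expect_equal(nrow(ev), 1)
  expect_equal(unlist(ev$set1), "chr1:8100:+")
  expect_equal(unlist(ev$set2), "chr1:8600:+")
  expect_equal(ev$autr_len, 500)
  # tie for second rank: the 3'-most pA wins
  counts2 <- counts; counts2[, 1] <- c(50L, 25L, 25L); counts2[, 2] <- c(50L, 5L, 5L)
  ev2 <- build_events(res, counts2, "top2_abundant")
  expect_equal(unlist(ev2$set2), "chr1:8900:+")
  expect_equal(ev2$autr_len, 800)
})

test_that("one-vs-rest, cds and promoter-proximal event modes partition sets correctly", {
  ds <- make_small_dataset(n_genes = 40, depth = 3e4, seed = 31,
                           frac_intronic_pa = 0.6, frac_ua_pa = 0.6,
                           frac_sp_pa = 0.5)
  ovr <- build_events(ds$pa_ann, ds$counts, "one_vs_rest")
  expect_true(all(vapply(seq_len(nrow(ovr)), function(i)
    length(intersect(ovr$set1[[i]], ovr$set2[[i]])) == 0, logical(1))))
  cds <- build_events(ds$pa_ann, ds$counts, "cds")
  for (i in seq_len(nrow(cds))) {
    cls <- ds$pa_ann$pa_class[match(cds$set1[[i]], ds$pa_ann$cluster_id)]
    expect_true(all(cls %in% c("intron", "internal_exon")))
    cls2 <- ds$pa_ann$pa_class[match(cds$set2[[i]], ds$pa_ann$cluster_id)]
    expect_true(all(cls2 == "utr3"))
  }
  ua <- build_events(ds$pa_ann, ds$counts, "uaRNA")
  expect_gt(nrow(ua), 0)
  for (i in seq_len(nrow(ua))) {
    expect_true(all(ds$pa_ann$ua_flag[match(ua$set1[[i]], ds$pa_ann$cluster_id)]))
    ref_d <- ds$pa_ann$tss_distance[match(ua$set2[[i]], ds$pa_ann$cluster_id)]
    expect_true(all(ref_d > 2000))
  }
  sp <- build_events(ds$pa_ann, ds$counts, "spRNA")
  expect_gt(nrow(sp), 0)
  for (i in seq_len(nrow(sp)))
    expect_true(all(ds$pa_ann$sp_flag[match(sp$set1[[i]], ds$pa_ann$cluster_id)]))
})

test_that("single-exon genes generate no spRNA events", {
  ds <- make_small_dataset(n_genes = 15, depth = 5e3, seed = 41,
                           exons_per_gene = c(1, 1), frac_sp_pa = 1,
                           frac_ua_pa = 0, frac_intronic_pa = 0)
  expect_false(any(ds$pa_ann$sp_flag))
  sp <- build_events(ds$pa_ann, ds$counts, "spRNA")
  expect_equal(nrow(sp), 0)
})

test_that("read-support rules use the stated arithmetic, boundaries inclusive", {
  ec <- data.frame(event_id = c("e1", "e2", "e3", "e4"),
                   a1 = c(12, 12, 10, 4), a2 = c(0, 0, 10, 10),
                   b1 = c(7, 8, 10, 5), b2 = c(0, 0, 10, 10))
  expect_equal(min_read_filter(ec, "utr3_20_combined"), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(min_read_filter(ec, "intronic_10_combined"), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(min_read_filter(ec, "matrix_5_all"), c(FALSE, FALSE, TRUE, FALSE))
  expect_error(min_read_filter(ec, "nonsense"))
})

test_that("event counts sum the cluster sets per sample", {
  ann <- make_tiny_annotation()
  cl <- make_clusters(c(8100, 8900))
  res <- classify_pa(cl, ann)
  counts <- matrix(c(10L, 40L, 40L, 10L), ncol = 2,
                   dimnames = list(cl$cluster_id, c("test", "ctrl")))
  ev <- build_events(res, counts, "top2_abundant")
  ec <- event_counts(ev, counts, "test", "ctrl")
  expect_equal(unlist(ec[1, c("a1", "a2", "b1", "b2")], use.names = FALSE),
               c(10, 40, 40, 10))
})
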