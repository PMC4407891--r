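test_that("window coordinates fix the off-by-one convention on both strands", {
  co <- pa_window_coords(1000L, "+", "U40_1")
  expect_equal(c(co$start, co$end), c(960L, 1000L))   # genomic 960..999
  co <- pa_window_coords(1000L, "-", "U40_1")
  expect_equal(c(co$start, co$end), c(1001L, 1041L))  # genomic 1001..1040
  co <- pa_window_coords(1000L, "+", "U100_41")
  expect_equal(c(co$start, co$end), c(900L, 960L))
  co <- pa_window_coords(1000L, "+", "D1_100")
  expect_equal(c(co$start, co$end), c(1001L, 1101L))
  co <- pa_window_coords(1000L, "-", "D1_100")
  expect_equal(c(co$start, co$end), c(900L, 1000L))
  expect_error(pa_window_coords(1000L, "+", "X"), "window")
})

test_that("extracted windows carry the genome content, sense-oriented", {
  genome <- random_genome(3000, seed = 12)
  gchar <- unname(as.character(genome))
  pa <- data.frame(cluster_id = c("p", "m"), chrom = "chr1",
                   position = c(1000L, 1500L), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  win <- extract_windows(pa, genome)
  w <- function(id, rg) win$seq[win$id == id & win$region == rg]
  expect_equal(w("p", "U40_1"), substr(gchar, 961, 1000))
  expect_equal(w("p", "D1_100"), substr(gchar, 1002, 1101))
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(w("m", "U40_1"), rc(substr(gchar, 1502, 1541)))
  expect_equal(w("m", "U100_41"), rc(substr(gchar, 1542, 1601)))
  expect_equal(w("m", "D1_100"), rc(substr(gchar, 1401, 1500)))
  expect_equal(nchar(win$seq[win$region == "U100_41"]), c(60L, 60L))
  expect_equal(nchar(win$seq[win$region == "U40_1"]), c(40L, 40L))
  expect_equal(nchar(win$seq[win$region == "D1_100"]), c(100L, 100L))
})

test_that("contig-edge windows are flagged truncated and excluded", {
  genome <- random_genome(500, seed = 2)
  pa <- data.frame(cluster_id = "edge", chrom = "chr1", position = 30L,
                   strand = "+", stringsAsFactors = FALSE)
  win <- extract_windows(pa, genome)
  expect_true(win$truncated[win$region == "U100_41"])
  expect_true(is.na(win$seq[win$region == "U100_41"]))
  expect_false(win$truncated[win$region == "D1_100"])
  expect_error(extract_windows(data.frame(cluster_id = "x", chrom = "nope",
                                          position = 10L, strand = "+"),
                               genome), "off-contig")
})

test_that("reverse-complement round trip: mirrored pAs on the flipped genome", {
  genome <- random_genome(2000, seed = 31)
  flipped <- Biostrings::reverseComplement(genome)
  names(flipped) <- names(genome)
  pa <- data.frame(cluster_id = sprintf("s%d", 1:6), chrom = "chr1",
                   position = c(300L, 700L, 1100L, 1500L, 900L, 450L),
                   strand = rep(c("+", "-"), 3), stringsAsFactors = FALSE)
  mirrored <- pa
  mirrored$position <- 2000L - 1L - pa$position
  mirrored$strand <- ifelse(pa$strand == "+", "-", "+")
  w1 <- extract_windows(pa, genome)
  w2 <- extract_windows(mirrored, flipped)
  expect_equal(w1$seq, w2$seq)
})

test_that("k-mer Fisher P matches the hypergeometric enumeration oracle", {
  # craft foreground/background windows with controlled TGTA containment
  base <- strrep("C", 60)
  with_m <- paste0(strrep("C", 28), "TGTA", strrep("C", 28))
  fg <- data.frame(id = sprintf("f%d", 1:10), region = "U100_41",
                   seq = c(rep(with_m, 8), rep(base, 2)), truncated = FALSE,
                   stringsAsFactors = FALSE)
  bg <- data.frame(id = sprintf("b%d", 1:100), region = "U100_41",
                   seq = c(rep(with_m, 10), rep(base, 90)), truncated = FALSE,
                   stringsAsFactors = FALSE)
  ks <- kmer_enrichment(fg, bg, k = 4, regions = "U100_41")
  row <- ks[ks$kmer == "TGTA", ]
  expect_equal(row$fg_with, 8)
  expect_equal(row$bg_with, 10)
  expect_equal(row$P, oracle_fisher_two_sided(8, 2, 10, 90), tolerance = 1e-12)
  expect_gt(row$SS, 0)
  # depletion: zero containment in the foreground, many in the background
  fg0 <- fg; fg0$seq <- base
  ks0 <- kmer_enrichment(fg0, bg, k = 4, regions = "U100_41")
  expect_lt(ks0$SS[ks0$kmer == "TGTA"], 0)
  expect_error(kmer_enrichment(fg, fg, 4), "overlap")
})

test_that("a foreground drawn from the background population shows no enrichment", {
  genome <- random_genome(200 * 400 + 400, seed = 41)
  pa <- data.frame(cluster_id = sprintf("s%03d", 1:200), chrom = "chr1",
                   position = seq(300L, by = 400L, length.out = 200),
                   strand = "+", stringsAsFactors = FALSE)
  idx <- apakit:::with_seed(5, sample(200, 40))
  win <- extract_windows(pa, genome)
  fg <- win[win$id %in% pa$cluster_id[idx], ]
  bg <- win[!win$id %in% pa$cluster_id[idx], ]
  ks <- kmer_enrichment(fg, bg, k = 4, regions = "U40_1")
  expect_lte(sum(ks$P < 0.001), 2)  # expected < 1 significant 4-mer by chance
})

test_that("nucleotide profiles are normalized and detect planted composition", {
  g <- Biostrings::DNAStringSet(strrep("A", 1000))
  names(g) <- "chr1"
  pa <- data.frame(cluster_id = "x", chrom = "chr1", position = 500L,
                   strand = "+", stringsAsFactors = FALSE)
  prof <- nucleotide_profile(pa, g, halfwidth = 50)
  expect_equal(prof$A, rep(1, 101))
  expect_equal(nrow(prof), 101)
  genome <- random_genome(6000, seed = 9)
  pa2 <- data.frame(cluster_id = sprintf("y%d", 1:10), chrom = "chr1",
                    position = seq(500L, by = 500L, length.out = 10),
                    strand = "+", stringsAsFactors = FALSE)
  prof2 <- nucleotide_profile(pa2, genome, halfwidth = 100)
  expect_true(all(abs(rowSums(prof2[, c("A", "C", "G", "U")]) - 1) < 1e-9))
  # plant an A-run at -25..-15 of 8/10 sites and expect an A peak there
  g3 <- plant_motifs(genome, pa2[1:8, ],
                     list(planted_motif(strrep("A", 11), "U40_1", "all", 1)),
                     seed = 3)
  prof3 <- nucleotide_profile(pa2, g3, halfwidth = 50)
  upstream <- prof3$A[prof3$position >= -40 & prof3$position <= -1]
  flank <- prof3$A[prof3$position > 10]
  expect_gt(max(upstream), mean(flank) + 0.2)
})

test_that("distance/PAS grouping applies the 120-nt boundary and AATAAA search", {
  genome <- Biostrings::DNAStringSet(strrep("C", 3000))
  names(genome) <- "chr1"
  # give pair 1 and 3 an AATAAA at +40 of the proximal pA
  genome <- plant_motifs(genome,
                         data.frame(pa_id = c("x1", "x3"), chrom = "chr1",
                                    position = c(500L, 1500L), strand = "+"),
                         list(planted_motif("AATAAA", "D1_100", "all", 1)),
                         seed = 2)
  pairs <- data.frame(event_id = c("x1", "x2", "x3", "x4"),
                      chrom = "chr1", strand = "+",
                      proximal_pos = c(500L, 1000L, 1500L, 2000L),
                      autr_len = c(119L, 119L, 120L, 300L),
                      RED = c(-0.5, -0.1, 0.2, 0.4), stringsAsFactors = FALSE)
  out <- distance_pas_groups(pairs, genome)
  expect_equal(out$assignments$group, c(1L, 2L, 3L, 4L))
  expect_equal(out$summary$n, rep(1L, 4))
})

test_that("K-S agrees with the brute-force ECDF oracle; identical samples give D=0", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  kt <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(unname(kt$statistic), oracle_ks_D(x, y), tolerance = 1e-12)
  pairs <- data.frame(event_id = sprintf("p%d", 1:40), chrom = "chr1",
                      strand = "+", proximal_pos = seq(200L, by = 60L,
                                                       length.out = 40),
                      autr_len = rep(c(100L, 200L), each = 20),
                      RED = rep(rnorm(20), 2), stringsAsFactors = FALSE)
  genome <- random_genome(4000, seed = 3)
  out <- distance_pas_groups(pairs, genome)
  gg <- merge(out$assignments, pairs)
  g1 <- gg$RED[gg$group %in% c(1, 2)]
  g2 <- gg$RED[gg$group %in% c(3, 4)]
  kt2 <- suppressWarnings(stats::ks.test(g1, g2))
  expect_equal(unname(kt2$statistic), 0)
  expect_equal(kt2$p.value, 1)
})
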