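# Event-count and dataset fixtures built in code.

# null events: both samples multinomial draws from one shared usage vector
make_null_ec <- function(E, min_reads = 50, seed = 1) {
  apakit:::with_seed(seed, {
    na <- min_reads + stats::rpois(E, 30)
    nb <- min_reads + stats::rpois(E, 30)
    p2 <- stats::rbeta(E, 5, 5)
    a2 <- stats::rbinom(E, na, p2)
    b2 <- stats::rbinom(E, nb, p2)
    data.frame(event_id = sprintf("E%05d", seq_len(E)),
               a1 = na - a2, a2 = a2, b1 = nb - b2, b2 = b2,
               stringsAsFactors = FALSE)
  })
}

# null events plus planted odds shifts (first n_sig events), each isoform
# expecting >= size * 0.2 reads per sample
make_shift_ec <- function(n_null, n_sig, fold = 4, size = 600, seed = 1) {
  apakit:::with_seed(seed, {
    E <- n_null + n_sig
    p_ctrl <- stats::rbeta(E, 8, 8)
    p_test <- p_ctrl
    if (n_sig > 0) {
      odds <- p_ctrl[1:n_sig] / (1 - p_ctrl[1:n_sig]) * fold
      p_test[1:n_sig] <- odds / (1 + odds)
    }
    a2 <- stats::rbinom(E, size, p_test)
    b2 <- stats::rbinom(E, size, p_ctrl)
    ec <- data.frame(event_id = sprintf("E%05d", seq_len(E)),
                     a1 = size - a2, a2 = a2, b1 = size - b2, b2 = b2,
                     stringsAsFactors = FALSE)
    attr(ec, "planted") <- if (n_sig > 0) ec$event_id[1:n_sig] else character(0)
    ec
  })
}

# small processed dataset: simulate, cluster, count, classify, 3'UTR events
make_small_dataset <- function(n_genes = 40, depth = 2e4, seed = 101,
                               effect_table = list(), make_genome = FALSE, ...) {
  cfg <- sim_config(n_genes = n_genes, depth_per_sample = depth, seed = seed,
                    effect_table = effect_table, make_genome = make_genome, ...)
  dat <- simulate_dataset(cfg)
  pass <- filter_pass(dat$reads)
  clusters <- cluster_pa(pass)
  counts <- build_count_matrix(clusters, pass)
  pa_ann <- classify_pa(clusters, dat$annotation)
  list(cfg = cfg, dat = dat, pass = pass, clusters = clusters,
       counts = counts, pa_ann = pa_ann)
}

# hand-built annotation: one plus-strand gene with 3 exons
make_tiny_annotation <- function() {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      start = 5000L, end = 9000L, tss = 5000L,
                      n_exons = 3L, n_introns = 2L, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      start = c(5000L, 6000L, 8000L),
                      end = c(5200L, 6500L, 9000L),
                      exon_rank = 1:3, stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "apa_annotation")
}

make_clusters <- function(positions, strand = "+", chrom = "chr1") {
  data.frame(cluster_id = sprintf("%s:%d:%s", chrom, positions, strand),
             chrom = chrom, strand = strand,
             start = positions, end = positions + 1L, position = positions,
             n_positions = 1L, total_reads = 1L, stringsAsFactors = FALSE)
}

random_genome <- function(len = 3000, seed = 1, chrom = "chr1") {
  apakit:::with_seed(seed, {
    g <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), len,
                                               replace = TRUE), collapse = ""))
    names(g) <- chrom
    g
  })
}
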