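# TSV conventions: tab separation, UTF-8, '.' decimal, '#' comment header
# lines carrying tool version / seed / config hash.

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                  sep = "\t", header = TRUE))
}

#' Read/write the 6-column read table
#'
#' Columns: `chrom`, `position` (0-based 3'-end), `strand`, `sample`,
#' `read_id`, `unaligned_T`.
#'
#' @param reads Read table (extra columns are dropped on write).
#' @param path File path.
#' @param comments Header comment lines.
#' @return The path (write) or the read table (read).
#' @export
write_reads_tsv <- function(reads, path, comments = character()) {
  cols <- c("chrom", "position", "strand", "sample", "read_id", "unaligned_T")
  write_tsv_commented(reads[, cols], path, comments)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) read_tsv_commented(path)

#' Read/write the true-usage table
#' @param usage Usage table from [simulate_usage()].
#' @param path File path.
#' @param comments Header comment lines.
#' @return The path (write) or the table (read).
#' @export
write_usage_tsv <- function(usage, path, comments = character()) {
  write_tsv_commented(usage, path, comments)
}

#' @rdname write_usage_tsv
#' @export
read_usage_tsv <- function(path) read_tsv_commented(path)

#' Read/write the cluster x sample count matrix as TSV
#'
#' First column `cluster_id`, remaining columns one per sample.
#'
#' @param counts Integer matrix from [build_count_matrix()].
#' @param path File path.
#' @param comments Header comment lines.
#' @return The path (write) or the matrix (read).
#' @export
write_counts_tsv <- function(counts, path, comments = character()) {
  df <- data.frame(cluster_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, comments)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_commented(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cluster_id
  storage.mode(m) <- "integer"
  m
}

#' Write pA clusters as BED6 / read them back
#'
#' BED is 0-based half-open; `name` carries the cluster id (which encodes
#' the representative position) and `score` the total read count.
#'
#' @param clusters Cluster table from [cluster_pa()].
#' @param path File path.
#' @return The path (write) or a cluster table (read; `n_positions` is not
#'   representable in BED6 and comes back as `NA`).
#' @export
write_clusters_bed <- function(clusters, path) {
  gr <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start + 1L, clusters$end),
                               strand = clusters$strand,
                               name = clusters$cluster_id,
                               score = clusters$total_reads)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_clusters_bed
#' @export
read_clusters_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  id <- gr$name
  pos <- as.integer(vapply(strsplit(id, ":", fixed = TRUE), `[[`, character(1), 2))
  data.frame(cluster_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             position = pos,
             n_positions = NA_integer_,
             total_reads = as.integer(gr$score),
             stringsAsFactors = FALSE)
}

#' Write the gene annotation as GTF / read it back
#'
#' Emits `gene` and `exon` features (1-based inclusive coordinates per the
#' GTF standard). Reading reconstructs the 0-based internal representation,
#' recomputing TSS, exon ranks and intron counts from the features.
#'
#' @param annotation An `"apa_annotation"` (or list with `genes`, `exons`).
#' @param path File path.
#' @return The path (write) or an annotation list (read).
#' @export
write_annotation_gtf <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  gr <- GenomicRanges::GRanges(
    c(g$chrom, e$chrom),
    IRanges::IRanges(c(g$start, e$start) + 1L, c(g$end, e$end)),
    strand = c(g$strand, e$strand),
    type = c(rep("gene", nrow(g)), rep("exon", nrow(e))),
    gene_id = c(g$gene_id, e$gene_id),
    source = "apakit")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = gr$type, gene_id = gr$gene_id,
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", c("gene_id", "chrom", "strand", "start", "end")]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  exons <- df[df$type == "exon", c("gene_id", "chrom", "strand", "start", "end")]
  exons <- exons[order(exons$gene_id, exons$start), ]
  rk <- stats::ave(exons$start, exons$gene_id,
                   FUN = function(x) seq_along(x))
  minus <- exons$strand == "-"
  nex <- stats::ave(exons$start, exons$gene_id, FUN = length)
  exons$exon_rank <- as.integer(ifelse(minus, nex - rk + 1, rk))
  genes$n_exons <- as.integer(nex[match(genes$gene_id, exons$gene_id)])
  genes$n_introns <- genes$n_exons - 1L
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons, introns = NULL,
                 pa_truth = NULL, genome = NULL, config = NULL),
            class = "apa_annotation")
}

#' Write/read the genome as FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path File path.
#' @return The path (write) or a `DNAStringSet` (read).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Read gene sets in GMT format
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write event tables (list columns collapsed with commas)
#' @param events Event table from [build_events()].
#' @param path File path.
#' @param comments Header comment lines.
#' @return The path (write) or an event table with list columns (read).
#' @export
write_events_tsv <- function(events, path, comments = character()) {
  df <- events
  df$set1 <- vapply(events$set1, paste, character(1), collapse = ",")
  df$set2 <- vapply(events$set2, paste, character(1), collapse = ",")
  write_tsv_commented(df, path, comments)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- read_tsv_commented(path)
  df$set1 <- I(strsplit(df$set1, ",", fixed = TRUE))
  df$set2 <- I(strsplit(df$set2, ",", fixed = TRUE))
  df
}
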