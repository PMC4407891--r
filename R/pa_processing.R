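#' Keep poly(A) site-supporting (PASS) reads
#'
#' A read supports a genuine poly(A) junction when at least 2 Ts at its 5'
#' end did not align to the genome. Filtering is order-preserving.
#'
#' @param reads `data.frame` with at least the column `unaligned_T`.
#' @return The rows of `reads` with `unaligned_T >= 2`.
#' @export
filter_pass <- function(reads) {
  if (!"unaligned_T" %in% names(reads)) stopf("reads lack the 'unaligned_T' column")
  if (anyNA(reads$unaligned_T)) stopf("unaligned_T has missing values")
  reads[reads$unaligned_T >= 2L, , drop = FALSE]
}

#' Cluster read 3'-end positions into poly(A) sites
#'
#' Distinct positions on the same chromosome and strand are chained by
#' single linkage: consecutive positions at most `max_gap` nt apart join the
#' same cluster, so a cluster's span may exceed `max_gap` through chaining.
#' The representative position is the member with the highest total read
#' count, ties broken towards the 3'-most position with respect to strand.
#'
#' @param reads PASS-filtered read table (`chrom`, `position`, `strand`).
#' @param max_gap Maximum distance between consecutive member positions
#'   (default 24 nt).
#' @return `data.frame` with columns `cluster_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open span over member positions),
#'   `position` (representative), `n_positions`, `total_reads`, sorted by
#'   coordinate.
#' @export
cluster_pa <- function(reads, max_gap = 24L) {
  dt <- data.table::as.data.table(reads[, c("chrom", "position", "strand")])
  pos <- dt[, .(n = .N), by = .(chrom, strand, position)]
  gr <- GenomicRanges::GRanges(pos$chrom,
                               IRanges::IRanges(pos$position + 1L, width = 1L),
                               strand = pos$strand)
  # reduce() merges ranges whose gap is < min.gapwidth; two 1-nt positions at
  # distance d have gap d - 1, so min.gapwidth = max_gap chains d <= max_gap
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap)
  hit <- GenomicRanges::findOverlaps(gr, red)
  pos$cl <- S4Vectors::subjectHits(hit)
  isplus <- as.character(GenomicRanges::strand(red))[pos$cl] == "+"
  # representative: modal position, tie -> 3'-most w.r.t. strand
  pos[, tiebreak := ifelse(isplus, position, -position)]
  rep_pos <- pos[order(cl, -n, -tiebreak),
                 .(position = position[1]), by = cl][order(cl)]
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    strand = as.character(GenomicRanges::strand(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    position = rep_pos$position,
                    n_positions = as.integer(table(factor(pos$cl, levels = seq_along(red)))),
                    total_reads = as.integer(tapply(pos$n, factor(pos$cl, levels = seq_along(red)), sum)),
                    stringsAsFactors = FALSE)
  out$cluster_id <- sprintf("%s:%d:%s", out$chrom, out$position, out$strand)
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out[, c("cluster_id", "chrom", "strand", "start", "end", "position",
          "n_positions", "total_reads")]
}

#' Assign each read to the pA cluster containing its 3'-end position
#'
#' @param reads PASS-filtered read table.
#' @param clusters Output of [cluster_pa()].
#' @return Character vector of cluster ids, one per read. Errors if any read
#'   falls outside every cluster span (a clustering/counting mismatch).
#' @export
read_cluster_ids <- function(reads, clusters) {
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$position + 1L, width = 1L),
                               strand = reads$strand)
  cl <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start + 1L, clusters$end),
                               strand = clusters$strand)
  hit <- GenomicRanges::findOverlaps(gr, cl, select = "first")
  if (anyNA(hit)) stopf("%d reads fall outside all cluster spans", sum(is.na(hit)))
  clusters$cluster_id[hit]
}

#' Build the pA cluster x sample count matrix
#'
#' @param clusters Output of [cluster_pa()].
#' @param reads PASS-filtered read table with a `sample` column.
#' @param samples Sample (column) universe; defaults to the samples present
#'   in `reads`. Samples without reads yield all-zero columns.
#' @return Integer matrix, rows = cluster ids, columns = samples; per-sample
#'   column sums equal the per-sample PASS read counts.
#' @export
build_count_matrix <- function(clusters, reads, samples = sort(unique(reads$sample))) {
  ids <- read_cluster_ids(reads, clusters)
  m <- table(factor(ids, levels = clusters$cluster_id),
             factor(reads$sample, levels = samples))
  m <- matrix(as.integer(m), nrow = nrow(clusters),
              dimnames = list(clusters$cluster_id, samples))
  stopifnot(sum(m) == nrow(reads))
  m
}
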