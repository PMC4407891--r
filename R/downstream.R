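#' Bin genes by aUTR size and summarize RED per bin
#'
#' Genes are ordered by aUTR size (the distance between the top two pAs)
#' and split into quintile bins of (near-)equal size, ties resolved by the
#' stable gene-id order so bins stay balanced. The first (shortest-aUTR)
#' and fifth (longest) bins are compared with the two-sided Wilcoxon rank
#' sum test.
#'
#' @param df `data.frame` with columns `gene_id`, `autr_len`, `RED`
#'   (already filtered for read support).
#' @param n_bins Number of bins (default 5).
#' @return List: `bins` (per gene: bin), `summary` (per bin: n, aUTR range,
#'   mean and median RED), `p_bin1_vs_bin5`.
#' @export
autr_bin_red <- function(df, n_bins = 5) {
  if (nrow(df) < n_bins) stopf("need at least %d genes", n_bins)
  o <- order(df$autr_len, df$gene_id)
  bin <- integer(nrow(df))
  bin[o] <- ceiling(seq_len(nrow(df)) / (nrow(df) / n_bins))
  bin <- pmin(bin, n_bins)
  summary <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    r <- df[bin == b, ]
    data.frame(bin = b, n = nrow(r),
               autr_min = min(r$autr_len), autr_max = max(r$autr_len),
               mean_RED = mean(r$RED), median_RED = stats::median(r$RED))
  }))
  p <- suppressWarnings(stats::wilcox.test(df$RED[bin == 1],
                                           df$RED[bin == n_bins])$p.value)
  list(bins = data.frame(gene_id = df$gene_id, bin = bin, stringsAsFactors = FALSE),
       summary = summary, p_bin1_vs_bin5 = p)
}

#' Build a gene x contrast RED matrix with non-significant entries zeroed
#'
#' @param red_list Named list of [saap()] results (one per contrast) that
#'   share a `gene_id` column (e.g. top-2 events merged per gene).
#' @param q_threshold Entries with `q` above this are set to 0 before any
#'   distance computation.
#' @return Numeric matrix, rows = genes common to all contrasts, columns =
#'   contrasts.
#' @export
red_matrix <- function(red_list, q_threshold = 0.05) {
  genes <- Reduce(intersect, lapply(red_list, `[[`, "gene_id"))
  m <- vapply(red_list, function(r) {
    r <- r[match(genes, r$gene_id), ]
    ifelse(!is.na(r$q) & r$q <= q_threshold, r$RED, 0)
  }, numeric(length(genes)))
  rownames(m) <- genes
  m
}

#' Hierarchical clustering of RED profiles (1 - Pearson correlation)
#'
#' Columns (contrasts) and rows (genes) are clustered with average linkage
#' on `1 - r` distances. Rows with missing values and zero-variance rows or
#' columns (correlation undefined) are dropped and reported.
#'
#' @param mat RED matrix, e.g. from [red_matrix()].
#' @param cluster_rows Also cluster rows (set `FALSE` for large matrices).
#' @return List: `col_hclust`, `row_hclust` (or `NULL`), `dropped_cols`,
#'   `dropped_rows`, `mat` (the matrix actually clustered).
#' @export
cluster_red_profiles <- function(mat, cluster_rows = TRUE) {
  keep_row <- rowSums(is.na(mat)) == 0
  mat <- mat[keep_row, , drop = FALSE]
  colvar <- apply(mat, 2, stats::var)
  dropped_cols <- colnames(mat)[colvar == 0]
  mat <- mat[, colvar > 0, drop = FALSE]
  if (ncol(mat) < 2) stopf("need >= 2 columns with variance")
  dcol <- stats::as.dist(1 - stats::cor(mat))
  ch <- stats::hclust(dcol, method = "average")
  rh <- NULL
  dropped_rows <- rownames(mat)[apply(mat, 1, stats::var) == 0]
  if (cluster_rows) {
    rmat <- mat[apply(mat, 1, stats::var) > 0, , drop = FALSE]
    if (nrow(rmat) >= 2) {
      drow <- stats::as.dist(1 - stats::cor(t(rmat)))
      rh <- stats::hclust(drow, method = "average")
    }
  }
  list(col_hclust = ch, row_hclust = rh, dropped_cols = dropped_cols,
       dropped_rows = dropped_rows, mat = mat)
}

#' Partition genes into ten regulation groups from five-factor calls
#'
#' Groups 1-8 enumerate the direction pair of two primary factors
#' (shortening factor first): `Sh/Sh = 1`, `Sh/ns = 2`, `Sh/Le = 3`,
#' `ns/Sh = 4`, `ns/Le = 5`, `Le/Sh = 6`, `Le/ns = 7`, `Le/Le = 8`. Genes
#' unregulated by both primary factors go to group 9 when regulated by any
#' secondary factor, otherwise to group 10. The result is a partition of
#' the supplied universe.
#'
#' @param calls `data.frame` with columns `gene_id`, `factor`, `direction`
#'   (`"Le"`, `"Sh"` or `"ns"`); one row per gene and factor.
#' @param primary Two factor names, order defining the group numbering.
#' @param secondary Remaining factor names feeding group 9.
#' @param universe Gene ids to partition (default: all genes in `calls`).
#' @return `data.frame` with `gene_id` and `group` (1-10).
#' @export
assign_groups <- function(calls, primary, secondary,
                          universe = unique(calls$gene_id)) {
  dup <- calls[duplicated(calls[, c("gene_id", "factor")]) |
                 duplicated(calls[, c("gene_id", "factor")], fromLast = TRUE), ]
  if (nrow(dup) > 0) {
    agree <- all(vapply(split(dup$direction, paste(dup$gene_id, dup$factor)),
                        function(d) length(unique(d)) == 1, logical(1)))
    if (!agree) stopf("conflicting duplicate calls for a gene/factor pair")
  }
  get_dir <- function(f) {
    d <- calls$direction[calls$factor == f][match(universe, calls$gene_id[calls$factor == f])]
    d[is.na(d)] <- "ns"
    d
  }
  d1 <- get_dir(primary[1]); d2 <- get_dir(primary[2])
  key <- paste(d1, d2, sep = "/")
  map <- c("Sh/Sh" = 1L, "Sh/ns" = 2L, "Sh/Le" = 3L, "ns/Sh" = 4L, "ns/Le" = 5L,
           "Le/Sh" = 6L, "Le/ns" = 7L, "Le/Le" = 8L)
  group <- unname(map[key])
  rest <- is.na(group)
  any_secondary <- Reduce(`|`, lapply(secondary, function(f) get_dir(f) != "ns"))
  group[rest] <- ifelse(any_secondary[rest], 9L, 10L)
  data.frame(gene_id = universe, group = group, stringsAsFactors = FALSE)
}

#' Gene-set enrichment of a gene group (one-sided Fisher test)
#'
#' @param genes Character vector (the group of interest).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe All genes under consideration.
#' @return `data.frame`: per set the 2x2 margins, one-sided enrichment `P`
#'   and `neg_log10_P`.
#' @export
geneset_enrichment <- function(genes, gene_sets, universe) {
  if (length(universe) == 0) stopf("empty universe")
  genes <- intersect(genes, universe)
  out <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(genes, s))
    tab <- matrix(c(k, length(genes) - k,
                    length(s) - k, length(universe) - length(genes) - length(s) + k), 2)
    P <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, n_set = length(s), n_group = length(genes), overlap = k,
               P = P, neg_log10_P = -log10(P), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene expression changes from 3'-most exon reads (RPM)
#'
#' Gene expression is measured as reads mapped to pAs of the gene's 3'-most
#' exon, expressed per million total PASS reads of the sample. Genes need
#' more than `min_total` reads (both samples combined, strict inequality)
#' to report a log2 change.
#'
#' @param pa_ann Output of [classify_pa()].
#' @param counts Count matrix.
#' @param sample_test,sample_ctrl Column names.
#' @param min_total Read-support threshold (default 20, strict).
#' @return `data.frame`: `gene_id`, `reads_test`, `reads_ctrl`, `rpm_test`,
#'   `rpm_ctrl`, `log2_change`.
#' @export
gene_expression_change <- function(pa_ann, counts, sample_test, sample_ctrl,
                                   min_total = 20) {
  tot_t <- sum(counts[, sample_test]); tot_c <- sum(counts[, sample_ctrl])
  if (tot_t == 0 || tot_c == 0) stopf("a sample has zero total reads")
  utr <- pa_ann[pa_ann$pa_class == "utr3", ]
  ct <- rowsum(counts[utr$cluster_id, sample_test], utr$gene_id)[, 1]
  cc <- rowsum(counts[utr$cluster_id, sample_ctrl], utr$gene_id)[, 1]
  keep <- ct + cc > min_total
  ct <- ct[keep]; cc <- cc[keep]
  z <- ct == 0 | cc == 0
  lt <- ct + 0.5 * z; lc <- cc + 0.5 * z
  data.frame(gene_id = names(ct),
             reads_test = unname(ct), reads_ctrl = unname(cc),
             rpm_test = unname(1e6 * ct / tot_t), rpm_ctrl = unname(1e6 * cc / tot_c),
             log2_change = unname(log2((lt / tot_t) / (lc / tot_c))),
             stringsAsFactors = FALSE, row.names = NULL)
}
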