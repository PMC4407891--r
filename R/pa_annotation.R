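#' Intron ordinal labels
#'
#' Introns are labelled by position in the transcript: first (`"+1"`),
#' second (`"+2"`), last (`"-1"`), second-to-last (`"-2"`) and middle
#' (`"M"`). The scheme is defined for genes with at least 4 introns; for
#' shorter genes `NA` is returned and callers flag the event as excluded.
#'
#' @param intron_index 1-based intron index in transcript order.
#' @param intron_count Number of introns of the gene.
#' @return Character vector of labels (`NA` when `intron_count < 4`).
#' @export
assign_intron_ordinal <- function(intron_index, intron_count) {
  n <- max(length(intron_index), length(intron_count))
  intron_index <- rep_len(intron_index, n)
  intron_count <- rep_len(intron_count, n)
  bad <- !is.na(intron_index) & !is.na(intron_count) &
    (intron_index < 1 | intron_index > intron_count)
  if (any(bad)) stopf("intron_index outside 1..intron_count")
  out <- rep(NA_character_, n)
  ok <- !is.na(intron_index) & !is.na(intron_count) & intron_count >= 4
  out[ok & intron_index == 1] <- "+1"
  out[ok & intron_index == 2] <- "+2"
  out[ok & intron_index == intron_count] <- "-1"
  out[ok & intron_index == intron_count - 1 & intron_count > 1] <- "-2"
  out[ok & is.na(out)] <- "M"
  out
}

# merge exons of all transcripts of a gene and derive intron intervals with
# transcript-order indices
derive_gene_structure <- function(genes, exons) {
  ex_gr <- GenomicRanges::GRanges(exons$chrom,
                                  IRanges::IRanges(exons$start + 1L, exons$end),
                                  strand = exons$strand)
  merged <- GenomicRanges::reduce(S4Vectors::split(ex_gr, exons$gene_id))
  mex <- as.data.frame(unlist(merged))
  mex$gene_id <- rep(names(merged), S4Vectors::elementNROWS(merged))
  mex <- data.frame(gene_id = mex$gene_id, chrom = as.character(mex$seqnames),
                    strand = as.character(mex$strand),
                    start = mex$start - 1L, end = mex$end, stringsAsFactors = FALSE)
  introns <- lapply(split(mex, mex$gene_id), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    is <- e$end[-nrow(e)]; ie <- e$start[-1]
    idx <- if (e$strand[1] == "+") seq_along(is) else rev(seq_along(is))
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1], strand = e$strand[1],
               start = is, end = ie, intron_index = idx, n_introns = length(is),
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, introns[!vapply(introns, is.null, TRUE)])
  rownames(introns) <- NULL
  last <- do.call(rbind, lapply(split(mex, mex$gene_id), function(e) {
    e[if (e$strand[1] == "+") which.max(e$end) else which.min(e$start), ]
  }))
  rownames(last) <- NULL
  list(merged_exons = mex, introns = introns, last_exons = last)
}

#' Classify pA clusters against the gene annotation
#'
#' Each cluster receives exactly one structural class: `utr3` (in the
#' 3'-most exon of a same-strand gene), `internal_exon`, `intron`, `uaRNA`
#' (antisense within `ua_max_dist` of a TSS, overlapping no gene on its own
#' strand) or `intergenic`. Because TSS-proximal sense (spRNA) sites and
#' intronic sites overlap by construction, spRNA membership is carried as
#' the boolean `sp_flag` (sense, within `sp_max_dist` downstream of the TSS,
#' multi-exon host, not in the 3'-most exon) rather than as a class.
#'
#' @param clusters Output of [cluster_pa()].
#' @param annotation An `"apa_annotation"` or a list with `genes` and
#'   `exons` data frames.
#' @param ua_max_dist,sp_max_dist Distance cutoffs from the TSS (nt).
#' @return `data.frame`, one row per cluster: `cluster_id`, `gene_id`,
#'   `pa_class`, `sp_flag`, `ua_flag`, `tss_distance`, `intron_index`,
#'   `n_introns`, `intron_ordinal`, `ordinal_excluded`, `utr3_len`,
#'   `rank_in_utr3`, plus cluster geometry.
#' @export
classify_pa <- function(clusters, annotation, ua_max_dist = 2000L, sp_max_dist = 2000L) {
  genes <- annotation$genes
  exons <- annotation$exons
  if (is.null(exons) || nrow(exons) == 0) stopf("annotation has no exons")
  gs <- derive_gene_structure(genes, exons)
  n <- nrow(clusters)
  pts <- GenomicRanges::GRanges(clusters$chrom,
                                IRanges::IRanges(clusters$position + 1L, width = 1L),
                                strand = clusters$strand)
  genes_gr <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L, genes$end),
                                     strand = genes$strand)
  out <- data.frame(cluster_id = clusters$cluster_id, chrom = clusters$chrom,
                    strand = clusters$strand, position = clusters$position,
                    gene_id = NA_character_, pa_class = "intergenic",
                    sp_flag = FALSE, ua_flag = FALSE, tss_distance = NA_integer_,
                    intron_index = NA_integer_, n_introns = NA_integer_,
                    intron_ordinal = NA_character_, ordinal_excluded = FALSE,
                    utr3_len = NA_integer_, rank_in_utr3 = NA_integer_,
                    stringsAsFactors = FALSE)
  hit <- GenomicRanges::findOverlaps(pts, genes_gr, select = "first")
  hosted <- which(!is.na(hit))
  if (length(hosted) > 0) {
    gi <- hit[hosted]
    out$gene_id[hosted] <- genes$gene_id[gi]
    tss <- genes$tss[gi]
    pos <- clusters$position[hosted]
    d <- ifelse(genes$strand[gi] == "+", pos - tss, tss - pos)
    out$tss_distance[hosted] <- as.integer(d)
    lex <- gs$last_exons[match(genes$gene_id[gi], gs$last_exons$gene_id), ]
    in_lex <- pos >= lex$start & pos < lex$end
    out$pa_class[hosted[in_lex]] <- "utr3"
    out$utr3_len[hosted[in_lex]] <- as.integer(
      ifelse(lex$strand[in_lex] == "+", pos[in_lex] - lex$start[in_lex],
             lex$end[in_lex] - 1L - pos[in_lex]))
    # remaining hosted clusters: internal exon or intron
    rest <- hosted[!in_lex]
    if (length(rest) > 0) {
      mex_gr <- GenomicRanges::GRanges(gs$merged_exons$chrom,
                                       IRanges::IRanges(gs$merged_exons$start + 1L,
                                                        gs$merged_exons$end),
                                       strand = gs$merged_exons$strand)
      eh <- GenomicRanges::findOverlaps(pts[rest], mex_gr)
      ok <- gs$merged_exons$gene_id[S4Vectors::subjectHits(eh)] ==
        out$gene_id[rest][S4Vectors::queryHits(eh)]
      in_ex <- unique(S4Vectors::queryHits(eh)[ok])
      out$pa_class[rest[in_ex]] <- "internal_exon"
      intr <- setdiff(seq_along(rest), in_ex)
      if (length(intr) > 0 && !is.null(gs$introns)) {
        int_gr <- GenomicRanges::GRanges(gs$introns$chrom,
                                         IRanges::IRanges(gs$introns$start + 1L,
                                                          gs$introns$end),
                                         strand = gs$introns$strand)
        ih <- GenomicRanges::findOverlaps(pts[rest[intr]], int_gr)
        okm <- gs$introns$gene_id[S4Vectors::subjectHits(ih)] ==
          out$gene_id[rest[intr]][S4Vectors::queryHits(ih)]
        q <- S4Vectors::queryHits(ih)[okm]; s <- S4Vectors::subjectHits(ih)[okm]
        keep <- !duplicated(q)
        idx <- rest[intr][q[keep]]
        out$pa_class[idx] <- "intron"
        out$intron_index[idx] <- gs$introns$intron_index[s[keep]]
        out$n_introns[idx] <- gs$introns$n_introns[s[keep]]
      }
    }
    # spRNA flag: sense, close to the TSS, multi-exon host, not 3'-most exon
    nex <- stats::ave(gs$merged_exons$gene_id, gs$merged_exons$gene_id, FUN = length)
    nex <- as.integer(nex[match(genes$gene_id[gi], gs$merged_exons$gene_id)])
    out$sp_flag[hosted] <- d > 0 & d <= sp_max_dist & nex >= 2 &
      out$pa_class[hosted] != "utr3"
  }
  # uaRNA: antisense within ua_max_dist upstream of a TSS, no same-strand gene
  free <- which(is.na(hit))
  if (length(free) > 0) {
    ua_start <- ifelse(genes$strand == "+", genes$tss - ua_max_dist, genes$tss + 1L)
    ua_end <- ifelse(genes$strand == "+", genes$tss, genes$tss + ua_max_dist + 1L)
    ua_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(ua_start + 1L, ua_end),
                                    strand = ifelse(genes$strand == "+", "-", "+"))
    uh <- GenomicRanges::findOverlaps(pts[free], ua_gr)
    if (length(uh) > 0) {
      q <- S4Vectors::queryHits(uh); s <- S4Vectors::subjectHits(uh)
      d <- abs(clusters$position[free][q] - genes$tss[s])
      ord <- order(q, d)
      q <- q[ord]; s <- s[ord]; d <- d[ord]
      keep <- !duplicated(q)  # nearest TSS wins
      idx <- free[q[keep]]
      out$pa_class[idx] <- "uaRNA"
      out$ua_flag[idx] <- TRUE
      out$gene_id[idx] <- genes$gene_id[s[keep]]
      out$tss_distance[idx] <- -as.integer(d[keep])
    }
  }
  out$intron_ordinal <- assign_intron_ordinal(out$intron_index, out$n_introns)
  out$ordinal_excluded <- out$pa_class == "intron" & !is.na(out$n_introns) &
    out$n_introns < 4
  # rank utr3 pAs 5' -> 3' within each gene
  u <- which(out$pa_class == "utr3")
  if (length(u) > 0) {
    dd <- out$tss_distance[u]
    rk <- stats::ave(dd, out$gene_id[u], FUN = rank)
    out$rank_in_utr3[u] <- as.integer(rk)
  }
  out
}

event_focal <- function(event_type) {
  ifelse(event_type == "utr3_pair", "set2", "set1")
}

#' Build APA events from classified pA clusters
#'
#' @param pa_ann Output of [classify_pa()].
#' @param counts Count matrix from [build_count_matrix()] (used for
#'   abundance ranking).
#' @param mode One of `"top2_abundant"` (per gene, the two most abundant
#'   3'UTR pAs; set1 = proximal, set2 = distal), `"one_vs_rest"` (each 3'UTR
#'   pA vs the gene's other 3'UTR pAs), `"cds"` (all pAs upstream of the
#'   3'-most exon combined vs all 3'-most exon pAs), `"intronic_single"`
#'   (each intronic pA vs the gene's other sense pAs), `"uaRNA"` and
#'   `"spRNA"` (class set vs the gene's sense pAs beyond `tss_far` from the
#'   TSS).
#' @param tss_far Reference-set TSS distance cutoff for uaRNA/spRNA events.
#' @return `data.frame` with `event_id`, `gene_id`, `event_type`, list
#'   columns `set1`/`set2` of cluster ids, and geometry columns
#'   (`autr_len`, `proximal_pos`, `distal_pos`; intron columns for intronic
#'   events). Abundance ties are broken towards the 3'-most pA.
#' @export
build_events <- function(pa_ann, counts, mode = c("top2_abundant", "one_vs_rest",
                                                  "cds", "intronic_single",
                                                  "uaRNA", "spRNA"),
                         tss_far = 2000L) {
  mode <- match.arg(mode)
  tot <- rowSums(counts)[pa_ann$cluster_id]
  tot[is.na(tot)] <- 0
  pa <- cbind(pa_ann, total = tot)
  ev <- list()
  add <- function(gene_id, type, set1, set2, ...) {
    ev[[length(ev) + 1]] <<- data.frame(gene_id = gene_id, event_type = type,
                                        set1 = I(list(set1)), set2 = I(list(set2)),
                                        ..., stringsAsFactors = FALSE)
  }
  threeprime_order <- function(p) {
    # ascending 5' -> 3' in transcript orientation
    if (p$strand[1] == "+") order(p$position) else order(-p$position)
  }
  if (mode %in% c("top2_abundant", "one_vs_rest")) {
    utr <- pa[pa$pa_class == "utr3", ]
    for (g in split(utr, utr$gene_id)) {
      if (nrow(g) < 2) next
      if (mode == "top2_abundant") {
        tb <- if (g$strand[1] == "+") g$position else -g$position
        sel <- g[order(-g$total, -tb), ][1:2, ]
        sel <- sel[threeprime_order(sel), ]  # row 1 = proximal
        add(g$gene_id[1], "utr3_pair", sel$cluster_id[1], sel$cluster_id[2],
            autr_len = abs(sel$position[2] - sel$position[1]),
            proximal_pos = sel$position[1], distal_pos = sel$position[2],
            chrom = sel$chrom[1], strand = sel$strand[1])
      } else {
        for (i in seq_len(nrow(g)))
          add(g$gene_id[1], "utr3_one_vs_rest", g$cluster_id[i],
              g$cluster_id[-i], position = g$position[i],
              chrom = g$chrom[1], strand = g$strand[1])
      }
    }
  } else if (mode == "cds") {
    for (g in split(pa, pa$gene_id)) {
      up <- g$cluster_id[g$pa_class %in% c("intron", "internal_exon")]
      ref <- g$cluster_id[g$pa_class == "utr3"]
      if (length(up) > 0 && length(ref) > 0)
        add(g$gene_id[1], "cds", up, ref)
    }
  } else if (mode == "intronic_single") {
    for (g in split(pa, pa$gene_id)) {
      sense <- g[g$pa_class != "uaRNA", ]
      ipa <- sense[sense$pa_class == "intron", ]
      for (i in seq_len(nrow(ipa))) {
        others <- setdiff(sense$cluster_id, ipa$cluster_id[i])
        if (length(others) == 0) next
        add(g$gene_id[1], "intronic", ipa$cluster_id[i], others,
            intron_index = ipa$intron_index[i], n_introns = ipa$n_introns[i],
            intron_ordinal = ipa$intron_ordinal[i],
            ordinal_excluded = ipa$ordinal_excluded[i])
      }
    }
  } else {  # uaRNA / spRNA
    for (g in split(pa, pa$gene_id)) {
      focal <- if (mode == "uaRNA") g$cluster_id[g$pa_class == "uaRNA"]
        else g$cluster_id[g$sp_flag]
      ref <- g$cluster_id[g$pa_class != "uaRNA" & !g$sp_flag &
                            !is.na(g$tss_distance) & g$tss_distance > tss_far]
      if (length(focal) > 0 && length(ref) > 0)
        add(g$gene_id[1], mode, focal, ref)
    }
  }
  if (length(ev) == 0) {
    return(data.frame(event_id = character(), gene_id = character(),
                      event_type = character(), set1 = I(list()), set2 = I(list()),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, ev)
  ev$event_id <- sprintf("%s|%s|%d", ev$gene_id, ev$event_type,
                         stats::ave(seq_len(nrow(ev)), ev$gene_id, FUN = seq_along))
  ev[, c("event_id", setdiff(names(ev), "event_id"))]
}

#' Per-event counts for a two-sample comparison
#'
#' @param events Output of [build_events()].
#' @param counts Count matrix.
#' @param sample_test,sample_ctrl Column names; the test sample is sample a,
#'   the control sample b.
#' @return `data.frame` `event_id`, `a1`, `a2`, `b1`, `b2`: PASS reads of
#'   set1/set2 in test/control.
#' @export
event_counts <- function(events, counts, sample_test, sample_ctrl) {
  sum_set <- function(sets, col) {
    vapply(sets, function(s) sum(counts[s, col]), numeric(1))
  }
  data.frame(event_id = events$event_id,
             a1 = sum_set(events$set1, sample_test),
             a2 = sum_set(events$set2, sample_test),
             b1 = sum_set(events$set1, sample_ctrl),
             b2 = sum_set(events$set2, sample_ctrl),
             stringsAsFactors = FALSE)
}

#' Minimum-read filters for APA events
#'
#' Implements the three read-support rules used by the analyses:
#' `utr3_20_combined` keeps events with >= 20 PASS reads for both pA sets
#' and both samples combined; `intronic_10_combined` requires >= 10 reads
#' for the focal isoform over the two samples combined; `matrix_5_all`
#' requires every isoform to have >= 5 reads in every sample.
#'
#' @param ec Output of [event_counts()].
#' @param rule One of `"utr3_20_combined"`, `"intronic_10_combined"`,
#'   `"matrix_5_all"`.
#' @return Logical keep/drop vector.
#' @export
min_read_filter <- function(ec, rule = c("utr3_20_combined", "intronic_10_combined",
                                         "matrix_5_all")) {
  rule <- match.arg(rule)
  switch(rule,
         utr3_20_combined = ec$a1 + ec$a2 + ec$b1 + ec$b2 >= 20,
         intronic_10_combined = ec$a1 + ec$b1 >= 10,
         matrix_5_all = pmin(ec$a1, ec$a2, ec$b1, ec$b2) >= 5)
}
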