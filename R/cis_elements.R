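.pa_window_width <- c(U100_41 = 60L, U40_1 = 40L, D1_100 = 100L)

#' Genomic coordinates of a pA-relative window
#'
#' Windows are defined in transcript coordinates with the cleaved nucleotide
#' at position 0: `U100_41` covers -100..-41 nt, `U40_1` -40..-1 nt and
#' `D1_100` +1..+100 nt. Coordinates returned are 0-based half-open on the
#' genome; minus-strand windows mirror around the pA.
#'
#' @param position 0-based pA position (vectorized).
#' @param strand `"+"` or `"-"` (vectorized).
#' @param region Window name.
#' @return List with integer vectors `start` and `end`.
#' @export
pa_window_coords <- function(position, strand, region) {
  if (!region %in% names(.pa_window_width)) stopf("unknown window '%s'", region)
  plus <- strand == "+"
  s <- switch(region,
              U100_41 = ifelse(plus, position - 100L, position + 41L),
              U40_1 = ifelse(plus, position - 40L, position + 1L),
              D1_100 = ifelse(plus, position + 1L, position - 100L))
  list(start = as.integer(s), end = as.integer(s + .pa_window_width[[region]]))
}

#' Extract sense-oriented sequence windows around pAs
#'
#' For each pA the three windows `U100_41`, `U40_1` and `D1_100` are
#' extracted in transcript orientation (minus-strand windows are
#' reverse-complemented so "upstream" is always 5'-ward). Windows running
#' off a contig are flagged truncated and carry an `NA` sequence; counting
#' functions exclude them.
#'
#' @param pa `data.frame` with `cluster_id` (or `pa_id`), `chrom`,
#'   `position`, `strand`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param regions Window names to extract.
#' @return `data.frame` with columns `id`, `region`, `seq`, `truncated`.
#' @export
extract_windows <- function(pa, genome, regions = names(.pa_window_width)) {
  id_col <- if ("cluster_id" %in% names(pa)) "cluster_id" else "pa_id"
  if (!all(pa$chrom %in% names(genome))) stopf("pA off-contig: unknown chromosome")
  clen <- Biostrings::width(genome)[match(pa$chrom, names(genome))]
  out <- lapply(regions, function(rg) {
    co <- pa_window_coords(pa$position, pa$strand, rg)
    trunc <- co$start < 0 | co$end > clen
    seqs <- rep(NA_character_, nrow(pa))
    ok <- which(!trunc)
    if (length(ok) > 0) {
      v <- Biostrings::DNAStringSet(rep("", length(ok)))
      for (ch in unique(pa$chrom[ok])) {
        sel <- ok[pa$chrom[ok] == ch]
        v[match(sel, ok)] <- Biostrings::extractAt(
          genome[[ch]], IRanges::IRanges(co$start[sel] + 1L, co$end[sel]))
      }
      minus <- pa$strand[ok] == "-"
      if (any(minus)) v[minus] <- Biostrings::reverseComplement(v[minus])
      seqs[ok] <- as.character(v)
    }
    data.frame(id = pa[[id_col]], region = rg, seq = seqs, truncated = trunc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-sequence k-mer containment matrix (sequences x 4^k), excluding NA
kmer_contains <- function(seqs, k) {
  seqs <- seqs[!is.na(seqs)]
  m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs), width = k)
  m > 0
}

#' K-mer enrichment around pAs with signed significance scores
#'
#' Per region and k-mer, sequences containing at least one occurrence are
#' counted in foreground and background and compared with a two-sided
#' Fisher's exact test. The significance score is `SS = -log10(P) * S` with
#' `S = +1` for enrichment (foreground containment above background) and
#' `-1` for depletion, so `|SS| >= 3` corresponds to `P <= 0.001`.
#' Foreground and background should come from the same positional stratum
#' (proximal vs proximal, distal vs distal) and must not overlap.
#'
#' @param fg,bg Window tables from [extract_windows()].
#' @param k K-mer length (4 or 6).
#' @param regions Regions to test.
#' @return `data.frame`: `kmer`, `region`, `fg_with`, `fg_without`,
#'   `bg_with`, `bg_without`, `P`, `SS`.
#' @export
kmer_enrichment <- function(fg, bg, k = 4, regions = names(.pa_window_width)) {
  if (!k %in% c(4, 6)) stopf("k must be 4 or 6")
  if (length(intersect(fg$id, bg$id)) > 0)
    stopf("foreground and background pA sets overlap")
  out <- lapply(regions, function(rg) {
    fs <- fg$seq[fg$region == rg & !fg$truncated]
    bs <- bg$seq[bg$region == rg & !bg$truncated]
    if (length(fs) == 0 || length(bs) == 0) stopf("empty window set for region %s", rg)
    fm <- kmer_contains(fs, k)
    bm <- kmer_contains(bs, k)
    fw <- colSums(fm); bw <- colSums(bm)
    Fn <- nrow(fm); Bn <- nrow(bm)
    P <- vapply(seq_along(fw), function(i) {
      stats::fisher.test(matrix(c(fw[i], Fn - fw[i], bw[i], Bn - bw[i]), 2))$p.value
    }, numeric(1))
    S <- ifelse(fw / Fn >= bw / Bn, 1, -1)
    data.frame(kmer = colnames(fm), region = rg,
               fg_with = as.integer(fw), fg_without = as.integer(Fn - fw),
               bg_with = as.integer(bw), bg_without = as.integer(Bn - bw),
               P = P, SS = -log10(P) * S, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Nucleotide frequency profile around pAs
#'
#' @param pa pA table (`chrom`, `position`, `strand`).
#' @param genome A [Biostrings::DNAStringSet].
#' @param halfwidth Half-width of the profile window (nt); positions run
#'   from `-halfwidth` to `+halfwidth` with the pA at 0, in transcript
#'   orientation.
#' @return `data.frame` with columns `position`, `A`, `C`, `G`, `U`
#'   (frequencies summing to 1 at each position; T counted as U).
#' @export
nucleotide_profile <- function(pa, genome, halfwidth = 100) {
  clen <- Biostrings::width(genome)[match(pa$chrom, names(genome))]
  s <- pa$position - halfwidth
  e <- pa$position + halfwidth + 1L
  ok <- which(s >= 0 & e <= clen)
  if (length(ok) == 0) stopf("no extractable windows")
  v <- Biostrings::DNAStringSet(rep("", length(ok)))
  for (ch in unique(pa$chrom[ok])) {
    sel <- ok[pa$chrom[ok] == ch]
    v[match(sel, ok)] <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(s[sel] + 1L, e[sel]))
  }
  minus <- pa$strand[ok] == "-"
  if (any(minus)) v[minus] <- Biostrings::reverseComplement(v[minus])
  cm <- Biostrings::consensusMatrix(v, as.prob = TRUE, baseOnly = TRUE)
  data.frame(position = seq(-halfwidth, halfwidth),
             A = cm["A", ], C = cm["C", ], G = cm["G", ], U = cm["T", ],
             row.names = NULL)
}

#' Group 3'UTR pairs by pA distance and downstream AATAAA, compare REDs
#'
#' Pairs are split into four groups by (i) whether the proximal-to-distal
#' distance is below 120 nt and (ii) whether an exact AATAAA occurs on the
#' sense strand within +1..+100 nt downstream of the proximal pA:
#' group 1 = `<120 & AATAAA+`, 2 = `<120 & AATAAA-`, 3 = `>=120 & AATAAA+`,
#' 4 = `>=120 & AATAAA-`. Group RED distributions are compared pairwise
#' with the two-sided Kolmogorov-Smirnov test.
#'
#' @param pairs `data.frame` with `event_id`, `chrom`, `strand`,
#'   `proximal_pos`, `autr_len`, `RED`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param dist_cut Distance threshold (default 120 nt; `>=` goes to the far
#'   branch).
#' @return List: `assignments` (per pair: group, has_pas), `summary`
#'   (per-group n and median RED), `ks` (pairwise two-sided K-S D and P;
#'   pairs with an empty group are flagged and skipped).
#' @export
distance_pas_groups <- function(pairs, genome, dist_cut = 120) {
  win <- extract_windows(data.frame(cluster_id = pairs$event_id,
                                    chrom = pairs$chrom,
                                    position = pairs$proximal_pos,
                                    strand = pairs$strand,
                                    stringsAsFactors = FALSE),
                         genome, regions = "D1_100")
  has <- !win$truncated &
    Biostrings::vcountPattern("AATAAA",
                              Biostrings::DNAStringSet(ifelse(is.na(win$seq), "", win$seq))) > 0
  near <- pairs$autr_len < dist_cut
  group <- ifelse(near, ifelse(has, 1L, 2L), ifelse(has, 3L, 4L))
  summary <- do.call(rbind, lapply(1:4, function(g) {
    r <- pairs$RED[group == g]
    data.frame(group = g, n = length(r),
               median_RED = if (length(r) > 0) stats::median(r) else NA_real_)
  }))
  combos <- utils::combn(4, 2)
  ks <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    r1 <- pairs$RED[group == g1]; r2 <- pairs$RED[group == g2]
    if (length(r1) == 0 || length(r2) == 0) {
      return(data.frame(group1 = g1, group2 = g2, D = NA_real_, P = NA_real_,
                        skipped = TRUE))
    }
    kt <- suppressWarnings(stats::ks.test(r1, r2))
    data.frame(group1 = g1, group2 = g2, D = unname(kt$statistic),
               P = kt$p.value, skipped = FALSE)
  }))
  list(assignments = data.frame(event_id = pairs$event_id, group = group,
                                has_pas = has, stringsAsFactors = FALSE),
       summary = summary, ks = ks)
}
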