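#' Log2 expression change of intronic pA isoforms
#'
#' Depth-normalizes each isoform's PASS reads to reads-per-million (RPM) of
#' the sample's total and returns the log2 test/control ratio. Isoforms
#' need >= 10 reads over the two samples combined and a host gene with at
#' least 4 introns; the usual zero-handling pseudocount (+0.5 to both
#' counts when either is zero) keeps the ratio finite.
#'
#' @param events Intronic event table from
#'   [build_events()]`(mode = "intronic_single")`.
#' @param counts Count matrix.
#' @param sample_test,sample_ctrl Column names.
#' @param pseudocount `"haldane_zero"` or `"none"`.
#' @return `data.frame`: `event_id`, `gene_id`, `intron_ordinal`,
#'   `log2_change` for the isoforms passing both filters.
#' @export
intronic_change <- function(events, counts, sample_test, sample_ctrl,
                            pseudocount = c("haldane_zero", "none")) {
  pseudocount <- match.arg(pseudocount)
  tot_t <- sum(counts[, sample_test])
  tot_c <- sum(counts[, sample_ctrl])
  if (tot_t == 0 || tot_c == 0) stopf("a sample has zero total reads")
  focal <- vapply(events$set1, `[[`, character(1), 1)
  ct <- counts[focal, sample_test]
  cc <- counts[focal, sample_ctrl]
  keep <- (ct + cc >= 10) & !events$ordinal_excluded & !is.na(events$intron_ordinal)
  ct <- ct[keep]; cc <- cc[keep]
  z <- ct == 0 | cc == 0
  if (any(z)) {
    if (pseudocount == "none") stopf("zero count with pseudocount policy 'none'")
    ct <- ct + 0.5 * z; cc <- cc + 0.5 * z
  }
  data.frame(event_id = events$event_id[keep], gene_id = events$gene_id[keep],
             intron_ordinal = events$intron_ordinal[keep],
             log2_change = log2((ct / tot_t) / (cc / tot_c)),
             stringsAsFactors = FALSE)
}

.ordinal_levels <- c("+1", "+2", "M", "-2", "-1")

#' Intron-position bias profile of expression changes
#'
#' Averages log2 changes within the five intron ordinal groups and
#' mean-centers the group means (subtracting their across-group mean), so
#' the profile reveals positional bias independent of the overall shift.
#'
#' @param changes Output of [intronic_change()] (columns `intron_ordinal`,
#'   `log2_change`).
#' @return `data.frame`: per group `n`, `mean`, `centered`, `sem`. Empty
#'   groups are flagged via `n = 0`; at least two non-empty groups are
#'   required.
#' @export
position_bias <- function(changes) {
  g <- factor(changes$intron_ordinal, levels = .ordinal_levels)
  n <- as.integer(table(g))
  mean_ <- as.numeric(tapply(changes$log2_change, g, mean))
  sem <- as.numeric(tapply(changes$log2_change, g, function(x) sd(x) / sqrt(length(x))))
  if (sum(n > 0) < 2) stopf("need >= 2 non-empty ordinal groups")
  centered <- mean_ - mean(mean_[n > 0])
  data.frame(ordinal = .ordinal_levels, n = n, mean = mean_,
             centered = centered, sem = sem, stringsAsFactors = FALSE)
}

#' Background set of pA-containing introns from control samples
#'
#' Keeps intronic pA isoforms detectably expressed in control conditions:
#' relative abundance (isoform reads over the gene's total reads) >= `min_ra`
#' in at least two control samples and read count >= `min_reads` in at least
#' two control samples.
#'
#' @param pa_ann Output of [classify_pa()].
#' @param counts Count matrix.
#' @param control_samples At least two column names.
#' @param min_ra,min_reads Detection thresholds (defaults 5% and 2 reads).
#' @return Subset of `pa_ann` rows (intronic clusters) passing both rules.
#' @export
background_introns <- function(pa_ann, counts, control_samples,
                               min_ra = 0.05, min_reads = 2) {
  if (length(control_samples) < 2) stopf("need >= 2 control samples")
  intr <- pa_ann[pa_ann$pa_class == "intron" & !is.na(pa_ann$gene_id), ]
  cnt <- counts[intr$cluster_id, control_samples, drop = FALSE]
  gene_tot <- rowsum(counts[pa_ann$cluster_id, control_samples, drop = FALSE],
                     group = ifelse(is.na(pa_ann$gene_id), "<none>", pa_ann$gene_id))
  gt <- gene_tot[intr$gene_id, , drop = FALSE]
  ra <- cnt / pmax(gt, 1)
  keep <- rowSums(ra >= min_ra) >= 2 & rowSums(cnt >= min_reads) >= 2
  intr[keep, , drop = FALSE]
}

#' Signed Wilcoxon significance score for an intron feature
#'
#' Compares a feature (intron length, splice-site strength, ...) between a
#' foreground and a background intron set with the two-sided Wilcoxon rank
#' sum test and reports `SS = -log10(P) * S`, `S = +1` when the foreground
#' median exceeds the background median, `-1` otherwise. All-tied data give
#' `P = 1`, `SS = 0`.
#'
#' @param fg,bg Numeric feature vectors.
#' @return One-row `data.frame` with `n_fg`, `n_bg`, `P`, `S`, `SS`.
#' @export
feature_score <- function(fg, bg) {
  if (length(fg) == 0 || length(bg) == 0) stopf("fg and bg must be non-empty")
  if (length(unique(c(fg, bg))) == 1) {
    return(data.frame(n_fg = length(fg), n_bg = length(bg), P = 1, S = 0, SS = 0))
  }
  P <- suppressWarnings(stats::wilcox.test(fg, bg)$p.value)
  S <- if (stats::median(fg) > stats::median(bg)) 1 else -1
  data.frame(n_fg = length(fg), n_bg = length(bg), P = P, S = S, SS = -log10(P) * S)
}

#' Feature scores stratified by intron ordinal group
#'
#' Foreground introns are compared to background introns with the same
#' relative location in the gene (the same ordinal group).
#'
#' @param fg,bg `data.frame`s with an `intron_ordinal` column and the
#'   feature column named by `feature`.
#' @param feature Column name to compare.
#' @return `data.frame` with one row per ordinal group present in both sets.
#' @export
feature_score_by_ordinal <- function(fg, bg, feature) {
  groups <- intersect(.ordinal_levels,
                      intersect(fg$intron_ordinal, bg$intron_ordinal))
  out <- lapply(groups, function(g) {
    cbind(ordinal = g,
          feature_score(fg[[feature]][fg$intron_ordinal == g],
                        bg[[feature]][bg$intron_ordinal == g]))
  })
  do.call(rbind, out)
}
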