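#' Permute sample labels of two read sets
#'
#' Combines the reads of both sets and redistributes them without
#' replacement into two new sets of the original sizes. Each read keeps its
#' cluster identity; only the sample label is randomized, so the pooled
#' per-cluster count vector is preserved exactly.
#'
#' @param A,B Character vectors of per-read cluster ids.
#' @param seed Integer seed or `NULL`.
#' @return List with elements `A` and `B` of the original lengths.
#' @export
permute_readsets <- function(A, B, seed = NULL) {
  pool <- sort(c(A, B))  # draws depend on the multiset, not the read order
  n <- length(pool)
  if (n == 0) return(list(A = A, B = B))
  with_seed(seed, {
    idx <- sample.int(n)
    list(A = pool[idx[seq_along(A)]],
         B = pool[idx[seq_len(length(B)) + length(A)]])
  })
}

#' Bootstrap a read set to a fixed depth
#'
#' @param X Character vector of per-read cluster ids.
#' @param p Number of reads to draw with replacement.
#' @param seed Integer seed or `NULL`.
#' @return Character vector of length `p`.
#' @export
bootstrap_readset <- function(X, p, seed = NULL) {
  if (p <= 0) stopf("p must be > 0")
  if (length(X) == 0) stopf("cannot bootstrap an empty read set")
  X <- sort(X)  # draws depend on the multiset, not the read order
  with_seed(seed, X[sample.int(length(X), p, replace = TRUE)])
}

# per-cluster counts of a read set, over a fixed cluster universe
count_readset <- function(X, universe) {
  tabulate(factor(X, levels = universe), nbins = length(universe))
}

#' Global analysis of APA: bootstrap/permutation-normalized event counts
#'
#' Runs `n` rounds. In round i the observed pair is a bootstrap sample of
#' `p` reads from each of A and B; the expected pair is a bootstrap sample
#' of `p` reads from each half of a fresh label permutation of A and B.
#' Both pairs are tested with [saap()] and the significant events counted by
#' direction; the normalized count per direction is the per-round observed
#' minus expected count, averaged over rounds (mean floored at zero, as a
#' negative count of regulated events is not meaningful) with its SD.
#' `log2_ratio` is the log of the positive-direction over
#' negative-direction floored means; it is `Inf`/`-Inf` when one direction
#' is zero and `NA` when both are.
#'
#' @param A,B Character vectors of per-read cluster ids (A = test sample,
#'   B = control), e.g. from [read_cluster_ids()].
#' @param events Event table from [build_events()] over the cluster universe
#'   of A and B.
#' @param n Bootstrap rounds (default 20).
#' @param p Reads per bootstrap sample (default 5e4, a desk-scale depth).
#' @param m SAAP bootstrap replicates per round.
#' @param q_threshold Significance threshold for direction calls.
#' @param min_rule Per-round minimum-read rule (see [min_read_filter()]), or
#'   `NULL` for none.
#' @param seed Integer seed for the whole run.
#' @return List of class `"gaap_result"`: `summary` (per-direction
#'   normalized mean, SD, `log2_ratio`), `rounds` (per-round observed and
#'   expected counts, unfloored differences), `n_tested` (median number of
#'   tested events per round).
#' @export
gaap_run <- function(A, B, events, n = 20, p = 5e4, m = 20, q_threshold = 0.05,
                     min_rule = "utr3_20_combined", seed = 1) {
  if (n < 2) stopf("n must be >= 2")
  # work on integer cluster indices internally; reads from clusters outside
  # the event universe still occupy their share of the sampled depth
  universe <- sort(unique(c(A, B)))
  A <- sort(match(A, universe))
  B <- sort(match(B, universe))
  nbins <- length(universe) + 1L  # last bin collects event clusters absent from A/B
  idx_of <- function(sets) lapply(sets, function(s) {
    i <- match(s, universe)
    i[is.na(i)] <- nbins
    i
  })
  i1 <- idx_of(events$set1)
  i2 <- idx_of(events$set2)
  etype <- events$event_type
  focal <- if (all(etype == "utr3_pair")) "set2" else "set1"
  pos_lab <- if (focal == "set2") "Le" else "UP"
  neg_lab <- if (focal == "set2") "Sh" else "DN"
  ev_counts <- function(cntA, cntB) {
    data.frame(event_id = events$event_id,
               a1 = vapply(i1, function(i) sum(cntA[i]), numeric(1)),
               a2 = vapply(i2, function(i) sum(cntA[i]), numeric(1)),
               b1 = vapply(i1, function(i) sum(cntB[i]), numeric(1)),
               b2 = vapply(i2, function(i) sum(cntB[i]), numeric(1)),
               stringsAsFactors = FALSE)
  }
  one_side <- function(X1, X2, saap_seed) {
    ec <- ev_counts(tabulate(X1, nbins = nbins), tabulate(X2, nbins = nbins))
    if (!is.null(min_rule)) ec <- ec[min_read_filter(ec, min_rule), , drop = FALSE]
    res <- saap(ec, m = m, seed = saap_seed, focal = focal)
    sig <- !is.na(res$q) & res$q < q_threshold & !is.na(res$RED)
    c(pos = sum(sig & res$RED > 0), neg = sum(sig & res$RED < 0),
      tested = sum(!is.na(res$Zo)))
  }
  rounds <- with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      sds <- sample.int(2147483646, 4)
      a <- bootstrap_readset(A, p, seed = NULL)
      b <- bootstrap_readset(B, p, seed = NULL)
      obs <- one_side(a, b, sds[1])
      perm <- permute_readsets(A, B, seed = NULL)
      a2 <- bootstrap_readset(perm$A, p, seed = NULL)
      b2 <- bootstrap_readset(perm$B, p, seed = NULL)
      exp_ <- one_side(a2, b2, sds[2])
      out[[i]] <- data.frame(round = i,
                             obs_pos = obs[["pos"]], obs_neg = obs[["neg"]],
                             exp_pos = exp_[["pos"]], exp_neg = exp_[["neg"]],
                             tested_obs = obs[["tested"]],
                             tested_exp = exp_[["tested"]])
    }
    do.call(rbind, out)
  })
  rounds$diff_pos <- rounds$obs_pos - rounds$exp_pos
  rounds$diff_neg <- rounds$obs_neg - rounds$exp_neg
  mpos <- max(mean(rounds$diff_pos), 0)
  mneg <- max(mean(rounds$diff_neg), 0)
  lr <- if (mpos == 0 && mneg == 0) NA_real_
    else if (mneg == 0) Inf
    else if (mpos == 0) -Inf
    else log2(mpos / mneg)
  summary <- data.frame(direction = c(pos_lab, neg_lab),
                        norm_mean = c(mpos, mneg),
                        norm_sd = c(sd(rounds$diff_pos), sd(rounds$diff_neg)),
                        stringsAsFactors = FALSE)
  structure(list(summary = summary, log2_ratio = lr, rounds = rounds,
                 n_tested = stats::median(rounds$tested_obs)),
            class = "gaap_result")
}

#' @export
print.gaap_result <- function(x, ...) {
  cat("GAAP result over", nrow(x$rounds), "rounds;",
      x$n_tested, "events tested per round (median)\n")
  print(x$summary, row.names = FALSE)
  cat("log2(", x$summary$direction[1], "/", x$summary$direction[2], ") = ",
      format(x$log2_ratio, digits = 4), "\n", sep = "")
  invisible(x)
}
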