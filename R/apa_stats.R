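#' Relative expression difference (RED)
#'
#' RED is the difference between two samples in the log2 ratio of the two
#' isoform read counts: `log2(a2/a1) - log2(b2/b1)`, where `a1`,`a2` are the
#' set1/set2 counts in the test sample and `b1`,`b2` in the control. With
#' set2 the distal 3'UTR pA, positive RED means the distal isoform is up in
#' the test sample (3'UTR lengthening). RED is antisymmetric under swapping
#' samples and invariant to per-sample depth scaling.
#'
#' The `"haldane_zero"` pseudocount policy adds 0.5 to all four counts of an
#' observation only when at least one of them is zero, keeping RED finite
#' while leaving zero-free observations untouched; `"none"` refuses zeros.
#'
#' @param a1,a2,b1,b2 Non-negative counts (vectorized).
#' @param pseudocount `"haldane_zero"` or `"none"`.
#' @return Numeric RED values.
#' @export
red <- function(a1, a2, b1, b2, pseudocount = c("haldane_zero", "none")) {
  pseudocount <- match.arg(pseudocount)
  z <- a1 == 0 | a2 == 0 | b1 == 0 | b2 == 0
  if (any(z)) {
    if (pseudocount == "none") stopf("zero count with pseudocount policy 'none'")
    a1 <- a1 + 0.5 * z; a2 <- a2 + 0.5 * z; b1 <- b1 + 0.5 * z; b2 <- b2 + 0.5 * z
  }
  log2(a2 / a1) - log2(b2 / b1)
}

#' Significance analysis of APA events (bootstrap randomization test)
#'
#' For each event the pooled relative abundance of the two pA sets across
#' both samples defines a null in which both samples share the same isoform
#' proportions. `m` bootstrap replicates redraw each sample's counts as a
#' two-category multinomial of its observed total under that pooled
#' abundance; the replicate (expected) RED scores provide a per-event mean
#' and SD used to standardize the observed and expected REDs to `Zo` and
#' `Ze`. The FDR at a cutoff `Zc` is `(#\{|Ze| >= Zc\} / m) / #\{|Zo| >= Zc\}`
#' over the whole event collection (capped at 1), and an event's q-value is
#' the FDR at `Zc = |Zo|`, made monotone non-increasing in `|Zo|` by a
#' cumulative minimum.
#'
#' RED is oriented so that positive values mean the focal pA set is up in
#' the test sample: the focal set is set2 (distal) for 3'UTR pairs and set1
#' for cds/intronic/uaRNA/spRNA events (`focal = "set1"`).
#'
#' @param ec Event counts from [event_counts()] (test sample = a).
#' @param m Number of bootstrap replicates (default 20).
#' @param seed Integer seed; replicate draws are keyed to the sorted event
#'   ids, so results do not depend on event order.
#' @param pseudocount Passed to [red()].
#' @param focal `"set2"` (default; 3'UTR pairs) or `"set1"`.
#' @return `data.frame`: `event_id`, the four counts, `RED`, `mu_exp`,
#'   `sd_exp` (bootstrap-null mean/SD of RED), `Zo`, `q`. Events with an
#'   all-zero sample or zero null SD are untestable (`Zo = NA`, `q = 1`).
#' @export
saap <- function(ec, m = 20, seed = NULL,
                 pseudocount = c("haldane_zero", "none"), focal = c("set2", "set1")) {
  pseudocount <- match.arg(pseudocount)
  focal <- match.arg(focal)
  if (m < 2) stopf("m must be >= 2")
  ord <- order(ec$event_id)
  e <- ec[ord, ]
  E <- nrow(e)
  sgn <- if (focal == "set2") 1 else -1
  na <- e$a1 + e$a2
  nb <- e$b1 + e$b2
  testable <- na > 0 & nb > 0
  RED <- rep(NA_real_, E)
  RED[testable] <- sgn * red(e$a1[testable], e$a2[testable],
                             e$b1[testable], e$b2[testable], pseudocount)
  mu <- rep(NA_real_, E); sdv <- rep(NA_real_, E)
  Ze <- NULL
  if (any(testable)) {
    t_idx <- which(testable)
    Et <- length(t_idx)
    p2 <- (e$a2[t_idx] + e$b2[t_idx]) / (na[t_idx] + nb[t_idx])
    rep_red <- with_seed(seed, {
      a2s <- matrix(rbinom(Et * m, rep(na[t_idx], m), rep(p2, m)), Et, m)
      b2s <- matrix(rbinom(Et * m, rep(nb[t_idx], m), rep(p2, m)), Et, m)
      sgn * red(rep(na[t_idx], m) - a2s, a2s, rep(nb[t_idx], m) - b2s, b2s,
                pseudocount)
    })
    dim(rep_red) <- c(Et, m)
    mu[t_idx] <- rowMeans(rep_red)
    sdv[t_idx] <- sqrt(rowSums((rep_red - mu[t_idx])^2) / (m - 1))
    ok <- t_idx[sdv[t_idx] > 0]
    Zo <- rep(NA_real_, E)
    Zo[ok] <- (RED[ok] - mu[ok]) / sdv[ok]
    Ze <- (rep_red[match(ok, t_idx), , drop = FALSE] - mu[ok]) / sdv[ok]
  } else {
    Zo <- rep(NA_real_, E)
  }
  q <- rep(1, E)
  ok <- which(!is.na(Zo))
  if (length(ok) > 0) {
    absZo <- abs(Zo[ok])
    s_ze <- sort(abs(as.vector(Ze)))
    s_zo <- sort(absZo)
    nze <- length(s_ze); nzo <- length(s_zo)
    # counts with >= (the event itself is in the denominator)
    num <- (nze - findInterval(absZo - 1e-12, s_ze)) / m
    den <- nzo - findInterval(absZo - 1e-12, s_zo)
    qq <- pmin(num / den, 1)
    o <- order(-absZo)
    qq[o] <- rev(cummin(rev(qq[o])))
    q[ok] <- qq
  }
  res <- data.frame(event_id = e$event_id, a1 = e$a1, a2 = e$a2, b1 = e$b1,
                    b2 = e$b2, RED = RED, mu_exp = mu, sd_exp = sdv,
                    Zo = Zo, q = q, stringsAsFactors = FALSE)
  res <- res[match(ec$event_id, res$event_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Direction calls for tested events
#'
#' Events with `q` below the threshold are labelled by the sign of RED:
#' `Le` (lengthened, distal up) / `Sh` (shortened) for 3'UTR pair events,
#' `UP` / `DN` (focal set up / down) for all other event types; others get
#' `ns`.
#'
#' @param res Output of [saap()].
#' @param event_type Scalar or per-event vector of event types.
#' @param q_threshold Significance threshold (0.05 default; 0.1 for the
#'   regulation-group analyses).
#' @return `res` with columns `significant` and `direction` added.
#' @export
call_direction <- function(res, event_type = "utr3_pair", q_threshold = 0.05) {
  event_type <- rep_len(event_type, nrow(res))
  sig <- !is.na(res$q) & res$q < q_threshold & !is.na(res$RED)
  pos <- ifelse(event_type == "utr3_pair", "Le", "UP")
  neg <- ifelse(event_type == "utr3_pair", "Sh", "DN")
  res$significant <- sig
  res$direction <- ifelse(!sig, "ns", ifelse(res$RED > 0, pos, neg))
  res
}

#' Top two most significantly regulated 3'UTR isoforms per gene
#'
#' Operates on one-vs-rest results: per gene, the two pAs with the smallest
#' q-value are selected, ties broken by larger `|Zo|`, then towards the
#' 3'-most position.
#'
#' @param res Output of [saap()] on one-vs-rest events.
#' @param events The matching [build_events()] table (supplies `gene_id`,
#'   `position`, `strand`).
#' @return Subset of `res` (two rows per eligible gene) with `gene_id` and
#'   `position` attached; genes with fewer than two tested isoforms are
#'   skipped.
#' @export
top2_regulated <- function(res, events) {
  stopifnot(identical(res$event_id, events$event_id))
  df <- cbind(res, events[, c("gene_id", "position", "strand")])
  df <- df[!is.na(df$Zo), ]
  picked <- lapply(split(df, df$gene_id), function(g) {
    if (nrow(g) < 2) return(NULL)
    tb <- if (g$strand[1] == "+") g$position else -g$position
    g[order(g$q, -abs(g$Zo), -tb), ][1:2, ]
  })
  out <- do.call(rbind, picked[!vapply(picked, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
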