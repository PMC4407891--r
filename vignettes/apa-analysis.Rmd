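---
title: "Quantifying alternative polyadenylation from 3' end read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternative polyadenylation from 3' end read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apakit)
```

## The measurement model

3' end sequencing reads a short fragment ending at the cleavage/
polyadenylation site (pA) of an mRNA. After alignment, a read whose 5' end
retains at least 2 Ts that did not align to the genome evidences a genuine
poly(A) junction and is called a PASS read; reads with fewer unaligned Ts
are treated as internal-priming artifacts and discarded. `apakit` models
the per-gene PASS counts as multinomial across the gene's pAs: a sample's
reads for a gene distribute over its isoforms according to usage
proportions, and all inference below conditions on observed totals. This
is the natural model for count data from a fixed sequencing depth and is
the one assumption every test in the package leans on; biological
replicate-to-replicate dispersion is *not* modelled (the package addresses
two-sample designs without replicates, as 3' end screens of many
knockdowns typically are).

Cleavage is microheterogeneous, so observed 3'-end positions scatter
around each site. Positions on the same chromosome and strand are chained
into pA clusters whenever consecutive positions lie within 24 nt
(single linkage, so a cluster's span can exceed 24 nt through chaining —
the rule bounds gaps, not spans). The cluster representative is the modal
position; ties break toward the 3'-most position w.r.t. strand, since the
most-3' cleavage best represents the mature end. Clustering
representatives again reproduces the clusters (adjacent representatives
are separated by more than the gap limit by construction), which the test
suite asserts as an invariant.

## RED, SAAP and the randomization FDR

For an isoform pair (proximal pA1, distal pA2) with counts
$(a_1, a_2)$ in the test sample and $(b_1, b_2)$ in the control, the
relative expression difference is

$$\mathrm{RED} = \log_2\frac{a_2}{a_1} - \log_2\frac{b_2}{b_1},$$

the log odds-ratio of isoform usage between samples: antisymmetric under
sample swap, invariant to per-sample depth, positive when the distal
isoform gains (3'UTR lengthening). For event classes where set 1 is the
focal class (CDS/intronic pAs, uaRNAs, spRNAs compared to a reference
set), RED is computed as log2(focal/other), so a positive score always
means the focal set is up — one sign convention for every event type
(`saap(..., focal =)`).

SAAP asks whether an observed RED exceeds what pure counting noise would
produce if both samples shared the same isoform proportions. The pooled
relative abundance $\hat p = (a_2+b_2)/(a_1+a_2+b_1+b_2)$ defines that
null; each of $m$ replicates redraws both samples as binomials of their
observed totals at $\hat p$, giving expected REDs whose per-event mean and
SD standardize observed and expected scores to $Z_o$ and $Z_e$. The
randomization FDR at a cutoff $Z_c$ is

$$\mathrm{FDR}(Z_c) = \frac{\#\{|Z_e| \ge Z_c\}/m}{\#\{|Z_o| \ge Z_c\}}$$

counted over the whole event collection, and an event's q-value is the FDR
at its own $|Z_o|$. Numerical choices, each motivated by a degenerate case:

* **Pseudocount.** 0.5 is added to all four counts *only when one of them
  is zero* (a Haldane-style correction), identically for observed and
  replicate counts. Zero-free events are untouched, so the algebraic
  identities of RED (antisymmetry, depth invariance) hold exactly where
  defined.
* **Boundary of the counts.** Both exceedance counts use $\ge$, so an
  event is counted at its own threshold; a strict inequality would leave
  the top-ranked event with a zero denominator.
* **Monotone q.** The raw FDR curve need not be monotone; q-values are
  made non-increasing in $|Z_o|$ by a cumulative minimum from the least
  significant end (standard q-value hygiene, so a stricter score never
  earns a worse q).
* **Untestable events.** An event with an all-zero sample or zero null SD
  (e.g. a fixed 0/N split) has no standardized score; it is reported with
  $Z_o=$ NA and q = 1 rather than dropped, keeping the event universe
  stable.
* **Standardization scope.** Each event is standardized by its *own* m
  replicates (pooling across events would mix very different count depths
  into one scale). With m = 20 the SD estimate is noisy, which fattens the
  tails of both $Z_o$ and $Z_e$ equally — the FDR ratio is self-calibrating
  in this respect, and the null-calibration test (2,000 null events, q <
  0.05 rate ≤ 10%) pins it down empirically.
* **Replicate draws** are keyed to the sorted event ids under one seeded
  generator per `saap()` call, so results are independent of event order.

$m$ defaults to 20 and is configurable; the oracle test raises it to
10,000 and checks the bootstrap-null mean/SD of RED against exhaustive
enumeration of the two binomials on small events.

## GAAP: depth-matched normalization of event counts

Comparing counts of significant events across sample pairs is confounded
by sequencing depth and by the number of chance rejections. GAAP runs $n$
rounds (default 20); in each, an observed pair is bootstrapped to exactly
$p$ PASS reads per sample from the two read sets, and an expected pair is
bootstrapped from a *fresh* label permutation of the pooled reads (the
permutation preserves each set's size and the pooled per-cluster counts
exactly). SAAP runs on both pairs, and the round's normalized count per
direction is observed − expected. Design choices:

* **Pairing.** Round $i$'s observed and expected counts are subtracted
  pairwise, and the SD over rounds of that paired difference is the error
  bar — this is what "SD over n bootstraps" means here.
* **Flooring.** The *mean* normalized count is floored at zero (a negative
  count of regulated genes is not meaningful); per-round differences are
  kept unfloored in the output for diagnostics.
* **`log2(Le/Sh)`** uses the floored means, with ±Inf when exactly one
  direction is zero and NA when both are.
* **Fresh permutations per round** (the permutation count equals $n$)
  rather than one global permutation: each round then contributes an
  independent draw of the expected count.
* **Read sampling, not gene sampling.** Bootstrap and permutation operate
  on reads (each read keeping its cluster identity); outputs are invariant
  to read and cluster ordering because the samplers act on sorted
  multisets.

The default bootstrap size for synthetic work is $p = 5\times10^4$. For
recovery experiments the package's simulations scale $p$ to keep
*per-gene* coverage near what a production 3' end dataset provides
(~1.5 M PASS reads over ~10^4 expressed genes ≈ 150 reads/gene): with
1,000 synthetic genes that is $p = 1.5\times10^5$. At ~50 reads/gene a
4-fold usage shift is detected in only ~60% of genes — an honest property
of the statistic at that depth, not a defect — so the recovery scenario is
run at the production-equivalent depth while the exchangeability-null
scenario (which is depth-insensitive) uses $p = 5\times10^4$.

## Classification geometry

Coordinates are 0-based half-open throughout; a pA position is the cleaved
nucleotide, and BED/GTF writers convert at the boundary. Each cluster gets
exactly one *structural* class — 3'-most exon (`utr3`), `internal_exon`,
`intron`, antisense-upstream (`uaRNA`), or `intergenic` — by precedence of
overlap with the merged exons of all the gene's transcripts. TSS-proximal
sense sites (spRNA: sense, 0 < TSS distance ≤ 2 kb, multi-exon host, not
in the 3'-most exon) are carried as a boolean flag rather than a class,
because intronic sites near the TSS are legitimately both intronic and
spRNA and the two analyses select non-exclusively. uaRNA assignment
requires no same-strand gene overlap and takes the nearest TSS within
2 kb; a gene's TSS is its 5'-most annotated start. Intron ordinals
(+1, +2, M, −2, −1) are defined for genes with ≥ 4 introns; others are
flagged excluded. In top-2 event construction, abundance ties break toward
the 3'-most pA (deterministic and biased toward the longer isoform, which
is the reference direction of the RED sign convention).

## Windows, k-mers and feature scores

Sequence windows around a pA are defined in transcript coordinates with
the cleaved nucleotide at position 0: −100..−41, −40..−1 and +1..+100 nt
(position 0 itself belongs to no window). On the plus strand with the pA
at genomic $g$, the −40..−1 window is $[g-40, g)$; minus-strand windows
mirror and reverse-complement, so "upstream" is always transcript 5'-ward.
Windows running off a contig are flagged truncated and excluded from
counting. K-mer tests use per-sequence *containment* (≥ 1 occurrence) in a
2×2 Fisher exact test — two-sided, since both enrichment and depletion are
of interest — with the signed score $SS = -\log_{10}(P)\,S$, $S$ from the
containment-rate direction; $|SS| \ge 3 \iff P \le 10^{-3}$. Foreground
sets are removed from their background (exclusive background), and
foreground/background should come from the same positional stratum
(proximal vs proximal, distal vs distal) so positional base composition
does not masquerade as a factor-specific element. The AAUAAA search in the
distance-grouping analysis is an exact AATAAA match on the sense strand in
+1..+100 of the proximal pA (no variants); the distance boundary is
< 120 vs ≥ 120 nt.

Intron feature scores use the two-sided Wilcoxon rank-sum test with
$S = +1$ when the foreground median exceeds the background median,
stratified by intron ordinal so "first introns" are compared to first
introns. Splice-site strengths are consumed as numeric columns — the
generator draws them from normal distributions; real analyses would import
maximum-entropy scores computed externally. All-tied inputs return P = 1,
SS = 0. Intron intervals derive from the union of all transcripts' exons
per gene.

## What the generator emulates — and what it does not

`sim_config()` builds non-overlapping gene models on one synthetic
chromosome with ≥ 2 kb flanks (both strands), each with tandem 3'UTR pAs
(spacing = the aUTR size, default 150–1,500 nt), optional intronic pAs,
antisense pAs at truncated-normal distances peaking near 700 nt upstream
of the TSS, and sense pAs inside intron 1 within 2 kb. Control usage is
Dirichlet (gamma weights 8/2/1.5 for 3'UTR / intronic / promoter-proximal
pAs, making non-3'UTR isoforms minor as in real cells); planted effects
multiply usage *odds* by a fold change and renormalize, so a 4-fold
proximal shift turns 50/50 into 80/20. Reads carry ±8 nt uniform jitter
(inside one 24-nt cluster, exercising the chaining rule), unaligned-T
counts ≥ 2, and an optional decoy fraction with < 2 Ts. Gene abundances
are log-normal (sdlog 0.5, a deliberately narrow desk-scale spread);
per-sample overdispersion is available but off by default because the
tests are multinomial-conditional.

The generator does **not** emulate sequencing error, alignment ambiguity,
genomic A-rich internal priming (the T-count filter is the only artifact
model, matching the processing contract), overlapping genes, multiple
transcription start sites, or replicate-level biological noise. Passing
tests therefore demonstrate that the statistics behave as designed under
their own model assumptions — calibration under exchangeability, power
against planted odds shifts, geometric correctness — not that any
particular biological dataset will meet those assumptions.

## Problem sizes and runtime posture

The shipped tests and the acceptance script use desk-scale sizes chosen to
make every Monte-Carlo assertion stable: 2,000 events for null
calibration; 20 replicate simulations for power; 1,000 genes with
$p = 5\times10^4$ (null) or $1.5\times10^5$ (recovery) and n = 20 rounds
for GAAP; 200 + 1,000 pAs for k-mer specificity; 300 genes with ≥ 4
introns for position bias; 250 genes × 4 conditions for RED-profile
clustering. The production-scale settings of the statistics
($p = 1.5\times10^6$, genome-wide annotations) are plain parameter
changes.

## Known limitations

* Two-sample comparisons only; no replicate-aware shrinkage or multi-way
  designs.
* The randomization FDR is granular at m = 20: attainable q-values near a
  target threshold come in steps of $1/(20\cdot\#\text{events})$, and
  abundant true signal relaxes the implied $|Z_o|$ threshold (more
  lenient false-positive behaviour when many events are regulated).
* Single-isoform-pair geometry per gene in the top-2 mode; genes with
  complex pA repertoires are summarized by their two dominant isoforms.
* uaRNA/spRNA classification is annotation-driven; unannotated TSSs will
  misclassify promoter-proximal transcription.
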