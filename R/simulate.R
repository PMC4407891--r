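#' Simulation configuration for synthetic 3' end sequencing data
#'
#' Builds the configuration object consumed by [simulate_annotation()],
#' [simulate_usage()] and [simulate_pass_reads()]. The generator emulates the
#' data structure of a 3' end sequencing experiment: multi-exon gene models on
#' both strands, a poly(A) site (pA) repertoire per gene (tandem 3'UTR sites,
#' optional intronic sites, upstream-antisense and TSS-proximal sense sites),
#' per-condition usage proportions with planted knockdown-style effects, and
#' reads whose 3' ends carry an unaligned-T count.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(lo, hi)` of exon counts.
#' @param exon_len Integer range of exon lengths (nt).
#' @param intron_len Integer range of intron lengths (nt).
#' @param utr3_pa_count Number of tandem pAs in the 3'-most exon (>= 1).
#' @param autr_len Integer range for the spacing between consecutive 3'UTR
#'   pAs (the alternative-UTR size), in nt.
#' @param utr3_offset Distance from the 3'-most exon start to the first pA (nt).
#' @param utr3_flank Sequence retained downstream of the last pA inside the
#'   3'-most exon (nt).
#' @param frac_intronic_pa,frac_ua_pa,frac_sp_pa Proportions of (eligible)
#'   genes receiving an intronic pA, an upstream-antisense (uaRNA) pA, and a
#'   TSS-proximal sense (spRNA) pA.
#' @param ua_distance Mean and SD of the (truncated-normal) distance of uaRNA
#'   pAs upstream of the TSS; the default mode near 700 nt reflects the
#'   typical promoter-upstream antisense cleavage distance.
#' @param depth_per_sample Total reads emitted per sample.
#' @param decoy_frac Fraction of reads emulating internal priming, emitted
#'   with fewer than 2 unaligned Ts so they fail the PASS filter.
#' @param unaligned_t_range Range of unaligned-T counts for genuine pA reads
#'   (all >= 2).
#' @param jitter Half-width (nt) of the discrete uniform positional jitter
#'   applied to each read 3' end around its true pA.
#' @param gene_abund_sdlog SD of the log-normal gene abundance distribution.
#' @param overdispersion Per-sample multiplicative gamma noise on gene
#'   abundances (0 disables; the read-count model is then plain multinomial).
#' @param samples `data.frame` with columns `sample` and `condition`
#'   (conditions `"ctrl"` and `"test"`).
#' @param effect_table List of [planted_effect()] entries.
#' @param motif_table List of [planted_motif()] entries.
#' @param make_genome Generate the genome sequence (disable to save time when
#'   only counts are needed).
#' @param seed Integer seed; all stages derive their own deterministic
#'   sub-streams from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 100,
                       exons_per_gene = c(4, 8),
                       exon_len = c(120, 300),
                       intron_len = c(200, 2000),
                       utr3_pa_count = 2,
                       autr_len = c(150, 1500),
                       utr3_offset = 100,
                       utr3_flank = 200,
                       frac_intronic_pa = 0.3,
                       frac_ua_pa = 0.3,
                       frac_sp_pa = 0.2,
                       ua_distance = c(mean = 700, sd = 300),
                       depth_per_sample = 5e4,
                       decoy_frac = 0,
                       unaligned_t_range = c(2, 8),
                       jitter = 8,
                       gene_abund_sdlog = 0.5,
                       overdispersion = 0,
                       samples = NULL,
                       effect_table = list(),
                       motif_table = list(),
                       make_genome = TRUE,
                       seed = 1) {
  if (is.null(samples)) {
    samples <- data.frame(sample = c("ctrl", "test"),
                          condition = c("ctrl", "test"),
                          stringsAsFactors = FALSE)
  }
  cfg <- list(n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
              utr3_pa_count = as.integer(utr3_pa_count), autr_len = as.integer(autr_len),
              utr3_offset = as.integer(utr3_offset), utr3_flank = as.integer(utr3_flank),
              frac_intronic_pa = frac_intronic_pa, frac_ua_pa = frac_ua_pa,
              frac_sp_pa = frac_sp_pa, ua_distance = ua_distance,
              depth_per_sample = depth_per_sample, decoy_frac = decoy_frac,
              unaligned_t_range = as.integer(unaligned_t_range), jitter = as.integer(jitter),
              gene_abund_sdlog = gene_abund_sdlog, overdispersion = overdispersion,
              samples = samples, effect_table = effect_table, motif_table = motif_table,
              make_genome = isTRUE(make_genome), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && !anyNA(r) && r[1] <= r[2]
  if (cfg$n_genes < 1) stopf("n_genes must be >= 1")
  for (f in c("exons_per_gene", "exon_len", "intron_len", "autr_len", "unaligned_t_range"))
    if (!rng_ok(cfg[[f]])) stopf("range '%s' must be a non-empty c(lo, hi)", f)
  if (cfg$exons_per_gene[1] < 1) stopf("genes need at least one exon")
  if (cfg$intron_len[1] < 1) stopf("introns shorter than 1 nt are impossible")
  if (cfg$exon_len[1] < 1) stopf("exons shorter than 1 nt are impossible")
  if (cfg$utr3_pa_count < 1) stopf("utr3_pa_count must be >= 1")
  for (f in c("frac_intronic_pa", "frac_ua_pa", "frac_sp_pa", "decoy_frac")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stopf("proportion '%s' must lie in [0, 1]", f)
  }
  if (cfg$depth_per_sample <= 0) stopf("depth_per_sample must be > 0")
  if (cfg$unaligned_t_range[1] < 2) stopf("genuine pA reads carry >= 2 unaligned Ts")
  if (!all(c("sample", "condition") %in% names(cfg$samples)))
    stopf("samples needs columns 'sample' and 'condition'")
  if (!all(cfg$samples$condition %in% c("ctrl", "test")))
    stopf("conditions must be 'ctrl' or 'test'")
  invisible(cfg)
}

#' Planted usage effect
#'
#' Describes a condition-specific shift of pA usage for a subset of genes:
#' the usage odds of the targeted pA are multiplied by `fold_change` in the
#' test condition and the gene's proportions renormalized.
#'
#' @param gene_subset Character gene ids, or a single integer n meaning the
#'   first n eligible genes (in gene-id order).
#' @param event_class One of `"utr3_shift"`, `"intronic_up"`, `"ua_up"`,
#'   `"sp_up"`.
#' @param fold_change Positive odds ratio applied in the test condition.
#' @param direction `"proximal_up"`/`"distal_up"` for `utr3_shift`;
#'   `"up"`/`"down"` for the single-site classes.
#' @param ordinal Optional intron-ordinal labels (e.g. `c("+1","+2")`)
#'   restricting `intronic_up` targets to pAs in those introns.
#' @return A list of class `"planted_effect"`.
#' @export
planted_effect <- function(gene_subset, event_class, fold_change,
                           direction = c("up", "down", "proximal_up", "distal_up"),
                           ordinal = NULL) {
  direction <- match.arg(direction)
  if (!event_class %in% c("utr3_shift", "intronic_up", "ua_up", "sp_up"))
    stopf("unknown event_class '%s'", event_class)
  if (fold_change <= 0) stopf("fold_change must be > 0")
  if (event_class == "utr3_shift" && !direction %in% c("proximal_up", "distal_up"))
    stopf("utr3_shift needs direction 'proximal_up' or 'distal_up'")
  structure(list(gene_subset = gene_subset, event_class = event_class,
                 fold_change = fold_change, direction = direction, ordinal = ordinal),
            class = "planted_effect")
}

#' Planted sequence motif
#'
#' Describes a motif written into one of the three windows around selected
#' pAs: `U100_41` (-100..-41 nt), `U40_1` (-40..-1 nt) or `D1_100`
#' (+1..+100 nt), the pA being position 0 in transcript orientation.
#'
#' @param motif Nucleotide string (U is treated as T).
#' @param window One of `"U100_41"`, `"U40_1"`, `"D1_100"`.
#' @param pa_subset `"all"`, character pA ids, or a single integer n (first n
#'   pAs in id order).
#' @param insertion_prob Probability that a selected pA receives the motif.
#' @return A list of class `"planted_motif"`.
#' @export
planted_motif <- function(motif, window, pa_subset = "all", insertion_prob = 1) {
  if (!window %in% names(.pa_window_width)) stopf("unknown window '%s'", window)
  motif <- chartr("Uu", "Tt", toupper(motif))
  if (!grepl("^[ACGT]+$", motif)) stopf("motif alphabet must be ACGT(U)")
  if (nchar(motif) > .pa_window_width[[window]])
    stopf("motif longer than window '%s'", window)
  if (insertion_prob < 0 || insertion_prob > 1) stopf("insertion_prob in [0,1]")
  structure(list(motif = motif, window = window, pa_subset = pa_subset,
                 insertion_prob = insertion_prob), class = "planted_motif")
}

#' Simulate a gene annotation, pA repertoire and genome sequence
#'
#' Generates non-overlapping gene models on a single synthetic chromosome
#' (both strands, >= 2 kb flanks around every gene), a per-gene pA repertoire
#' and, optionally, a random genome sequence. Coordinates are 0-based,
#' half-open; a pA position is the cleaved nucleotide.
#'
#' @param config A [sim_config()].
#' @return A list of class `"apa_annotation"` with elements `genes`, `exons`,
#'   `introns`, `pa_truth` (true pA table) and `genome` (a
#'   [Biostrings::DNAStringSet] or `NULL`).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(derive_seed(cfg$seed, "annotation"), {
    flank <- 2500L
    gap <- 5200L  # keeps uaRNA sites (< 2 kb upstream) clear of neighbours
    chrom <- "chrS"
    cursor <- flank
    genes <- vector("list", cfg$n_genes)
    exons <- vector("list", cfg$n_genes)
    introns <- vector("list", cfg$n_genes)
    pas <- vector("list", cfg$n_genes)
    rint <- function(r, n = 1) if (r[1] == r[2]) rep(r[1], n) else sample(r[1]:r[2], n, replace = TRUE)
    for (i in seq_len(cfg$n_genes)) {
      gid <- sprintf("G%04d", i)
      strand <- sample(c("+", "-"), 1)
      ne <- rint(cfg$exons_per_gene)
      elens <- rint(cfg$exon_len, ne)
      k <- cfg$utr3_pa_count
      spac <- if (k > 1) rint(cfg$autr_len, k - 1) else integer(0)
      elens[ne] <- cfg$utr3_offset + sum(spac) + cfg$utr3_flank
      ilens <- if (ne > 1) rint(cfg$intron_len, ne - 1) else integer(0)
      glen <- sum(elens) + sum(ilens)
      gs <- cursor; ge <- cursor + glen
      cursor <- ge + gap
      # exon genomic coordinates in transcript order
      es <- integer(ne); ee <- integer(ne)
      if (strand == "+") {
        p <- gs
        for (j in seq_len(ne)) { es[j] <- p; ee[j] <- p + elens[j]; p <- ee[j] + if (j < ne) ilens[j] else 0L }
      } else {
        p <- ge
        for (j in seq_len(ne)) { ee[j] <- p; es[j] <- p - elens[j]; p <- es[j] - if (j < ne) ilens[j] else 0L }
      }
      tss <- if (strand == "+") gs else ge - 1L
      ni <- ne - 1L
      if (ni > 0) {
        if (strand == "+") { is <- ee[-ne]; ie <- es[-1] } else { is <- ee[-1]; ie <- es[-ne] }
        introns[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                                   start = is, end = ie, intron_index = seq_len(ni),
                                   n_introns = ni,
                                   ss5_strength = rnorm(ni, 8, 2),
                                   ss3_strength = rnorm(ni, 8, 2),
                                   stringsAsFactors = FALSE)
      }
      # tandem 3'UTR pAs in the 3'-most exon, rank 1 = proximal (5'-ward)
      if (strand == "+") {
        putr <- es[ne] + cfg$utr3_offset + c(0L, cumsum(spac))
      } else {
        putr <- ee[ne] - 1L - cfg$utr3_offset - c(0L, cumsum(spac))
      }
      pa <- data.frame(pa_id = sprintf("%s:utr3:%d", gid, seq_len(k)), gene_id = gid,
                       chrom = chrom, strand = strand, position = putr, class = "utr3",
                       utr3_rank = seq_len(k), intron_index = NA_integer_,
                       tss_distance = if (strand == "+") putr - tss else tss - putr,
                       stringsAsFactors = FALSE)
      if (ni > 0 && runif(1) < cfg$frac_intronic_pa) {
        ix <- sample.int(ni, 1)
        ipos <- as.integer(floor((introns[[i]]$start[ix] + introns[[i]]$end[ix]) / 2))
        pa <- rbind(pa, data.frame(pa_id = sprintf("%s:intron:%d", gid, ix), gene_id = gid,
                                   chrom = chrom, strand = strand, position = ipos,
                                   class = "intron", utr3_rank = NA_integer_, intron_index = ix,
                                   tss_distance = if (strand == "+") ipos - tss else tss - ipos,
                                   stringsAsFactors = FALSE))
      }
      if (runif(1) < cfg$frac_ua_pa) {
        d <- as.integer(round(min(max(rnorm(1, cfg$ua_distance[["mean"]],
                                            cfg$ua_distance[["sd"]]), 100), 2000)))
        uapos <- if (strand == "+") tss - d else tss + d
        pa <- rbind(pa, data.frame(pa_id = sprintf("%s:ua:1", gid), gene_id = gid,
                                   chrom = chrom, strand = if (strand == "+") "-" else "+",
                                   position = uapos, class = "ua", utr3_rank = NA_integer_,
                                   intron_index = NA_integer_, tss_distance = -d,
                                   stringsAsFactors = FALSE))
      }
      if (ni > 0 && runif(1) < cfg$frac_sp_pa) {
        i1 <- introns[[i]][if (strand == "+") 1L else 1L, ]  # transcript intron 1
        cand <- seq.int(i1$start, i1$end - 1L)
        dist <- if (strand == "+") cand - tss else tss - cand
        cand <- cand[dist >= 1 & dist <= 1995]
        if (length(cand) > 0) {
          sppos <- cand[sample.int(length(cand), 1)]
          pa <- rbind(pa, data.frame(pa_id = sprintf("%s:sp:1", gid), gene_id = gid,
                                     chrom = chrom, strand = strand, position = sppos,
                                     class = "sp", utr3_rank = NA_integer_,
                                     intron_index = 1L,
                                     tss_distance = if (strand == "+") sppos - tss else tss - sppos,
                                     stringsAsFactors = FALSE))
        }
      }
      pas[[i]] <- pa
      exons[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               start = es, end = ee, exon_rank = seq_len(ne),
                               stringsAsFactors = FALSE)
      genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               start = gs, end = ge, tss = tss, n_exons = ne,
                               n_introns = ni, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    genes$abundance <- rlnorm(nrow(genes), 0, cfg$gene_abund_sdlog)
    ann <- list(genes = genes,
                exons = do.call(rbind, exons),
                introns = if (any(!vapply(introns, is.null, TRUE)))
                  do.call(rbind, introns[!vapply(introns, is.null, TRUE)])
                  else NULL,
                pa_truth = do.call(rbind, pas),
                genome = NULL,
                config = cfg)
    if (cfg$make_genome) {
      glen <- cursor + flank
      seq <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                          prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
      genome <- Biostrings::DNAStringSet(seq)
      names(genome) <- chrom
      ann$genome <- genome
    }
    class(ann) <- "apa_annotation"
    ann
  })
}

resolve_gene_subset <- function(subset, eligible) {
  eligible <- sort(unique(eligible))
  if (is.character(subset)) {
    bad <- setdiff(subset, eligible)
    if (length(bad) > 0)
      stopf("gene_subset entries not eligible for this effect: %s",
            paste(utils::head(bad, 5), collapse = ", "))
    subset
  } else if (is.numeric(subset) && length(subset) == 1) {
    if (subset > length(eligible))
      stopf("gene_subset asks for %d genes but only %d are eligible",
            subset, length(eligible))
    eligible[seq_len(subset)]
  } else stopf("gene_subset must be gene ids or a single count")
}

#' Simulate per-condition pA usage proportions
#'
#' Control usage is drawn from a Dirichlet prior over each gene's pAs
#' (gamma-distributed weights: shape 8 for 3'UTR pAs, 2 for intronic pAs and
#' 1.5 for uaRNA/spRNA pAs, so promoter-proximal and intronic isoforms are
#' minor by default). Test usage multiplies the usage odds of the pAs
#' targeted by each [planted_effect()] by its fold change and renormalizes;
#' untargeted genes are identical across conditions.
#'
#' @param annotation An `"apa_annotation"`.
#' @param config The [sim_config()] (supplies `effect_table` and `seed`).
#' @return `data.frame` with columns `pa_id`, `gene_id`, `ctrl`, `test`, and
#'   attribute `"planted"` listing the affected pAs.
#' @export
simulate_usage <- function(annotation, config) {
  pa <- annotation$pa_truth
  with_seed(derive_seed(config$seed, "usage"), {
    alpha <- c(utr3 = 8, intron = 2, ua = 1.5, sp = 1.5)[pa$class]
    w <- rgamma(nrow(pa), shape = alpha, rate = 1)
    w[w < 1e-9] <- 1e-9
    wt <- w
    planted <- list()
    for (eff in config$effect_table) {
      stopifnot(inherits(eff, "planted_effect"))
      eligible <- switch(eff$event_class,
        utr3_shift = {
          tab <- table(pa$gene_id[pa$class == "utr3"])
          names(tab)[tab >= 2]
        },
        intronic_up = {
          sel <- pa$class == "intron"
          if (!is.null(eff$ordinal)) {
            ni <- annotation$genes$n_introns[match(pa$gene_id, annotation$genes$gene_id)]
            sel <- sel & assign_intron_ordinal(pa$intron_index, ni) %in% eff$ordinal
          }
          unique(pa$gene_id[sel])
        },
        ua_up = unique(pa$gene_id[pa$class == "ua"]),
        sp_up = unique(pa$gene_id[pa$class == "sp"]),
        stopf("unknown event_class '%s'", eff$event_class))
      gids <- resolve_gene_subset(eff$gene_subset, eligible)
      idx <- switch(eff$event_class,
        utr3_shift = {
          utr <- pa$class == "utr3" & pa$gene_id %in% gids
          if (eff$direction == "proximal_up") which(utr & pa$utr3_rank == 1)
          else {
            maxrank <- stats::ave(pa$utr3_rank, pa$gene_id, FUN = function(x) max(x, na.rm = TRUE))
            which(utr & pa$utr3_rank == maxrank)
          }
        },
        intronic_up = {
          sel <- pa$class == "intron" & pa$gene_id %in% gids
          if (!is.null(eff$ordinal)) {
            ni <- annotation$genes$n_introns[match(pa$gene_id, annotation$genes$gene_id)]
            sel <- sel & assign_intron_ordinal(pa$intron_index, ni) %in% eff$ordinal
          }
          which(sel)
        },
        ua_up = which(pa$class == "ua" & pa$gene_id %in% gids),
        sp_up = which(pa$class == "sp" & pa$gene_id %in% gids))
      fold <- if (eff$direction == "down") 1 / eff$fold_change else eff$fold_change
      wt[idx] <- wt[idx] * fold
      if (length(idx) > 0)
        planted[[length(planted) + 1]] <-
          data.frame(pa_id = pa$pa_id[idx], gene_id = pa$gene_id[idx],
                     event_class = eff$event_class, direction = eff$direction,
                     fold_change = eff$fold_change, stringsAsFactors = FALSE)
    }
    norm_by_gene <- function(x) {
      s <- stats::ave(x, pa$gene_id, FUN = sum)
      x / s
    }
    usage <- data.frame(pa_id = pa$pa_id, gene_id = pa$gene_id,
                        ctrl = norm_by_gene(w), test = norm_by_gene(wt),
                        stringsAsFactors = FALSE)
    attr(usage, "planted") <- if (length(planted) > 0) do.call(rbind, planted)
      else data.frame(pa_id = character(), gene_id = character(),
                      event_class = character(), direction = character(),
                      fold_change = numeric(), stringsAsFactors = FALSE)
    usage
  })
}

#' Simulate reads with annotated 3'-end positions and unaligned-T counts
#'
#' Per sample, gene read totals are multinomial over log-normal gene
#' abundances (optionally overdispersed with multiplicative gamma noise),
#' pA-level counts are multinomial given the condition's usage, each read's
#' 3'-end position is jittered uniformly within the configured half-width of
#' the true pA, and each read carries an unaligned-T count (>= 2 for genuine
#' pA reads; internal-priming decoys get 0 or 1).
#'
#' @param usage Output of [simulate_usage()].
#' @param annotation An `"apa_annotation"`.
#' @param config The [sim_config()].
#' @return `data.frame` with columns `chrom`, `position`, `strand`, `sample`,
#'   `read_id`, `unaligned_T`, plus `true_pa` (generator-side truth, dropped
#'   by the TSV writer).
#' @export
simulate_pass_reads <- function(usage, annotation, config) {
  validate_sim_config(config)
  pa <- annotation$pa_truth
  stopifnot(identical(pa$pa_id, usage$pa_id))
  genes <- annotation$genes
  rows_by_gene <- split(seq_len(nrow(pa)), factor(pa$gene_id, levels = genes$gene_id))
  with_seed(derive_seed(config$seed, "reads"), {
    out <- vector("list", nrow(config$samples))
    for (si in seq_len(nrow(config$samples))) {
      smp <- config$samples$sample[si]
      cond <- config$samples$condition[si]
      ab <- genes$abundance
      if (config$overdispersion > 0) {
        shp <- 1 / config$overdispersion
        ab <- ab * rgamma(length(ab), shape = shp, rate = shp)
      }
      ng <- rmultinom(1, config$depth_per_sample, ab)[, 1]
      ucol <- usage[[cond]]
      cnt <- integer(nrow(pa))
      for (gi in seq_len(nrow(genes))) {
        if (ng[gi] == 0) next
        rows <- rows_by_gene[[gi]]
        cnt[rows] <- rmultinom(1, ng[gi], ucol[rows])[, 1]
      }
      n <- sum(cnt)
      rows <- rep.int(seq_len(nrow(pa)), cnt)
      jit <- sample.int(2L * config$jitter + 1L, n, replace = TRUE) - config$jitter - 1L
      tr <- config$unaligned_t_range
      ut <- if (tr[1] == tr[2]) rep(tr[1], n) else sample(tr[1]:tr[2], n, replace = TRUE)
      if (config$decoy_frac > 0) {
        dec <- runif(n) < config$decoy_frac
        ut[dec] <- sample(0:1, sum(dec), replace = TRUE)
      }
      out[[si]] <- data.frame(chrom = pa$chrom[rows],
                              position = pa$position[rows] + jit,
                              strand = pa$strand[rows],
                              sample = smp,
                              read_id = sprintf("%s_%08d", smp, seq_len(n)),
                              unaligned_T = ut,
                              true_pa = pa$pa_id[rows],
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Plant motifs into the genome around selected pAs
#'
#' Writes each motif at a uniformly chosen offset inside the named
#' strand-aware window with the configured probability. Windows are read in
#' transcript orientation, so a motif planted for a minus-strand pA appears
#' reverse-complemented on the plus strand at the mirrored coordinates.
#' Sequence length is unchanged. Insertions that would overlap an earlier
#' insertion on the same chromosome are skipped.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param pa_table `data.frame` with columns `pa_id` (or `cluster_id`),
#'   `chrom`, `position`, `strand`.
#' @param motif_table List of [planted_motif()] entries.
#' @param seed Integer seed.
#' @return The modified genome.
#' @export
plant_motifs <- function(genome, pa_table, motif_table, seed = 1) {
  id_col <- if ("pa_id" %in% names(pa_table)) "pa_id" else "cluster_id"
  with_seed(seed, {
    repl <- list()
    for (mt in motif_table) {
      stopifnot(inherits(mt, "planted_motif"))
      ids <- pa_table[[id_col]]
      sel <- if (identical(mt$pa_subset, "all")) seq_along(ids)
        else if (is.character(mt$pa_subset)) which(ids %in% mt$pa_subset)
        else order(ids)[seq_len(mt$pa_subset)]
      ml <- nchar(mt$motif)
      wl <- .pa_window_width[[mt$window]]
      for (i in sel) {
        if (runif(1) >= mt$insertion_prob) next
        co <- pa_window_coords(pa_table$position[i], pa_table$strand[i], mt$window)
        o <- sample.int(wl - ml + 1L, 1) - 1L
        if (pa_table$strand[i] == "+") {
          s <- co$start + o
          val <- mt$motif
        } else {
          s <- co$end - o - ml
          val <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mt$motif)))
        }
        repl[[length(repl) + 1]] <- data.frame(chrom = pa_table$chrom[i],
                                               start = s, end = s + ml, val = val,
                                               stringsAsFactors = FALSE)
      }
    }
    if (length(repl) == 0) return(genome)
    repl <- do.call(rbind, repl)
    for (ch in unique(repl$chrom)) {
      r <- repl[repl$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      keep <- rep(TRUE, nrow(r))
      last_end <- -1L
      for (j in seq_len(nrow(r))) {
        if (r$start[j] < last_end) keep[j] <- FALSE else last_end <- r$end[j]
      }
      r <- r[keep, , drop = FALSE]
      x <- genome[[ch]]
      x <- Biostrings::replaceAt(x, IRanges::IRanges(r$start + 1L, r$end),
                                 Biostrings::DNAStringSet(r$val))
      genome[[ch]] <- x
    }
    genome
  })
}

#' Run the full generator: annotation, usage, motifs, reads
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (genome already carrying planted motifs),
#'   `usage` and `reads`.
#' @export
simulate_dataset <- function(config) {
  ann <- simulate_annotation(config)
  usage <- simulate_usage(ann, config)
  if (length(config$motif_table) > 0 && !is.null(ann$genome)) {
    ann$genome <- plant_motifs(ann$genome, ann$pa_truth, config$motif_table,
                               seed = derive_seed(config$seed, "motifs"))
  }
  reads <- simulate_pass_reads(usage, ann, config)
  list(annotation = ann, usage = usage, reads = reads)
}
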