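#' Run the synthetic-data APA pipeline end to end
#'
#' Generates a dataset from a [sim_config()], writes the standard artifacts
#' (GTF annotation, FASTA genome, read/usage TSVs), then runs PASS
#' filtering, pA clustering, counting, classification, 3'UTR event
#' construction and the SAAP test, writing each stage's table with a header
#' comment carrying the tool version, seed and a configuration hash.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param sample_test,sample_ctrl Sample names for the comparison.
#' @param m SAAP bootstrap replicates.
#' @param q_threshold Significance threshold for direction calls.
#' @param min_rule Event read-support rule (see [min_read_filter()]).
#' @param verbose Log per-stage kept/dropped counts with `message()`.
#' @return Invisibly, a list with the stage objects (`annotation`, `usage`,
#'   `reads`, `clusters`, `counts`, `pa_ann`, `events`, `results`) and
#'   `paths` of everything written.
#' @export
run_pipeline <- function(sim, out_dir, sample_test = "test", sample_ctrl = "ctrl",
                         m = 20, q_threshold = 0.05, min_rule = "utr3_20_combined",
                         verbose = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  cfg_hash <- format(fnv1a(paste(deparse(sim), collapse = "")))
  hdr <- c(sprintf("apakit %s", as.character(utils::packageVersion("apakit"))),
           sprintf("seed=%d", sim$seed),
           sprintf("config_hash=%s", cfg_hash))
  p <- function(f) file.path(out_dir, f)
  dat <- simulate_dataset(sim)
  write_annotation_gtf(dat$annotation, p("annotation.gtf"))
  if (!is.null(dat$annotation$genome))
    write_genome_fasta(dat$annotation$genome, p("genome.fa"))
  write_reads_tsv(dat$reads, p("reads.tsv"), hdr)
  write_usage_tsv(dat$usage, p("usage.tsv"), hdr)
  say("simulate: %d genes, %d reads", nrow(dat$annotation$genes), nrow(dat$reads))
  pass <- filter_pass(dat$reads)
  say("pass-filter: kept %d of %d reads (dropped %d)",
      nrow(pass), nrow(dat$reads), nrow(dat$reads) - nrow(pass))
  clusters <- cluster_pa(pass)
  say("cluster: %d pA clusters", nrow(clusters))
  counts <- build_count_matrix(clusters, pass)
  write_clusters_bed(clusters, p("clusters.bed"))
  write_counts_tsv(counts, p("counts.tsv"), hdr)
  pa_ann <- classify_pa(clusters, dat$annotation)
  write_tsv_commented(pa_ann, p("pa_annotation.tsv"), hdr)
  say("classify: %s", paste(names(table(pa_ann$pa_class)),
                            table(pa_ann$pa_class), sep = "=", collapse = " "))
  events <- build_events(pa_ann, counts, mode = "top2_abundant")
  ec <- event_counts(events, counts, sample_test, sample_ctrl)
  keep <- min_read_filter(ec, min_rule)
  say("events: %d 3'UTR pairs, %d pass %s (dropped %d)",
      nrow(ec), sum(keep), min_rule, sum(!keep))
  write_events_tsv(events, p("events.tsv"), hdr)
  results <- saap(ec[keep, , drop = FALSE], m = m,
                  seed = derive_seed(sim$seed, "saap"))
  results <- call_direction(results, "utr3_pair", q_threshold)
  write_tsv_commented(results, p("saap_results.tsv"), hdr)
  say("saap: %d significant at q<%g (Le=%d Sh=%d)",
      sum(results$significant), q_threshold,
      sum(results$direction == "Le"), sum(results$direction == "Sh"))
  paths <- vapply(c("annotation.gtf", "reads.tsv", "usage.tsv", "clusters.bed",
                    "counts.tsv", "pa_annotation.tsv", "events.tsv",
                    "saap_results.tsv"), p, character(1))
  invisible(list(annotation = dat$annotation, usage = dat$usage,
                 reads = dat$reads, clusters = clusters, counts = counts,
                 pa_ann = pa_ann, events = events, results = results,
                 paths = paths))
}
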