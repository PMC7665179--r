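#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full discovery run. The
#' pipeline either consumes external contigs (`contigs_fasta` +
#' `reads_fastq`) or simulates its inputs from a `simulation` block, in
#' which case the simulator's ground-truth tail-less arrays stand in for
#' assembled contigs (de novo assembly is outside the pipeline: its bespoke
#' content starts downstream of assembly).
#'
#' @param output_dir directory for all stage outputs.
#' @param seed integer seed governing every stochastic stage.
#' @param contigs_fasta,reads_fastq input paths (optional when `simulation`
#'   is given).
#' @param simulation optional list passed to [sim_config()] plus
#'   `n_satellite`, `n_decoys`, `families`.
#' @param probe probe list; default DYZ1.
#' @param screen_frac half-probe fraction.
#' @param cluster_threshold greedy clustering identity threshold.
#' @param min_reads,min_tail,tail_purity polyA verification parameters.
#' @param quant_k pseudoalignment k-mer length.
#' @param trim_min_length drop floor for trimmed reads.
#' @param sample_id label stored in the abundance table.
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir, seed = 1L,
                       contigs_fasta = NULL, reads_fastq = NULL,
                       simulation = NULL,
                       probe = dyz1_probe(), screen_frac = 0.5,
                       cluster_threshold = 0.90,
                       min_reads = 2L, min_tail = 10L, tail_purity = 0.9,
                       quant_k = 21L, trim_min_length = 20L,
                       sample_id = "sample") {
  if (is.null(simulation) && (is.null(contigs_fasta) || is.null(reads_fastq)))
    stop("provide either contigs_fasta + reads_fastq or a simulation block")
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 contigs_fasta = contigs_fasta, reads_fastq = reads_fastq,
                 simulation = simulation, probe = probe,
                 screen_frac = screen_frac,
                 cluster_threshold = cluster_threshold,
                 min_reads = as.integer(min_reads),
                 min_tail = as.integer(min_tail), tail_purity = tail_purity,
                 quant_k = as.integer(quant_k),
                 trim_min_length = as.integer(trim_min_length),
                 sample_id = sample_id),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys mirror the
#'   arguments of [run_config()].
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the discovery pipeline
#'
#' Executes the full stage order on one sample: trim reads, screen contigs
#' with the half-probe rule, verify polyA status of the passing contigs
#' against the untrimmed reads, cluster the verified transcripts and call
#' consensuses, quantify the consensuses against the trimmed reads, and
#' annotate them. Every intermediate is written under `output_dir` as
#' FASTA/FASTQ/TSV/BED, the run is summarized in `report.json`, and a
#' re-run from the same configuration is bit-identical.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly written as JSON.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$simulation)) {
    simargs <- config$simulation
    extra <- simargs[names(simargs) %in% c("n_satellite", "n_decoys", "families")]
    simargs <- simargs[!names(simargs) %in% names(extra)]
    if (is.null(simargs$seed)) simargs$seed <- config$seed
    cfg <- do.call(sim_config, simargs)
    sim <- do.call(simulate_transcriptome, c(list(config = cfg), extra))
    reads <- simulate_reads(sim$molecules, sim$truth, cfg)
    contigs <- sim$arrays
    # non-satellite decoy contigs enter screening too
    bg <- sim$molecules[!sim$molecules$id %in% sim$arrays$id, , drop = FALSE]
    bg$seq <- sub("A+$", "", bg$seq)
    contigs <- rbind(contigs, bg)
    truth <- sim$truth
    write_fasta(contigs, file.path(config$output_dir, "contigs.fasta"))
    write_fastq(reads, file.path(config$output_dir, "reads.fastq"))
    write_tsv(truth, file.path(config$output_dir, "truth.tsv"))
  } else {
    contigs <- read_fasta(config$contigs_fasta)
    reads <- read_fastq(config$reads_fastq)
  }
  if (nrow(reads) == 0) stop("empty read set")

  report <- list(parameters = config[setdiff(names(config), "probe")],
                 probe = config$probe$name, warnings = character(0))
  report$n_reads_in <- nrow(reads)
  report$n_contigs_in <- nrow(contigs)

  trimmed <- trim_polya(reads, min_tail = config$min_tail,
                        min_length = config$trim_min_length)
  write_fastq(trimmed$records, file.path(config$output_dir, "reads.trimmed.fastq"))
  write_tsv(trimmed$log, file.path(config$output_dir, "tail_log.tsv"))
  report$n_reads_trimmed <- nrow(trimmed$records)
  report$n_reads_dropped <- trimmed$n_dropped

  scr <- screen_probe(contigs, config$probe, config$screen_frac)
  passing <- contigs[scr$pass, , drop = FALSE]
  write_tsv(scr$matches, file.path(config$output_dir, "probe_matches.tsv"))
  write_fasta(passing, file.path(config$output_dir, "contigs.pass.fasta"))
  report$n_screened <- nrow(contigs)
  report$n_passed <- nrow(passing)

  verified_ids <- character(0)
  tail_evidence <- NULL
  if (nrow(passing)) {
    tail_evidence <- verify_polya_all(passing, reads,
                                      min_reads = config$min_reads,
                                      min_tail = config$min_tail,
                                      tail_purity = config$tail_purity)
    write_tsv(tail_evidence, file.path(config$output_dir, "polya_evidence.tsv"))
    verified_ids <- tail_evidence$transcript_id[tail_evidence$verdict]
  }
  verified <- passing[passing$id %in% verified_ids, , drop = FALSE]
  report$n_verified <- nrow(verified)

  consensuses <- NULL
  if (nrow(verified)) {
    cl <- greedy_cluster(verified, config$cluster_threshold)
    write_tsv(cl$members[setdiff(names(cl$members), "seq")],
              file.path(config$output_dir, "clusters.tsv"))
    consensuses <- build_consensus(cl)
    write_fasta(consensuses, file.path(config$output_dir, "consensus.fasta"))
    report$n_clusters <- nrow(cl$centroids)
  } else report$n_clusters <- 0L

  if (!is.null(consensuses)) {
    tab <- quantify_sample(consensuses, trimmed$records,
                           sample_id = config$sample_id, k = config$quant_k)
    write_tsv(tab, file.path(config$output_dir, "abundance.tsv"))
    report$n_assigned_reads <- attr(tab, "n_assigned")

    ann <- annotate_repeats(consensuses)
    write_tsv(ann$annotations, file.path(config$output_dir, "annotation.tsv"))
    write_blocks_bed(ann$blocks, file.path(config$output_dir, "blocks.bed"))
  } else {
    report$n_assigned_reads <- 0L
  }

  stopifnot(report$n_screened >= report$n_passed,
            report$n_passed >= report$n_verified)
  if (!is.null(truth)) report$truth_satellites <-
    sum(truth$family != "background")
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
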