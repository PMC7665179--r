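#' Simulation configuration
#'
#' Parameters of the synthetic HS2/HS3 data generator. The defaults emulate
#' the conditions the discovery pipeline assumes: polyadenylated satellite
#' transcripts of 300-640 bp, unstranded single-end reads with substitution
#' errors, and a background of non-satellite decoys including one fixed
#' "ACTB-like" stable reference decoy.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   identical across runs.
#' @param family satellite family: `"HS2like"` (diverged 23- and 26-bp
#'   units built from ATTCC pentamers), `"HS3like"` (strict 5-bp ATTCC
#'   periodicity with a CAACCCGAGT decanucleotide inserted every
#'   `deca_period` pentamers), or `"HS3_GATGAT"` (HS3like with a fraction of
#'   pentamers replaced by GATGAT hexamers).
#' @param unit_divergence per-base substitution probability within repeat
#'   units. The default 0.18 is calibrated against the printed HS2/HS3
#'   oocyte transcript cDNAs (see [published_transcripts()]), whose global
#'   identity to a pure (ATTCC)n backbone is 0.71-0.85 and which share
#'   almost no exact 21-mers with one another; lower values produce arrays
#'   far more internally repetitive than real satellite transcripts.
#' @param transcript_length_range satellite transcript body length range in
#'   bp, default `c(300, 640)`.
#' @param polyA_range range of polyA tail lengths (uniform integer draw).
#' @param deca_period HS3like decanucleotide insertion period, in pentamers.
#' @param gatgat_frac fraction of pentamers replaced by GATGAT for the
#'   `HS3_GATGAT` family (at least one is always replaced).
#' @param read_length read length in bp.
#' @param read_error_rate per-base substitution error probability.
#' @param n_reads number of reads per simulated sample.
#' @param strand_flip_prob probability a read is emitted as the reverse
#'   complement of its fragment (0.5 = unstranded library).
#' @param background_fraction fraction of true abundance assigned to
#'   non-satellite decoy transcripts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       family = c("HS3like", "HS2like", "HS3_GATGAT"),
                       unit_divergence = 0.18,
                       transcript_length_range = c(300L, 640L),
                       polyA_range = c(20L, 60L),
                       deca_period = 20L,
                       gatgat_frac = 0.05,
                       read_length = 100L,
                       read_error_rate = 0.01,
                       n_reads = 5000L,
                       strand_flip_prob = 0.5,
                       background_fraction = 0.5) {
  family <- match.arg(family)
  probs <- c(unit_divergence, read_error_rate, strand_flip_prob,
             background_fraction, gatgat_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (transcript_length_range[1] > transcript_length_range[2])
    stop("transcript_length_range: min > max")
  structure(list(seed = as.integer(seed), family = family,
                 unit_divergence = unit_divergence,
                 transcript_length_range = as.integer(transcript_length_range),
                 polyA_range = as.integer(polyA_range),
                 deca_period = as.integer(deca_period),
                 gatgat_frac = gatgat_frac,
                 read_length = as.integer(read_length),
                 read_error_rate = read_error_rate,
                 n_reads = as.integer(n_reads),
                 strand_flip_prob = strand_flip_prob,
                 background_fraction = background_fraction),
            class = "sim_config")
}

DECA <- "CAACCCGAGT"

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(alt, b), 1), character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a satellite array
#'
#' Builds one tandem-repeat array of the configured family. HS2like arrays
#' concatenate per-copy diverged 23-bp and 26-bp units derived from ATTCC
#' pentamers; HS3like arrays are ATTCC pentamer runs with a CAACCCGAGT
#' decanucleotide inserted every `deca_period` pentamers; HS3_GATGAT
#' additionally replaces a fraction of pentamers with GATGAT hexamers.
#' Output is trimmed to exactly `length` bp.
#'
#' @param config a [sim_config()] (its `family`, `unit_divergence`,
#'   `deca_period` and `gatgat_frac` are used; the caller controls the RNG
#'   state).
#' @param length target array length in bp (>= 50).
#' @param id record id.
#' @return one-row record data frame.
#' @export
make_array <- function(config, length, id = "array") {
  if (length < 50) stop("make_array: length must be >= 50")
  n_pent <- ceiling(length / 5) + config$deca_period
  if (config$family == "HS2like") {
    unit23 <- substr(strrep("ATTCC", 5), 1, 23)
    unit26 <- substr(strrep("CATTC", 6), 1, 26)
    n_units <- ceiling(length / 23) + 1
    units <- vapply(seq_len(n_units), function(i) {
      mutate_seq(if (i %% 2 == 1) unit23 else unit26, config$unit_divergence)
    }, character(1))
    body <- paste(units, collapse = "")
  } else {
    pent <- rep("ATTCC", n_pent)
    if (config$family == "HS3_GATGAT") {
      n_rep <- max(1L, round(config$gatgat_frac * n_pent))
      # avoid the tail region so trimming cannot remove every hexamer
      safe <- seq_len(max(1L, floor(length / 5) - 2L))
      pent[sample(safe, min(n_rep, length(safe)))] <- "GATGAT"
    }
    keep <- seq_along(pent)
    ins <- which(keep %% config$deca_period == 0)
    chunks <- pent
    chunks[ins] <- paste0(chunks[ins], DECA)
    body <- mutate_seq(paste(chunks, collapse = ""), config$unit_divergence)
  }
  seq_records(id, substr(body, 1, length), desc = config$family)
}

#' Polyadenylate and orient a transcript
#'
#' Appends a 3' polyA tail to an array and emits the molecule on the
#' requested strand: minus-strand emission is the reverse complement, so the
#' printed cDNA begins with a 5' polyT leader.
#'
#' @param array one-row record data frame.
#' @param polyA_len tail length in bp (>= 0).
#' @param emit_strand `"plus"` or `"minus"`.
#' @return one-row record data frame.
#' @export
make_transcript <- function(array, polyA_len = 30L, emit_strand = c("plus", "minus")) {
  emit_strand <- match.arg(emit_strand)
  if (polyA_len < 0) stop("polyA_len must be >= 0")
  s <- paste0(array$seq[1], strrep("A", polyA_len))
  if (emit_strand == "minus") s <- revcomp(s)
  seq_records(array$id[1], s,
              desc = paste(array$desc[1], emit_strand, sep = " "))
}

#' Simulate unstranded reads
#'
#' Draws per-transcript read counts from a multinomial with probabilities
#' proportional to true TPM times effective length, places read starts
#' uniformly, applies per-base substitution errors, and reverse-complements
#' each read independently with `strand_flip_prob` (emulating an unstranded
#' library). The generating transcript, strand and start are recorded in
#' each read id (`read|<target>|<+/->|<start>`).
#'
#' @param transcripts record data frame of source molecules.
#' @param truth data frame with columns `target_id`, `true_tpm`.
#' @param config a [sim_config()].
#' @param eff_k k defining the effective length `max(1, len - eff_k + 1)`
#'   used in the count model; matches the quantifier's default k so that
#'   abundance estimation inverts the generative model exactly.
#' @return record data frame of reads with constant qualities.
#' @export
simulate_reads <- function(transcripts, truth, config, eff_k = 21L) {
  rl <- config$read_length
  len <- nchar(transcripts$seq)
  if (rl > min(len)) stop("read_length exceeds shortest transcript")
  tpm <- truth$true_tpm[match(transcripts$id, truth$target_id)]
  eff <- len - rl + 1
  prob <- tpm * pmax(1, len - eff_k + 1)
  counts <- as.vector(rmultinom(1, config$n_reads, prob / sum(prob)))
  out_seq <- character(config$n_reads)
  out_id <- character(config$n_reads)
  pos <- 1L
  for (t in seq_len(nrow(transcripts))) {
    if (counts[t] == 0) next
    starts <- sample.int(eff[t], counts[t], replace = TRUE)
    frag <- substring(transcripts$seq[t], starts, starts + rl - 1)
    flip <- runif(counts[t]) < config$strand_flip_prob
    if (any(flip)) frag[flip] <- revcomp(frag[flip])
    if (config$read_error_rate > 0)
      frag <- vapply(frag, mutate_seq, character(1),
                     rate = config$read_error_rate, USE.NAMES = FALSE)
    idx <- pos:(pos + counts[t] - 1L)
    out_seq[idx] <- frag
    out_id[idx] <- sprintf("read%06d|%s|%s|%d", idx, transcripts$id[t],
                           ifelse(flip, "-", "+"), starts - 1L)
    pos <- pos + counts[t]
  }
  ord <- sample.int(config$n_reads)
  seq_records(out_id[ord], out_seq[ord],
              qual = strrep("I", rl))
}

# Deterministic "ACTB-like" decoy: a fixed synthetic non-satellite sequence
# held at constant abundance across a donor's GV/MII pair.
actb_decoy <- function(length = 1000L) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  state <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", state, envir = globalenv()))
  set.seed(424242L)
  seq_records("ACTB_like", random_seq(length), desc = "stable control decoy")
}

#' Simulate a sample transcriptome with ground truth
#'
#' Builds `n_satellite` polyadenylated satellite transcripts (family drawn
#' per transcript when `families` has several entries), `n_decoys` random
#' non-satellite decoys, and the fixed ACTB-like decoy, together with a
#' truth table whose `true_tpm` sums to exactly 1e6.
#'
#' @param config a [sim_config()].
#' @param n_satellite,n_decoys transcript counts.
#' @param families satellite families to cycle over.
#' @param sat_weights optional relative abundances of the satellite
#'   transcripts (recycled).
#' @return list with `molecules` (tailed, oriented transcripts used for read
#'   simulation), `arrays` (tail-less satellite bodies, the ground-truth
#'   "contigs"), and `truth` (target_id, family, strand, polyA_len,
#'   true_tpm).
#' @export
simulate_transcriptome <- function(config, n_satellite = 4L, n_decoys = 3L,
                                   families = config$family,
                                   sat_weights = NULL) {
  set.seed(config$seed)
  fam <- rep_len(families, n_satellite)
  lens <- sample(seq(config$transcript_length_range[1],
                     config$transcript_length_range[2]), n_satellite,
                 replace = TRUE)
  tails <- sample(seq(config$polyA_range[1], config$polyA_range[2]),
                  n_satellite, replace = TRUE)
  strands <- sample(c("plus", "minus"), n_satellite, replace = TRUE)
  arrays <- do.call(rbind, lapply(seq_len(n_satellite), function(i) {
    cfg <- config; cfg$family <- fam[i]
    make_array(cfg, lens[i], id = sprintf("sat%02d", i))
  }))
  molecules <- do.call(rbind, lapply(seq_len(n_satellite), function(i) {
    make_transcript(arrays[i, ], tails[i], strands[i])
  }))
  decoys <- NULL
  if (n_decoys > 0) {
    decoys <- seq_records(sprintf("decoy%02d", seq_len(n_decoys)),
                          vapply(rep(800L, n_decoys), random_seq, character(1)),
                          desc = "background decoy")
    decoys$seq <- paste0(decoys$seq, strrep("A", 30L))
  }
  actb <- actb_decoy()
  actb$seq <- paste0(actb$seq, strrep("A", 30L))
  molecules <- rbind(molecules, decoys, actb)

  w_sat <- rep_len(if (is.null(sat_weights)) 1 else sat_weights, n_satellite)
  w_sat <- w_sat / sum(w_sat) * (1 - config$background_fraction)
  n_bg <- n_decoys + 1L
  w_bg <- rep(config$background_fraction / n_bg, n_bg)
  tpm <- c(w_sat, w_bg) * 1e6
  tpm <- tpm / sum(tpm) * 1e6
  truth <- data.frame(
    target_id = molecules$id,
    family = c(fam, rep("background", n_bg)),
    strand = c(strands, rep("plus", n_bg)),
    polyA_len = c(tails, rep(30L, n_bg)),
    true_tpm = tpm,
    stringsAsFactors = FALSE)
  list(molecules = molecules, arrays = arrays, truth = truth)
}

#' Simulate a paired GV/MII donor panel
#'
#' For each donor, two read sets (GV and MII) are simulated over a shared
#' target set; the satellite transcripts' abundance is scaled by the donor's
#' `mii_over_gv_ratio` in the MII sample while the ACTB-like decoy and
#' random background stay at constant absolute abundance, so a ratio of 1
#' yields an expected MII percentage of exactly 100.
#'
#' @param n_donors number of donors (>= 1).
#' @param ratios per-donor MII/GV satellite abundance ratios (recycled).
#'   The default encodes the study design of seven increased and three
#'   decreased donors.
#' @param config a [sim_config()].
#' @param n_satellite,n_decoys transcript counts shared by all samples.
#' @return list with `targets` (shared molecules), `arrays`, `samples`
#'   (named list of read record frames, names `d<donor>_GV` / `d<donor>_MII`),
#'   `manifest` (donor_id, stage, sample_id) and `truth` (per sample truth
#'   tables plus per-donor `expected_pct_mii` and `increase`).
#' @export
make_donor_panel <- function(n_donors = 10L,
                             ratios = c(2.0, 1.5, 3.0, 0.5, 1.8,
                                        0.7, 2.5, 1.4, 0.6, 1.6),
                             config = sim_config(),
                             n_satellite = 4L, n_decoys = 2L) {
  if (n_donors < 1) stop("n_donors must be >= 1")
  ratios <- rep_len(ratios, n_donors)
  base <- simulate_transcriptome(config, n_satellite, n_decoys,
                                 families = c("HS3like", "HS2like",
                                              "HS3_GATGAT"))
  sat <- base$truth$family != "background"
  samples <- list()
  manifest <- NULL
  sample_truth <- list()
  per_donor <- data.frame(donor_id = sprintf("donor%02d", seq_len(n_donors)),
                          ratio = ratios, expected_pct_mii = NA_real_,
                          increase = ratios > 1, stringsAsFactors = FALSE)
  for (d in seq_len(n_donors)) {
    for (stage in c("GV", "MII")) {
      level <- base$truth$true_tpm
      if (stage == "MII") level[sat] <- level[sat] * ratios[d]
      tpm <- level / sum(level) * 1e6
      truth <- transform(base$truth, true_tpm = tpm)
      sid <- sprintf("d%02d_%s", d, stage)
      cfg <- config
      cfg$seed <- config$seed + 1000L * d + (stage == "MII")
      set.seed(cfg$seed)
      samples[[sid]] <- simulate_reads(base$molecules, truth, cfg)
      sample_truth[[sid]] <- truth
      manifest <- rbind(manifest,
                        data.frame(donor_id = per_donor$donor_id[d],
                                   stage = stage, sample_id = sid,
                                   stringsAsFactors = FALSE))
    }
    gv <- sum(sample_truth[[sprintf("d%02d_GV", d)]]$true_tpm[sat])
    mii <- sum(sample_truth[[sprintf("d%02d_MII", d)]]$true_tpm[sat])
    per_donor$expected_pct_mii[d] <- 100 * mii / gv
  }
  list(targets = base$molecules, arrays = base$arrays, samples = samples,
       manifest = manifest, truth = sample_truth, donors = per_donor,
       satellite_ids = base$truth$target_id[sat])
}
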