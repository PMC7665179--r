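#' Pseudoalign reads to targets
#'
#' Strand-agnostic k-mer pseudoalignment: the index maps every canonical
#' k-mer (lexicographic minimum of a k-mer and its reverse complement —
#' required by unstranded libraries) to the targets containing it. A read's
#' compatible target set is the intersection of the target sets of its
#' indexed k-mers, k-mers absent from the index being skipped; reads with
#' no indexed k-mer or an empty intersection are unassigned. Reads with
#' identical target sets are pooled into equivalence classes.
#'
#' @param reads record data frame (reads shorter than `k` are unassigned).
#' @param targets record data frame of quantification targets.
#' @param k k-mer length (default 21).
#' @return list with `classes` (list of sorted 1-based target index
#'   vectors), `counts` (reads per class), `read_class` (per read; 0 =
#'   unassigned), `n_unassigned`, `n_assigned`, `target_ids`.
#' @export
pseudoalign <- function(reads, targets, k = 21L) {
  res <- pseudoalign_cpp(targets$seq, reads$seq, as.integer(k))
  list(classes = res$class_targets,
       counts = res$class_counts,
       read_class = res$read_class,
       n_unassigned = res$n_unassigned,
       n_assigned = length(res$read_class) - res$n_unassigned,
       target_ids = targets$id)
}

#' EM abundance estimation over equivalence classes
#'
#' Iterates the classic transcript-abundance EM: each class's count is
#' shared among its targets proportionally to `alpha_i / l_i` (current
#' abundance over effective length), and the shares are summed into the new
#' abundances. Counts are conserved at every iteration. Effective length is
#' `max(1, length - k + 1)`, floored so short references never divide by
#' zero. Iteration starts from uniform abundances and stops when
#' `max |d alpha| / sum(alpha) < tol`.
#'
#' @param classes list of 1-based target index vectors.
#' @param counts integer vector of class read counts.
#' @param target_lengths target lengths in bp.
#' @param k k-mer length used for pseudoalignment.
#' @param max_iter,tol convergence controls; non-convergence returns the
#'   last iterate with a warning.
#' @return list with `est_counts` (per target) and `eff_length`.
#' @export
em_abundance <- function(classes, counts, target_lengths, k = 21L,
                         max_iter = 1000L, tol = 1e-8) {
  if (length(classes) == 0) stop("em_abundance: no equivalence classes")
  n <- length(target_lengths)
  eff <- pmax(1, target_lengths - k + 1)
  total <- sum(counts)
  alpha <- rep(total / n, n)
  idx <- lapply(classes, as.integer)
  for (it in seq_len(max_iter)) {
    new <- numeric(n)
    for (e in seq_along(idx)) {
      i <- idx[[e]]
      w <- alpha[i] / eff[i]
      sw <- sum(w)
      if (sw == 0) w <- rep(1 / length(i), length(i)) else w <- w / sw
      new[i] <- new[i] + counts[e] * w
    }
    if (max(abs(new - alpha)) / max(sum(new), 1) < tol) {
      alpha <- new
      return(list(est_counts = alpha, eff_length = eff))
    }
    alpha <- new
  }
  warning("EM did not converge in ", max_iter, " iterations")
  list(est_counts = alpha, eff_length = eff)
}

#' Transcripts per million
#'
#' `tpm_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)`; an all-zero count
#' vector yields all zeros rather than a division error.
#'
#' @param est_counts estimated counts per target.
#' @param eff_length effective lengths (> 0).
#' @return TPM vector summing to 1e6 (or all zeros).
#' @export
tpm <- function(est_counts, eff_length) {
  if (any(eff_length <= 0)) stop("effective lengths must be positive")
  rate <- est_counts / eff_length
  s <- sum(rate)
  if (s == 0) return(rep(0, length(est_counts)))
  1e6 * rate / s
}

#' Quantify one sample
#'
#' Full quantification of a read set against a target set: pseudoalignment,
#' EM, TPM. The output follows the de-facto abundance-table layout
#' (target_id, length, eff_length, est_counts, tpm).
#'
#' @param targets,reads record data frames.
#' @param sample_id label stored in the table.
#' @param k k-mer length.
#' @param ... passed to [em_abundance()].
#' @return `data.frame` expression table with attribute `n_assigned`.
#' @export
quantify_sample <- function(targets, reads, sample_id = "sample", k = 21L, ...) {
  pa <- pseudoalign(reads, targets, k)
  len <- nchar(targets$seq)
  if (length(pa$classes) == 0) {
    est <- list(est_counts = rep(0, nrow(targets)),
                eff_length = pmax(1, len - k + 1))
  } else {
    est <- em_abundance(pa$classes, pa$counts, len, k, ...)
  }
  out <- data.frame(target_id = targets$id, length = len,
                    eff_length = est$eff_length,
                    est_counts = est$est_counts,
                    tpm = tpm(est$est_counts, est$eff_length),
                    sample_id = sample_id, stringsAsFactors = FALSE)
  attr(out, "n_assigned") <- pa$n_assigned
  out
}

#' Summed TPM of named reference targets
#'
#' @param table expression table from [quantify_sample()].
#' @param reference_ids target ids to sum; an empty vector yields 0;
#'   missing ids are an error naming them.
#' @return total TPM of the named targets.
#' @export
total_reference_tpm <- function(table, reference_ids) {
  if (length(reference_ids) == 0) return(0)
  missing <- setdiff(reference_ids, table$target_id)
  if (length(missing))
    stop("reference ids absent from table: ", paste(missing, collapse = ", "))
  sum(table$tpm[table$target_id %in% reference_ids])
}

#' Per-donor GV vs MII comparison
#'
#' For each donor with exactly one GV and one MII expression table, sums
#' satellite TPM in each stage and expresses the MII total as a percentage
#' of the GV total (GV = 100%). A donor counts as an increase when the
#' percentage exceeds 100. The control report gives the coefficient of
#' variation of the positive-control TPM across all samples (per
#' publication: cross-publication TPM values are never pooled, so all
#' samples handed to one call are assumed to share a publication) and flags
#' the negative control whenever its TPM exceeds `negative_floor` anywhere.
#'
#' @param tables named list of expression tables (names = sample ids).
#' @param manifest data frame with columns `donor_id`, `stage`
#'   (`"GV"`/`"MII"`), `sample_id`.
#' @param satellite_ids target ids summed as HS2/HS3 signal.
#' @param control_id positive-control target id (ACTB-like).
#' @param negative_control_id optional negative-control target id.
#' @param negative_floor TPM floor above which the negative control is
#'   flagged.
#' @return list with `donors` (donor_id, gv_tpm, mii_tpm, pct_mii,
#'   increase), `n_increase`, `control` (mean, sd, cv of control TPM) and
#'   `negative_flagged`.
#' @export
compare_donors <- function(tables, manifest, satellite_ids, control_id,
                           negative_control_id = NULL, negative_floor = 1) {
  donors <- unique(manifest$donor_id)
  rows <- lapply(donors, function(d) {
    sub <- manifest[manifest$donor_id == d, , drop = FALSE]
    gv <- sub$sample_id[sub$stage == "GV"]
    mii <- sub$sample_id[sub$stage == "MII"]
    if (length(gv) != 1 || length(mii) != 1)
      stop("donor ", d, " must have exactly one GV and one MII sample")
    gv_tpm <- total_reference_tpm(tables[[gv]], satellite_ids)
    mii_tpm <- total_reference_tpm(tables[[mii]], satellite_ids)
    data.frame(donor_id = d, gv_tpm = gv_tpm, mii_tpm = mii_tpm,
               pct_mii = 100 * mii_tpm / gv_tpm,
               increase = mii_tpm > gv_tpm, stringsAsFactors = FALSE)
  })
  donors_df <- do.call(rbind, rows)
  ctl <- vapply(manifest$sample_id, function(s)
    total_reference_tpm(tables[[s]], control_id), numeric(1))
  control <- data.frame(mean = mean(ctl), sd = sd(ctl),
                        cv = sd(ctl) / mean(ctl))
  neg_flag <- FALSE
  if (!is.null(negative_control_id)) {
    neg <- vapply(manifest$sample_id, function(s)
      total_reference_tpm(tables[[s]], negative_control_id), numeric(1))
    neg_flag <- any(neg > negative_floor)
  }
  list(donors = donors_df, n_increase = sum(donors_df$increase),
       control = control, negative_flagged = neg_flag)
}
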