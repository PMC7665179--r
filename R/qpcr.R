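#' Read a Ct table
#'
#' TSV with columns `sample_id`, `group`, `gene`, `ct` (one row per
#' replicate well).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  check_ct_table(ct)
  ct
}

check_ct_table <- function(ct) {
  need <- c("sample_id", "group", "gene", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  invisible(ct)
}

#' Relative quantification by 2^-ddCt
#'
#' Classic ddCt arithmetic with a two-group test: within each group,
#' `dCt = mean Ct(target) - mean Ct(reference)`; `ddCt = dCt(test) -
#' dCt(calibrator)`; `fold = 2^-ddCt`. Per-sample dCt values (mean over
#' that sample's replicates) are the units of a two-sided t-test between
#' the groups; the conventional significance threshold is p < 0.01. Fold
#' is 1 exactly when ddCt is 0, and results with two reference genes are
#' reported per reference, never averaged.
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param target,reference gene names, both present in both groups.
#' @param test_group,calibrator_group group labels.
#' @return list with `target`, `reference`, `ddct`, `fold`, `group_stats`
#'   (per-group mean and SD of per-sample dCt), `p_value` (NA when a group
#'   has fewer than two samples) and `significant` (p < 0.01).
#' @export
delta_delta_ct <- function(ct, target, reference, test_group,
                           calibrator_group) {
  check_ct_table(ct)
  for (g in c(test_group, calibrator_group)) {
    for (gene in c(target, reference)) {
      if (!any(ct$group == g & ct$gene == gene))
        stop("gene ", gene, " missing in group ", g)
    }
  }
  grp_dct <- function(g) {
    sub <- ct[ct$group == g, , drop = FALSE]
    mean(sub$ct[sub$gene == target]) - mean(sub$ct[sub$gene == reference])
  }
  ddct <- grp_dct(test_group) - grp_dct(calibrator_group)
  # per-sample dCt values as test units
  sample_dct <- function(g) {
    sub <- ct[ct$group == g, , drop = FALSE]
    samples <- unique(sub$sample_id)
    vapply(samples, function(s) {
      ss <- sub[sub$sample_id == s, , drop = FALSE]
      mean(ss$ct[ss$gene == target]) - mean(ss$ct[ss$gene == reference])
    }, numeric(1))
  }
  d_test <- sample_dct(test_group)
  d_cal <- sample_dct(calibrator_group)
  p <- if (length(d_test) >= 2 && length(d_cal) >= 2)
    tryCatch(t.test(d_test, d_cal)$p.value, error = function(e) NA_real_)
  else NA_real_
  group_stats <- data.frame(
    group = c(test_group, calibrator_group),
    mean_dct = c(mean(d_test), mean(d_cal)),
    sd_dct = c(sd(d_test), sd(d_cal)),
    n_samples = c(length(d_test), length(d_cal)))
  list(target = target, reference = reference, ddct = ddct,
       fold = 2^(-ddct), group_stats = group_stats, p_value = p,
       significant = !is.na(p) && p < 0.01)
}

#' Reference-gene stability check
#'
#' A reference gene is usable only if its Ct is comparable between the
#' groups being contrasted; a gene whose group means differ by more than
#' `max_delta` cycles (default 3, i.e. nearly an order of magnitude in
#' template) is flagged unstable.
#'
#' @param ct Ct table.
#' @param gene reference gene name (present in both groups).
#' @param max_delta tolerated between-group mean Ct difference, in cycles.
#' @return list with `gene`, `group_stats` (group, mean, sd, n), `delta`
#'   (absolute difference of group means) and `stable`.
#' @export
reference_stability <- function(ct, gene, max_delta = 3.0) {
  check_ct_table(ct)
  sub <- ct[ct$gene == gene, , drop = FALSE]
  groups <- unique(sub$group)
  if (length(groups) < 2) stop("gene ", gene, " present in fewer than 2 groups")
  stats <- do.call(rbind, lapply(groups, function(g) {
    v <- sub$ct[sub$group == g]
    data.frame(group = g, mean = mean(v), sd = sd(v), n = length(v))
  }))
  delta <- max(stats$mean) - min(stats$mean)
  list(gene = gene, group_stats = stats, delta = delta,
       stable = delta <= max_delta)
}
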