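#' Greedy centroid clustering
#'
#' UCLUST-style clustering of verified transcripts: sequences are sorted by
#' length descending (ties broken by id), then each sequence is compared to
#' existing centroids in creation order and joins the first whose
#' [global_identity()] reaches the threshold, else founds a new cluster with
#' itself as centroid. Unstranded assembly produces mixed orientations, so
#' every sequence is also compared as its reverse complement and joins in
#' whichever orientation reaches the threshold (forward checked first).
#' Sorting is internal, so the result does not depend on input order.
#'
#' @param records record data frame (at least one sequence).
#' @param threshold identity threshold T in (0, 1]; a required, logged
#'   parameter of any run.
#' @param best_hit if `TRUE`, join the best-identity centroid above T
#'   instead of the first (the classic alternative assignment rule).
#' @return object of class `sat_clusters`: list with `members` (data frame
#'   member_id, cluster_id, orientation, identity_to_centroid, seq in
#'   joined orientation), `centroids` (cluster_id, centroid_id) and
#'   `threshold`.
#' @export
greedy_cluster <- function(records, threshold = 0.90, best_hit = FALSE) {
  if (nrow(records) == 0) stop("greedy_cluster: no sequences")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  ord <- order(-nchar(records$seq), records$id)
  recs <- records[ord, , drop = FALSE]
  cent_seq <- character(0)
  cent_id <- character(0)
  members <- NULL
  for (i in seq_len(nrow(recs))) {
    s <- recs$seq[i]
    rs <- revcomp(s)
    chosen <- 0L; chosen_ident <- 0; chosen_orient <- "plus"
    for (ci in seq_along(cent_seq)) {
      idf <- global_identity(s, cent_seq[ci])
      orient <- "plus"; ident <- idf
      if (idf < threshold) {
        idr <- global_identity(rs, cent_seq[ci])
        if (idr >= threshold) { orient <- "minus"; ident <- idr }
      }
      if (ident >= threshold) {
        if (!best_hit) { chosen <- ci; chosen_ident <- ident
                         chosen_orient <- orient; break }
        if (ident > chosen_ident) { chosen <- ci; chosen_ident <- ident
                                    chosen_orient <- orient }
      }
    }
    if (chosen == 0L) {
      cent_seq <- c(cent_seq, s)
      cent_id <- c(cent_id, recs$id[i])
      chosen <- length(cent_seq); chosen_ident <- 1; chosen_orient <- "plus"
    }
    members <- rbind(members, data.frame(
      member_id = recs$id[i],
      cluster_id = sprintf("cluster%02d", chosen),
      orientation = chosen_orient,
      identity_to_centroid = chosen_ident,
      seq = if (chosen_orient == "minus") rs else s,
      stringsAsFactors = FALSE))
  }
  structure(list(
    members = members,
    centroids = data.frame(cluster_id = sprintf("cluster%02d",
                                                seq_along(cent_id)),
                           centroid_id = cent_id, seq = cent_seq,
                           stringsAsFactors = FALSE),
    threshold = threshold), class = "sat_clusters")
}

#' @export
print.sat_clusters <- function(x, ...) {
  cat("greedy clustering: ", nrow(x$members), " sequences in ",
      nrow(x$centroids), " clusters (T = ", x$threshold, ")\n", sep = "")
  invisible(x)
}

# Merge a centroid-vs-member pairwise alignment into a growing center-star
# alignment ("once a gap, always a gap"). `master` is the gapped centroid,
# `rows` the gapped members.
merge_star <- function(master, rows, c_aln, m_aln) {
  mc <- strsplit(master, "")[[1]]
  ca <- strsplit(c_aln, "")[[1]]
  ma <- strsplit(m_aln, "")[[1]]
  rws <- lapply(rows, function(r) strsplit(r, "")[[1]])
  out_master <- character(0); out_new <- character(0)
  out_rows <- rep(list(character(0)), length(rws))
  i <- 1L; j <- 1L
  nm <- length(mc); na <- length(ca)
  while (i <= nm || j <= na) {
    gi <- i <= nm && mc[i] == "-"
    gj <- j <= na && ca[j] == "-"
    if (i <= nm && j <= na && !gi && !gj) {
      out_master <- c(out_master, mc[i]); out_new <- c(out_new, ma[j])
      for (r in seq_along(rws)) out_rows[[r]] <- c(out_rows[[r]], rws[[r]][i])
      i <- i + 1L; j <- j + 1L
    } else if (gi) { # old gap column: new member gets a gap
      out_master <- c(out_master, "-"); out_new <- c(out_new, "-")
      for (r in seq_along(rws)) out_rows[[r]] <- c(out_rows[[r]], rws[[r]][i])
      i <- i + 1L
    } else {         # new gap column: previous rows get gaps
      out_master <- c(out_master, "-"); out_new <- c(out_new, ma[j])
      for (r in seq_along(rws)) out_rows[[r]] <- c(out_rows[[r]], "-")
      j <- j + 1L
    }
  }
  list(master = paste(out_master, collapse = ""),
       rows = c(lapply(out_rows, paste, collapse = ""),
                paste(out_new, collapse = "")))
}

#' Per-cluster consensus sequence
#'
#' Center-star multiple alignment with the centroid as the star: each
#' member is globally aligned to the centroid and the pairwise alignments
#' are merged under "once a gap, always a gap". Columns whose strict
#' majority is a gap are dropped; otherwise the most frequent base is
#' taken, ties broken in the fixed order A < C < G < T.
#'
#' @param clusters a `sat_clusters` object from [greedy_cluster()].
#' @param cluster_id which cluster to call; default all.
#' @return record data frame of consensus sequences (id =
#'   `<cluster_id>_consensus`, desc = centroid id and member count).
#' @export
build_consensus <- function(clusters, cluster_id = NULL) {
  ids <- cluster_id %||% clusters$centroids$cluster_id
  do.call(rbind, lapply(ids, function(cid) {
    mem <- clusters$members[clusters$members$cluster_id == cid, , drop = FALSE]
    if (nrow(mem) == 0) stop("empty cluster: ", cid)
    cent <- clusters$centroids$seq[clusters$centroids$cluster_id == cid]
    if (nrow(mem) == 1)
      return(seq_records(paste0(cid, "_consensus"), mem$seq[1],
                         desc = sprintf("centroid=%s n=1", mem$member_id[1])))
    others <- mem$seq[-match(cent, mem$seq)] # centroid appears once, as the star
    master <- cent
    rows <- list(cent)
    for (m in others) {
      aln <- global_align(master_ungapped(master), m)
      # re-gap the centroid row of the new pairwise alignment to the master
      merged <- merge_star(master, rows, aln$a_aln, aln$b_aln)
      master <- merged$master
      rows <- merged$rows
    }
    mat <- do.call(rbind, strsplit(unlist(rows), ""))
    cons <- apply(mat, 2, function(col) {
      gaps <- sum(col == "-")
      if (gaps > length(col) / 2) return("")
      tab <- table(factor(col[col != "-"], levels = c("A", "C", "G", "T", "N")))
      names(tab)[which.max(tab)]   # which.max takes the first => A<C<G<T order
    })
    seq_records(paste0(cid, "_consensus"), paste(cons, collapse = ""),
                desc = sprintf("centroid=%s n=%d",
                               clusters$centroids$centroid_id[
                                 clusters$centroids$cluster_id == cid],
                               nrow(mem)))
  }))
}

master_ungapped <- function(master) gsub("-", "", master, fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
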