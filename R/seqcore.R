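#' Sequence records
#'
#' The pipeline's universal sequence container is a plain data frame with
#' columns `id`, `desc`, `seq` and `qual` (Phred+33 string or `NA`).
#' Sequences are uppercase over the alphabet A, C, G, T, N; `U` is mapped to
#' `T` on construction because public satellite records mix RNA and DNA
#' alphabets and cases.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of nucleotide sequences (same length as `id`).
#' @param desc optional description strings.
#' @param qual optional Phred+33 quality strings, each the same length as its
#'   sequence, or `NA`.
#' @return a `data.frame` with columns `id`, `desc`, `seq`, `qual`.
#' @export
seq_records <- function(id, seq, desc = "", qual = NA_character_) {
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  seq <- normalize_seq(seq)
  if (any(!nzchar(seq))) stop("empty sequence in record(s): ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("non-IUPAC characters in record(s): ",
                     paste(id[bad], collapse = ", "))
  qual <- rep_len(as.character(qual), length(seq))
  mism <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(mism)) stop("quality length mismatch in record(s): ",
                      paste(id[mism], collapse = ", "))
  data.frame(id = as.character(id), desc = rep_len(as.character(desc), length(id)),
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}

normalize_seq <- function(seq) {
  chartr("U", "T", toupper(as.character(seq)))
}

#' Reverse complement
#'
#' Watson-Crick reverse complement over the alphabet A, C, G, T, N
#' (N maps to N). Vectorized; an involution.
#'
#' @param seq character vector of non-empty nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  seq <- normalize_seq(seq)
  if (any(!nzchar(seq))) stop("revcomp: empty sequence")
  if (any(grepl("[^ACGTN]", seq))) stop("revcomp: non-IUPAC character")
  vapply(chartr("ACGT", "TGCA", seq),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

#' Global alignment identity
#'
#' Fraction of matching columns in an optimal global (Needleman-Wunsch)
#' alignment scored match +1, mismatch -1, gap -1. Among equal-score
#' alignments the one with the most matches, then the fewest columns, is
#' used, which makes the value deterministic and symmetric.
#'
#' @param a,b non-empty nucleotide strings.
#' @return identity in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity: empty sequence")
  aln <- nw_align_cpp(normalize_seq(a), normalize_seq(b))
  aln$matches / aln$columns
}

#' Global alignment
#'
#' Full Needleman-Wunsch alignment under the package scoring scheme
#' (see [global_identity()]); used by the center-star consensus builder.
#'
#' @param a,b non-empty nucleotide strings.
#' @return list with `a_aln`, `b_aln` (gapped strings), `matches`,
#'   `columns`, `score`.
#' @export
global_align <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_align: empty sequence")
  nw_align_cpp(normalize_seq(a), normalize_seq(b))
}

# All occurrences (overlapping) of a fixed pattern; 1-based start positions.
find_all <- function(seq, pattern) {
  hits <- gregexpr(paste0("(?=\\Q", pattern, "\\E)"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

# ---- FASTA / FASTQ ----------------------------------------------------------

split_header <- function(nm) {
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  list(id = id, desc = desc)
}

warn_duplicates <- function(id, path) {
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    warning("duplicate ids in ", path, ": ", paste(dup, collapse = ", "),
            " (all records kept)", call. = FALSE)
}

#' Read FASTA
#'
#' Reads a (possibly gzip-compressed) FASTA file into a record data frame.
#' Sequences are uppercased and U is mapped to T; duplicate ids are kept
#' with a warning.
#'
#' @param path file path.
#' @return record data frame (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("parse error reading FASTA ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  h <- split_header(names(set))
  warn_duplicates(h$id, path)
  seq_records(h$id, as.character(set), h$desc)
}

#' Read FASTQ
#'
#' Reads a (possibly gzip-compressed) Sanger Phred+33 FASTQ file into a
#' record data frame, preserving qualities.
#'
#' @param path file path.
#' @return record data frame with `qual` filled.
#' @export
read_fastq <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fastq",
                                             with.qualities = TRUE),
                  error = function(e) stop("parse error reading FASTQ ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  h <- split_header(names(set))
  warn_duplicates(h$id, path)
  seq_records(h$id, as.character(set), h$desc,
              qual = as.character(S4Vectors::mcols(set)$qualities))
}

#' Write FASTA / FASTQ
#'
#' Round-trips [read_fasta()] / [read_fastq()]: id, description and sequence
#' are preserved (qualities too for FASTQ). A `.gz` suffix triggers gzip
#' compression.
#'
#' @param records record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, format = "fasta",
                              compress = grepl("\\.gz$", path), width = 80L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  qual[is.na(qual)] <- vapply(nchar(records$seq[is.na(qual)]),
                              function(n) strrep("I", n), character(1))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# ---- bundled probe and transcript constants ---------------------------------

#' Hybridization probes
#'
#' The two pericentromeric satellite oligonucleotide probes used throughout
#' the pipeline: DYZ1, a 48-mer built on the ATTCC pentamer (the selection
#' bait for HS2/HS3 transcripts), and PCT14, a 50-mer from a chromosome-14
#' HS3 subfamily built on the opposite-strand GGAAT pentamer.
#'
#' @return a list with `name`, `seq` and `declared_strand_motif`.
#' @export
dyz1_probe <- function() {
  list(name = "DYZ1",
       seq = "TCCATTCCATTCCATTCCATTCCATTCCATTCCATTCCATTCCATTCC",
       declared_strand_motif = "ATTCC")
}

#' @rdname dyz1_probe
#' @export
pct14_probe <- function() {
  list(name = "PCT14",
       seq = "TCAACCCGAGTGTGTTTCATTGGAATGGAACGAAAGGAAGGGAATGGGGT",
       declared_strand_motif = "GGAAT")
}

#' Published HS2/HS3 oocyte transcripts
#'
#' The four most abundant polyadenylated HS2/HS3 transcript cDNAs assembled
#' from public GV/MII oocyte transcriptomes, named by the SRA run they were
#' assembled from. All begin with a polyT leader (cDNA orientation of the
#' polyA tail).
#'
#' @return record data frame with four entries.
#' @export
published_transcripts <- function() {
  seq_records(
    id = c("SRR5295893", "SRR5295901_t1", "SRR5295901_t2", "SRR6350575"),
    desc = c("Reyes et al.", "Reyes et al. transcript 1",
             "Reyes et al. transcript 2", "Zhang et al."),
    seq = c(
      paste0(
        "TTTTTTTTTTTTTTTATTCCATTCAAGTCCATTCCATTCCATTCCATTCTATTCCATTCCATTCCAC",
        "TCCGCTCCAATCCATTCCATTCGAGCCCATTCCATTCCATTATATTCCATTCGACTCTATTCCGTTC",
        "CAATACTCTTGAGTCCATTCCATTCCACTCCATTCCAATCCATTACATTCCTTTCGAGTCCATTCCA",
        "TTGCTTCCAAATCCTTTCCATTCAATTTCATTCGAGTCCATTCCATTCCACTCCATTCTATTCCATT",
        "CAAGTCCATTCCTTTGCATTCCACTCCATTCCATTCCATTCCATTCCAGTCCATTTCATTTCATTGC",
        "ATTTCATCCCAGTCCATTCCATTCCACTTCTTTCCATTCCATTCATGTCCATTCAATTCCATTCCAT",
        "TCGTGTACATTCC"),
      paste0(
        "TTTTTTTTTTTTTTTTTTTTTTTTTTTCATTCCATTCCATTCCATTCCATTCCATTCCATTCCATTC",
        "CATTCCATTGCATTCCATTCCATTCCATTCCATTGCACTGCACTCCATTCCATTACATTCTACTCTA",
        "TCTGAGTCGGTTTTATTGCATTAGATTCTATTCCATTGGATTACTTTCCATTCGATTACATTCCATT",
        "CATGTACATTCCATTCCAGTCAATTACATTCGAGTTCATTACGTTACATTCCAGTATATTCCATTGT",
        "ATTCGATCCCATTCCTTTCAATTCCATTTCATTCGACTCCATTATATTCGATTCCATTCCACTCGAA",
        "TCCATTCCATTAGAGGACATTCCATTCAGAT"),
      paste0(
        "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTGCCATTCTATTTCATTGCAATGCATTCCATTCCATTCC",
        "ATTCCATTCCATTCCATTCCATCACATTACATTACGTTTGCACCCAGTTCATTTCATGCCATTCGAT",
        "GCCAATACATACCATTCCATTCGAATCCATTCAATTTCATTCCATTATAGTCAATTCCATTCCATTC",
        "AATTATATTACATTCCTTTCAAGTCTATTCCATTCCATTACTTTCCATTTGTGACCATTCCATTGCA",
        "TTCCATTCGAGTCCATCCACTCGAGTCCATTCCATTCCATTCCATTCCATTCCTTTCGAGTCCACTC",
        "AATTCCATAG"),
      paste0(
        "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTCGATGATTGTTCCATTCGATTCTGTTCGGTGATTCCAT",
        "TCGATTCCATTTGATAATGATTCCGTTCGAGACCATTCGATGATTCCATTCAATTCCATTCAATAAA",
        "GATTCCATTCGAGTCCATTCATTGATTCCCTTCAAGTCCATTCGATGATTCCATCAGATTCCATTCA",
        "ATGAATCCATTCGATTCCATTCAGTGATGATTCCATTCATTTCCATCTGATGATGATTCCATTCGAT",
        "TCCATTCAATGATTCCATTCAATTCCATTTGATGATGATTTCAATCAATTTCATTCGGTGATTCCAT",
        "TCGAATCCACTCGATGATGAGTCCATCCATTTCAATTTCATGATAATTCCATTCGTTTCCTTTCGAT",
        "GGCGTTTCCATTCGATTCCATTCGATGTTGATTCCATTTGTTTCCATTGGATGATGATTCCGTTCGT",
        "GTCCATTCGATGATGATCATATTGGATTTCATTCCATAATTCTATTCGAATCCATTTGATGAT")))
}

#' qPCR assay constants
#'
#' The HS2/HS3 qPCR primer pair (designed on the SRR6350575 transcript) and
#' the two reference-gene primer pairs used for relative quantification.
#'
#' @return named list of primer sequences.
#' @export
qpcr_primers <- function() {
  list(
    hs_fwd = "CGTTTCCTTTCGATGGCGTT",
    hs_rev = "TGAAATCCAATATGATCATCATCGAA",
    gapdh_fwd = "AGGTCGGAGTCAACGGATTT",
    gapdh_rev = "TTCCCGTTCTCAGCCTTGAC",
    actb_fwd = "ATTGCCGACAGGATGCAGA",
    actb_rev = "GAGTACTTGCGCTCAGGAGGA")
}

#' Reference HS2/HS3 accessions
#'
#' GenBank identifiers of the three already-known HS2/HS3 sequences whose
#' summed TPM serves as the reference trend in donor comparisons. The
#' sequences themselves are external downloads and are never required by
#' the test suite.
#'
#' @return character vector of accession ids.
#' @export
reference_hs_accessions <- function() {
  c("X60726.1", "S90110.1", "X82942.1")
}
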