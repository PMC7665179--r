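#!/usr/bin/env Rscript
# Desk analyses of the four published HS2/HS3 oocyte transcript cDNAs:
# polyT leaders, DYZ1 half-probe screening, motif annotation (ATTCC/GGAAT,
# CAACCCGAGT, GATGAT), satellite block segmentation and in-silico PCR with
# the published primer pair.

suppressPackageStartupMessages(library(satseeker))
dir.create("results/published", showWarnings = FALSE, recursive = TRUE)

t1 <- published_transcripts()
p <- qpcr_primers()

tails <- do.call(rbind, lapply(seq_len(nrow(t1)), function(i) {
  tl <- detect_tail(t1$seq[i], max_mismatch_frac = 0)
  data.frame(id = t1$id[i], length = nchar(t1$seq[i]),
             tail_side = tl$side, tail_base = tl$base, tail_len = tl$length)
}))
write.table(tails, "results/published/tails.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

scr <- screen_probe(t1, dyz1_probe())
ann <- annotate_repeats(t1)
ann$annotations$dyz1_half_probe_pass <- unname(scr$pass)
write.table(ann$annotations, "results/published/annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_blocks_bed(ann$blocks, "results/published/blocks.bed")

amps <- do.call(rbind, lapply(seq_len(nrow(t1)), function(i)
  in_silico_pcr(t1$seq[i], p$hs_fwd, p$hs_rev, seq_id = t1$id[i])))
write.table(amps, "results/published/amplicons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("All four cDNAs start with polyT leaders of",
    paste(tails$tail_len, collapse = "/"), "bp.\n")
cat(sum(scr$pass), "of 4 pass the exact half-DYZ1 screen;",
    sum(ann$annotations$gatgat_count > 0), "carries the GATGAT hallmark.\n")
cat("The published primer pair amplifies", nrow(amps), "product(s) of",
    paste(amps$length, collapse = ","), "bp (SRR6350575 only).\n")
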