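#!/usr/bin/env Rscript
# Stage 2: extract introns from the annotation and count, per intron and
# sample, the reads traversing the exon-exon (EEJR), exon-intron (EIJR) and
# intron-exon (IEJR) junctions. Writes results/junction_counts.tsv.

suppressMessages(library(irscore))

introns <- extract_introns("results/data/annotation.gtf")
samples <- read.delim("results/data/sample_sheet.tsv")

counts <- count_samples(samples, introns, min_anchor = 5)
counts <- merge(introns[c("intron_id", "chrom", "start", "end", "strand",
                          "length")], counts, by = "intron_id")
counts <- counts[order(counts$intron_id, counts$sample_id), ]
write.table(counts, "results/junction_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

filt <- filter_low_coverage(counts, min_total = 10,
                            all_introns = introns$intron_id)
writeLines(filt$kept, "results/introns_kept.txt")

cat("annotated introns:", nrow(introns), "\n")
cat("junction-count rows:", nrow(counts), "\n")
cat("introns with >= 10 junction reads in every condition:",
    length(filt$kept), "(dropped:", length(filt$dropped), ")\n")
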