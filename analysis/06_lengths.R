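#!/usr/bin/env Rscript
# Stage 6: intron-length-stratified splicing defects. Bins classified
# introns into 20-40/40-60/60-100/100-500/>500 nt classes (plus the 10-nt
# scan), profiles IRS and IRSdiff per bin, and runs pairwise Wilcoxon
# rank-sum comparisons. Writes results/lengths/.

suppressMessages(library(irscore))

dir.create("results/lengths", showWarnings = FALSE)
introns <- extract_introns("results/data/annotation.gtf")
summ <- read.delim("results/irs_summary.tsv")
cats <- read.delim("results/intron_categories.tsv")

keep <- cats$intron_id[cats$category %in%
  c("STRONGLY_AFFECTED", "MILDLY_AFFECTED", "UNAFFECTED")]
summ_k <- summ[summ$intron_id %in% keep, ]

prof <- length_defect_profile(summ_k, cats, introns)
write.table(prof$profile, "results/lengths/length_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

d <- merge(summ_k, introns[c("intron_id", "length")], by = "intron_id")
vals <- split(d$irs_diff, bin_by_length(d$length)$bin)
wm <- suppressWarnings(compare_bins(vals))
write.table(data.frame(bin = rownames(wm), wm, check.names = FALSE),
            "results/lengths/wilcoxon_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

scan <- length_defect_profile(summ_k, cats, introns, bins = scan_bins())
write.table(scan$profile, "results/lengths/scan_10nt_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("per-bin median IRSdiff:\n")
print(prof$profile[c("bin", "n", "irs_diff_median")])
cat("pairwise Wilcoxon p-values (IRSdiff between length bins):\n")
print(signif(wm, 3))
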