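#!/usr/bin/env Rscript
# Stage 5: splice-site sequence features. Extracts 5'SS/3'SS windows,
# builds position probability/information matrices for all, strongly
# affected (top Z quartile) and unaffected introns, the differential
# (Jensen-Shannon) profile between the latter two, per-position Fisher
# tests, exonic signature groups and their IRS/IRSdiff ECDFs, and U5 loop1
# pairing scores. Writes results/motifs/.

suppressMessages(library(irscore))

dir.create("results/motifs", showWarnings = FALSE)
genome <- Biostrings::readDNAStringSet("results/data/genome.fa")
introns <- extract_introns("results/data/annotation.gtf")
summ <- read.delim("results/irs_summary.tsv")
cats <- read.delim("results/intron_categories.tsv")

win <- extract_site_windows(genome, introns)
win$signature_group <- assign_signature_group(win$last3_exon,
                                              win$first1_exon3)
win$u5_pairing <- vapply(win$last3_exon, u5_pairing_score, 0L)
write.table(win, "results/motifs/site_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

strong <- cats$intron_id[cats$high_confidence_z %in% TRUE]
unaff <- cats$intron_id[cats$category == "UNAFFECTED"]
pw_strong <- build_matrix(win$five_prime_window[win$intron_id %in% strong])
pw_unaff <- build_matrix(win$five_prime_window[win$intron_id %in% unaff])
dl <- diff_matrix(pw_strong, pw_unaff)
write.table(data.frame(position = seq_along(dl$jsd), jsd = dl$jsd,
                       t(dl$diff)),
            "results/motifs/difflogo_5ss.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# enrichment of the exonic -3/-2/-1 bases in unaffected vs strong introns
for (pos in 1:3) {
  base <- c("A", "A", "G")[pos]
  ft <- position_fisher(win$five_prime_window[win$intron_id %in% unaff],
                        win$five_prime_window[win$intron_id %in% strong],
                        pos, base)
  cat(sprintf("5' exon position -%d, base %s: OR %.2f, p %.3g\n",
              4 - pos, base, ft$odds_ratio, ft$p_value))
}

sg <- merge(win[c("intron_id", "signature_group", "u5_pairing")], summ,
            by = "intron_id")
sg <- sg[is.finite(sg$irs_diff), ]
ecdf_tab <- rbind(
  cbind(score = "irs_wt", group_irs_curves(sg$mean_wt, sg$signature_group)),
  cbind(score = "irs_diff",
        group_irs_curves(sg$irs_diff, sg$signature_group)))
write.table(ecdf_tab, "results/motifs/group_ecdf.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

med <- tapply(sg$irs_diff, sg$signature_group, median)
cat("median IRSdiff by signature group:\n")
print(round(med, 2))
cat("U5 pairing by group (AAG ends pair fully with loop1 CUU):\n")
print(tapply(sg$u5_pairing, sg$signature_group, mean))
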