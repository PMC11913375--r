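test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(intron_length_mixture = list(c(0.5, 40, 60))),
               "sum to 1")
  expect_error(sim_config(rho_wt = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(exon_length = c(50L, 80L)), "read_length")
  expect_error(sim_config(exons_per_gene = c(1L, 1L)), "exons_per_gene")
  expect_error(sim_config(signature_proportions = c(AAG_G = 1)), "four groups")
  expect_equal(sum(default_signature_proportions()), 1)
})

test_that("intron lengths track the configured mixture (mean near 56 nt)", {
  cfg <- sim_config(n_genes = 170, exons_per_gene = c(4L, 4L),
                    intron_length_mixture = list(c(1, 40, 70)), seed = 101)
  sim <- simulate_genome(cfg)
  expect_gte(nrow(sim$introns), 500)
  expect_lt(abs(mean(sim$introns$length) - 56), 5)
  expect_true(all(sim$introns$length >= 40 & sim$introns$length <= 70))
})

test_that("canonical sites are forced and truth matches annotation", {
  cfg <- sim_config(n_genes = 40, seed = 5)
  sim <- simulate_genome(cfg)
  win <- extract_site_windows(sim$genome, sim$introns)
  expect_true(all(substr(win$five_prime_window, 4, 5) == "GT"))
  expect_true(all(substr(win$three_prime_window, 5, 6) == "AG"))
  expect_equal(sim$truth$length, sim$truth$end - sim$truth$start)
  expect_true(all(sim$truth$rho_wt >= 0 & sim$truth$rho_wt <= 1))
  expect_true(all(sim$truth$rho_kd >= 0 & sim$truth$rho_kd <= 1))
})

test_that("same config and seed give byte-identical FASTA and GTF", {
  cfg <- sim_config(n_genes = 15, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_genome(cfg, outdir = d1)
  simulate_genome(cfg, outdir = d2)
  for (f in c("genome.fa", "annotation.gtf", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("empirical signature-group frequencies match configured proportions", {
  cfg <- sim_config(n_genes = 400, exons_per_gene = c(3L, 3L), seed = 9)
  sim <- simulate_genome(cfg)
  n <- nrow(sim$introns)
  obs <- table(factor(sim$introns$signature_group,
                      names(cfg$signature_proportions)))
  p <- cfg$signature_proportions
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(as.integer(obs) - n * p) <= 3 * sigma + 1))
})

test_that("rho extremes produce pure read classes", {
  cfg0 <- sim_config(n_genes = 8, rho_wt = 0, rho_kd = 0,
                     coverage_mean = 20, seed = 2)
  sim0 <- simulate_genome(cfg0)
  aln0 <- simulate_alignments(sim0, withr::local_tempdir())
  expect_true(all(aln0$counts$eijr == 0 & aln0$counts$iejr == 0))
  cfg1 <- sim_config(n_genes = 8, rho_wt = 1, rho_kd = 1,
                     coverage_mean = 20, seed = 2)
  sim1 <- simulate_genome(cfg1)
  aln1 <- simulate_alignments(sim1, withr::local_tempdir())
  expect_true(all(aln1$counts$eejr == 0))
  sam <- readLines(aln1$samples$path[1])
  sam <- sam[!startsWith(sam, "@")]
  expect_false(any(grepl("N", vapply(strsplit(sam, "\t"), `[`, "", 6))))
})

test_that("pooled boundary-read fraction matches the binomial expectation", {
  truth <- data.frame(intron_id = sprintf("t%04d", 1:1000),
                      rho_wt = 0.5, rho_kd = 0.5)
  cfg <- sim_config(n_genes = 1, coverage_mean = 200, dispersion = 10,
                    n_replicates = 2L, seed = 77)
  cnt <- simulate_junction_counts(truth, cfg)
  frac <- sum(cnt$eijr + cnt$iejr) / sum(cnt$eejr + cnt$eijr + cnt$iejr)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("deterministic-mode counts round-trip exactly through counting", {
  cfg <- sim_config(n_genes = 10, coverage_mean = 20, deterministic = TRUE,
                    seed = 13)
  sim <- simulate_genome(cfg)
  aln <- simulate_alignments(sim, withr::local_tempdir())
  introns <- extract_introns(sim$exons)
  for (i in seq_len(2)) {  # one sample per condition suffices
    path <- aln$samples$path[c(1, 4)][i]
    sid <- aln$samples$sample_id[c(1, 4)][i]
    got <- count_junctions(path, introns)
    want <- aln$counts[aln$counts$sample_id == sid, ]
    m <- merge(got, want, by = "intron_id")
    expect_equal(m$eejr.x, m$eejr.y)
    expect_equal(m$eijr.x, m$eijr.y)
    expect_equal(m$iejr.x, m$iejr.y)
  }
})

test_that("simulated reads stay within chromosome bounds", {
  cfg <- sim_config(n_genes = 12, coverage_mean = 15, seed = 21)
  sim <- simulate_genome(cfg)
  aln <- simulate_alignments(sim, withr::local_tempdir())
  clen <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  for (p in aln$samples$path) {
    for (rd in oracle_parse_sam(p)) {
      expect_gte(rd$blocks[1, 1], 1)
      expect_lte(rd$blocks[nrow(rd$blocks), 2], clen[[rd$chrom]])
    }
  }
})

test_that("stochastic counts recover expectations within sampling error", {
  cfg <- sim_config(n_genes = 40, coverage_mean = 80, dispersion = 50,
                    rho_wt = 0.3, rho_kd = 0.3, seed = 31)
  sim <- simulate_genome(cfg)
  cnt <- simulate_junction_counts(sim$truth, cfg)
  wt <- cnt[cnt$condition == "WT", ]
  pooled_rho <- sum(wt$eijr + wt$iejr) / sum(wt$eejr + wt$eijr + wt$iejr)
  expect_lt(abs(pooled_rho - 0.3), 0.03)
  expect_lt(abs(mean(wt$eejr + wt$eijr + wt$iejr) - 80), 80 * 0.1)
})
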