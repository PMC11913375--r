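test_that("site windows slice plus- and minus-strand sequence correctly", {
  # chrT: positions 1..30 = A, 31..40 hand-set around a toy intron [20, 26)
  base <- rep("A", 60)
  # exon ends at 1-based 20 with TAC; intron 21..26 = GTNNAG; exon starts CGG
  base[18:20] <- c("T", "A", "C")
  base[21:26] <- c("G", "T", "T", "T", "A", "G")
  base[27:29] <- c("C", "G", "G")
  genome <- Biostrings::DNAStringSet(c(chrT = paste(base, collapse = "")))
  introns <- data.frame(intron_id = c("p", "m"), chrom = "chrT",
                        start = 20L, end = 26L, strand = c("+", "-"),
                        length = 6L)
  w <- extract_site_windows(genome, introns, e5 = 3, i5 = 6, i3 = 6, e3 = 1)
  expect_equal(w$five_prime_window[1], "TACGTTTAG")
  expect_equal(w$three_prime_window[1], "GTTTAGC")
  expect_equal(w$last3_exon[1], "TAC")
  expect_equal(w$first1_exon3[1], "C")
  # minus strand reads the opposite ends, reverse-complemented
  expect_equal(w$five_prime_window[2], "CCGCTAAAC")
  expect_equal(w$three_prime_window[2], "CTAAACG")
  expect_equal(w$last3_exon[2], "CCG")
  expect_equal(w$first1_exon3[2], "G")
  expect_true(all(w$short_intron_overlap))  # length 6 < i5 + i3
})

test_that("introns too close to contig ends are dropped with a warning", {
  genome <- Biostrings::DNAStringSet(c(chrT = strrep("A", 50)))
  introns <- data.frame(intron_id = c("edge", "ok"), chrom = "chrT",
                        start = c(2L, 20L), end = c(10L, 40L),
                        strand = "+", length = c(8L, 20L))
  expect_warning(w <- extract_site_windows(genome, introns), "contig ends")
  expect_equal(w$intron_id, "ok")
  expect_error(
    extract_site_windows(genome,
                         data.frame(intron_id = "x", chrom = "chrZ",
                                    start = 10L, end = 20L, strand = "+",
                                    length = 10L)),
    "chrZ")
})

test_that("position matrices carry correct probabilities and information", {
  m <- build_matrix(c("AA", "AC", "AG", "AT"))
  expect_equal(unname(m$information[1]), 2)
  expect_equal(unname(m$information[2]), 0)
  expect_equal(colSums(m$probabilities), c(1, 1), ignore_attr = TRUE)
  m2 <- build_matrix(c("A", "A", "A", "C"))
  expect_equal(unname(m2$information[1]),
               2 + 0.75 * log2(0.75) + 0.25 * log2(0.25), tolerance = 1e-12)
  expect_error(build_matrix(c("AA", "A")), "equal length")
  # ambiguous bases are dropped from the column count
  m3 <- build_matrix(c("AN", "AA"))
  expect_equal(unname(m3$probabilities["A", 2]), 1)
})

test_that("differential profile is the per-position JSD in bits", {
  p <- build_matrix(c("AC", "AC"))
  expect_equal(diff_matrix(p, p)$jsd, c(0, 0), ignore_attr = TRUE)
  a <- build_matrix(rep("A", 4)); c4 <- build_matrix(rep("C", 4))
  expect_equal(unname(diff_matrix(a, c4)$jsd), 1)
  half <- build_matrix(c("A", "C"))
  pure <- build_matrix(c("A", "A"))
  dm <- diff_matrix(half, pure)
  expect_equal(unname(dm$jsd), 0.311278, tolerance = 1e-5)
  expect_equal(unname(dm$diff["A", 1]), -0.5)
  expect_error(diff_matrix(p, build_matrix("A")), "geometry")
})

test_that("Fisher test matches exact enumeration on the stated tables", {
  wa <- c(rep("A", 3), "C"); wb <- c("A", rep("C", 3))
  ft <- position_fisher(wa, wb, 1, "A")     # table [[3,1],[1,3]]
  expect_equal(ft$p_value, oracle_fisher_exact(ft$table), tolerance = 1e-12)
  expect_equal(ft$p_value, 0.4857143, tolerance = 1e-6)
  ft0 <- position_fisher(rep("A", 5), rep("C", 5), 1, "A")  # [[5,0],[0,5]]
  expect_equal(ft0$p_value, 0.007936508, tolerance = 1e-8)
  fteq <- position_fisher(c("A", "C"), c("A", "C"), 1, "A")
  expect_equal(fteq$p_value, 1)
  expect_error(position_fisher(wa, wb, 5, "A"), "out of window")
  expect_error(position_fisher(wa, character(0), 1, "A"), "non-empty")
})

test_that("signature groups follow the precedence rules and partition", {
  expect_equal(assign_signature_group("AAG", "G"), "AAG_G")
  expect_equal(assign_signature_group("AAG", "C"), "AAG_H")
  expect_equal(assign_signature_group("TTC", "A"), "BBH_H")  # UUC..A context
  expect_equal(assign_signature_group("AAA", "G"), "NNN_N")
  expect_equal(assign_signature_group("NAG", "G"), "NNN_N")  # ambiguous base
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(b1 = bases, b2 = bases, b3 = bases, f = bases,
                        stringsAsFactors = FALSE)
  grp <- assign_signature_group(paste0(combos$b1, combos$b2, combos$b3),
                                combos$f)
  expect_setequal(unique(grp), c("AAG_G", "AAG_H", "BBH_H", "NNN_N"))
  expect_equal(sum(table(grp)), nrow(combos))       # total function
  expect_equal(unname(table(grp)["AAG_G"]), 1L)
  expect_equal(unname(table(grp)["AAG_H"]), 3L)
  expect_equal(unname(table(grp)["BBH_H"]), 3 * 3 * 3 * 3 - 0L)
})

test_that("U5 loop1 pairing scores reproduce the register logic", {
  expect_equal(u5_pairing_score("AAG", "CUU"), 3)
  expect_equal(u5_pairing_score("UUC", "CUU"), 0)
  expect_equal(u5_pairing_score("UUC", "GAA"), 3)
  expect_equal(u5_pairing_score("TTC", "GAA"), 3)   # DNA alphabet accepted
  expect_equal(u5_pairing_score("GUG", "CAU", allow_wobble = FALSE), 2)
  expect_equal(u5_pairing_score("GUG", "CAU", allow_wobble = TRUE), 3)
  expect_error(u5_pairing_score("AAGG", "CUU"), "3-mer")
  # perfect score against the reverse complement of any 3-mer
  rc <- function(x) chartr("ACGU", "UGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (x in c("AAA", "ACG", "GGC", "UUC", "CAU")) {
    expect_equal(u5_pairing_score(x, rc(x)), 3)
  }
})

test_that("group ECDF tables are right-continuous and reach one", {
  out <- group_irs_curves(c(1, 2, 2, 3), rep("a", 4))
  expect_equal(out$value, c(1, 2, 3))
  expect_equal(out$cum_frac, c(0.25, 0.75, 1))
  single <- group_irs_curves(5, "b")
  expect_equal(single$cum_frac, 1)
  # stochastically smaller group dominates pointwise
  two <- group_irs_curves(c(1:10, 6:15), rep(c("lo", "hi"), each = 10))
  at <- function(g, x) {
    sub <- two[two$group == g, ]
    if (!any(sub$value <= x)) 0 else max(sub$cum_frac[sub$value <= x])
  }
  for (x in 0:16) expect_gte(at("lo", x), at("hi", x))
  expect_warning(group_irs_curves(c(1, NA), c("a", "b")), "omitted")
})

test_that("group-wise defect ordering is recovered from simulation", {
  # knockdown effect ordered AAG_G < AAG_H < BBH_H by construction
  cfg <- sim_config(
    n_genes = 150, exons_per_gene = c(3L, 3L), coverage_mean = 100,
    dispersion = 10,
    signature_proportions = c(AAG_G = 0.25, AAG_H = 0.25, BBH_H = 0.25,
                              NNN_N = 0.25),
    rho_wt = 0.08,
    rho_kd = c(AAG_G = 0.1, AAG_H = 0.25, BBH_H = 0.55, NNN_N = 0.35),
    seed = 53)
  sim <- simulate_genome(cfg)
  s <- summarize_conditions(compute_irs(simulate_junction_counts(sim$truth, cfg)))
  d <- merge(s, sim$truth[c("intron_id", "signature_group")], by = "intron_id")
  med <- tapply(d$irs_diff, d$signature_group, median)
  expect_lt(med[["AAG_G"]], med[["AAG_H"]])
  expect_lt(med[["AAG_H"]], med[["BBH_H"]])
})
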