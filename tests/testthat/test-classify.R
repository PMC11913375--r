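mk_summ <- function(z, d, ids = sprintf("i%02d", seq_along(z))) {
  data.frame(intron_id = ids, mean_wt = 0, sd_wt = 0.1, n_wt = 3L,
             mean_kd = d, sd_kd = 0.1, n_kd = 3L, irs_diff = d,
             z_score = z, p_value = 2 * pnorm(-abs(z)), tested = TRUE)
}

test_that("quartile thresholds follow the descending midpoint convention", {
  q <- z_quartiles(c(8, 7, 6, 5, 4, 3, 2, 1))
  expect_equal(unname(q["q1_threshold"]), 6.5)
  expect_equal(unname(q["q3_threshold"]), 2.5)
  q2 <- z_quartiles(rep(3, 6))
  expect_equal(unname(q2["q1_threshold"]), unname(q2["q3_threshold"]))
  expect_error(z_quartiles(c(1, 2, NaN, 4)), "positions: 3")
  expect_error(z_quartiles(c(1, 2, 3)), "at least 4")
})

test_that("the hand-traced eight-intron table reproduces its frozen labels", {
  z <- c(4, 3.5, 3, 2.5, 1, 0.5, -0.2, -1)
  d <- c(3.0, 2.4, 1.2, 0.8, 0.4, 0.3, 0.2, -0.5)
  out <- classify_introns(mk_summ(z, d), strong_cut = 2)
  out <- out[match(sprintf("i%02d", 1:8), out$intron_id), ]
  # quartile threshold over all 8 z values is 3.25; candidates z > 3.25 give
  # cutoff c = min(3.0, 2.4) = 2.4; the negative/negative intron is excluded
  expect_equal(attr(out, "irs_diff_cutoff"), 2.4)
  expect_equal(unname(attr(out, "z_thresholds")["q1_threshold"]), 3.25)
  expect_equal(out$category,
               c("STRONGLY_AFFECTED", "STRONGLY_AFFECTED",
                 rep("UNAFFECTED", 5), "EXCLUDED_NEGATIVE"))
  expect_equal(out$high_confidence_z,
               c(TRUE, TRUE, rep(FALSE, 6)))
})

test_that("negative irs_diff with negative z is excluded", {
  out <- classify_introns(mk_summ(c(3, 2, 1, -1.1), c(2, 1.5, 1, -0.3)))
  expect_equal(out$category[out$intron_id == "i04"], "EXCLUDED_NEGATIVE")
})

test_that("uniform positive irs_diff makes every intron affected", {
  out <- classify_introns(mk_summ(c(4, 3, 2, 1), rep(1.5, 4)))
  expect_equal(attr(out, "irs_diff_cutoff"), 1.5)
  expect_true(all(out$category == "MILDLY_AFFECTED"))
})

test_that("ties at the strong cut stay mildly affected (strict split)", {
  out <- classify_introns(mk_summ(c(4, 3, 2, 1), c(2.0, 2.0, 2.0, 2.0)),
                          strong_cut = 2)
  expect_true(all(out$category == "MILDLY_AFFECTED"))
  out2 <- classify_introns(mk_summ(c(4, 3, 2, 1), c(2.01, 2.0, 2.0, 2.0)),
                           strong_cut = 2)
  expect_equal(sum(out2$category == "STRONGLY_AFFECTED"), 1)
})

test_that("categories partition the tested introns", {
  set.seed(6)
  z <- rnorm(200, 1); d <- rnorm(200, 1)
  out <- classify_introns(mk_summ(z, d, ids = sprintf("p%03d", 1:200)))
  cc <- category_counts(out)
  expect_equal(sum(cc), 200)
  expect_equal(unname(cc["LOW_COVERAGE"]), 0L)
})

test_that("raising strong_cut never promotes mild introns to strong", {
  set.seed(7)
  s <- mk_summ(rnorm(100, 1.5), rnorm(100, 2), sprintf("q%03d", 1:100))
  a <- classify_introns(s, strong_cut = 1.5)
  b <- classify_introns(s, strong_cut = 2.5)
  was_mild <- a$intron_id[a$category == "MILDLY_AFFECTED"]
  expect_false(any(b$category[b$intron_id %in% was_mild] ==
                     "STRONGLY_AFFECTED"))
})

test_that("untested introns come back as LOW_COVERAGE", {
  s <- mk_summ(c(3, 2, 1.5, 1, 0.5), c(2, 1, 1, 0.5, 0.4))
  s$tested[5] <- FALSE
  s$z_score[5] <- NA
  out <- classify_introns(s)
  expect_equal(out$category[out$intron_id == "i05"], "LOW_COVERAGE")
})

test_that("classification recovers designated affected introns", {
  # 30% of introns with a 4-fold retention increase, the rest null
  set.seed(3)
  n <- 600
  affected <- rep(c(TRUE, FALSE), times = c(0.3 * n, 0.7 * n))
  truth <- data.frame(intron_id = sprintf("r%04d", 1:n),
                      rho_wt = 0.1, rho_kd = ifelse(affected, 0.4, 0.1))
  cfg <- sim_config(n_genes = 1, coverage_mean = 100, dispersion = 10,
                    seed = 37)
  s <- summarize_conditions(compute_irs(simulate_junction_counts(truth, cfg)))
  out <- classify_introns(s)
  out <- out[match(truth$intron_id, out$intron_id), ]
  called_aff <- out$category %in% c("STRONGLY_AFFECTED", "MILDLY_AFFECTED")
  sens <- mean(called_aff[affected])
  spec <- mean(!called_aff[!affected] )
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("sensitivity is monotone non-decreasing in effect size", {
  cfg <- sim_config(n_genes = 1, coverage_mean = 100, dispersion = 10,
                    seed = 41)
  sens_at <- function(fold) {
    n <- 400
    affected <- rep(c(TRUE, FALSE), times = c(0.3 * n, 0.7 * n))
    truth <- data.frame(intron_id = sprintf("m%04d", 1:n), rho_wt = 0.1,
                        rho_kd = ifelse(affected, pmin(0.1 * fold, 1), 0.1))
    s <- summarize_conditions(compute_irs(simulate_junction_counts(truth, cfg)))
    out <- classify_introns(s)
    out <- out[match(truth$intron_id, out$intron_id), ]
    mean(out$category[affected] %in% c("STRONGLY_AFFECTED", "MILDLY_AFFECTED"))
  }
  s <- vapply(c(2, 4, 8), sens_at, 1)
  expect_true(all(diff(s) >= -0.02))
})
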