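#' Per-replicate intron retention score
#'
#' Converts junction counts into the intron retention score (IRS) for every
#' intron and sample. The retention level averages the two retained-intron
#' junction counts against the spliced junction count with a pseudocount:
#' `retention_level = (eijr + iejr + 2a) / (2 * (eejr + a))`, and
#' `irs = log2(retention_level)`. The pseudocount `a` keeps the score finite
#' for all counts; at `a = 1` a fully symmetric case (`eijr = iejr = eejr`)
#' gives IRS = 0.
#'
#' @param counts Data frame with columns `eejr, eijr, iejr` (plus any
#'   identifier columns, which are carried through).
#' @param pseudocount Pseudocount `a` added to each junction class.
#' @return `counts` with `retention_level` and `irs` columns appended.
#' @examples
#' compute_irs(data.frame(eejr = 31, eijr = 0, iejr = 0))$irs  # -5
#' @export
compute_irs <- function(counts, pseudocount = 1) {
  stopifnot(all(c("eejr", "eijr", "iejr") %in% names(counts)))
  if (any(counts$eejr < 0 | counts$eijr < 0 | counts$iejr < 0))
    stop("junction counts must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  counts$retention_level <-
    (counts$eijr + counts$iejr + 2 * pseudocount) /
    (2 * (counts$eejr + pseudocount))
  counts$irs <- log2(counts$retention_level)
  counts
}

#' Per-intron condition summary and two-sample Z test
#'
#' Aggregates replicate-level IRS values per intron and condition into
#' means and sample standard deviations (n - 1 denominator), the IRS
#' difference `irs_diff = mean(KD) - mean(WT)`, and an unpooled two-sample Z
#' statistic `z = irs_diff / sqrt(sd_kd^2 / n_kd + sd_wt^2 / n_wt + floor)`
#' with two-sided normal p-value, testing the null hypothesis of equal IRS
#' between conditions. A small variance floor guards replicate sets with
#' zero variance. Introns with fewer than two replicates in either condition
#' are flagged (`tested = FALSE`) and carry `NA` statistics.
#'
#' @param irs Data frame from [compute_irs()] with `intron_id, condition,
#'   irs` (conditions labelled as in `wt`/`kd`).
#' @param wt,kd Condition labels for wild type and knockdown.
#' @param var_floor Variance floor added inside the square root.
#' @return Data frame with one row per intron: `intron_id, mean_wt, sd_wt,
#'   n_wt, mean_kd, sd_kd, n_kd, irs_diff, z_score, p_value, tested`.
#' @export
summarize_conditions <- function(irs, wt = "WT", kd = "KD", var_floor = 1e-6) {
  stopifnot(all(c("intron_id", "condition", "irs") %in% names(irs)))
  sub <- irs[irs$condition %in% c(wt, kd), ]
  stat <- function(cond, f) {
    x <- sub[sub$condition == cond, ]
    tapply(x$irs, x$intron_id, f)
  }
  ids <- sort(unique(sub$intron_id))
  pick <- function(v) unname(v[ids])
  out <- data.frame(
    intron_id = ids,
    mean_wt = pick(stat(wt, mean)), sd_wt = pick(stat(wt, sd)),
    n_wt = pick(stat(wt, length)),
    mean_kd = pick(stat(kd, mean)), sd_kd = pick(stat(kd, sd)),
    n_kd = pick(stat(kd, length))
  )
  out$n_wt[is.na(out$n_wt)] <- 0L
  out$n_kd[is.na(out$n_kd)] <- 0L
  out$tested <- out$n_wt >= 2L & out$n_kd >= 2L
  out$irs_diff <- out$mean_kd - out$mean_wt
  se <- sqrt(out$sd_kd^2 / out$n_kd + out$sd_wt^2 / out$n_wt + var_floor)
  out$z_score <- out$irs_diff / se
  out$p_value <- 2 * pnorm(-abs(out$z_score))
  out$irs_diff[!out$tested] <- NA_real_
  out$z_score[!out$tested] <- NA_real_
  out$p_value[!out$tested] <- NA_real_
  rownames(out) <- NULL
  out[c("intron_id", "mean_wt", "sd_wt", "n_wt", "mean_kd", "sd_kd", "n_kd",
        "irs_diff", "z_score", "p_value", "tested")]
}
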