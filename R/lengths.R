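#' Length-bin definitions
#'
#' The default partition mirrors the five classes used for the
#' length-stratified splicing analysis: 20-40, 40-60, 60-100, 100-500 and
#' >500 nt, with lower-inclusive / upper-exclusive intervals so shared
#' endpoints are not double-counted. `scan_bins()` gives the finer preset
#' of 10-nt bins over \[20, 100) used for the high-resolution scan.
#'
#' @param edges Increasing numeric vector of bin edges; the last bin is
#'   unbounded when the final edge is finite.
#' @return Data frame `label, lower, upper` (upper exclusive, possibly Inf).
#' @export
length_bins <- function(edges = c(20, 40, 60, 100, 500)) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  lower <- edges
  upper <- c(edges[-1], Inf)
  label <- ifelse(is.finite(upper),
                  paste0(lower, "-", upper),
                  paste0(">", lower))
  data.frame(label = label, lower = lower, upper = upper)
}

#' @rdname length_bins
#' @export
scan_bins <- function() {
  b <- length_bins(seq(20, 100, by = 10))
  b[b$label != ">100", ]
}

#' Assign introns to length bins
#'
#' Each intron falls in exactly one bin under the lower-inclusive /
#' upper-exclusive convention; introns shorter than the first edge are
#' reported separately rather than binned.
#'
#' @param lengths Integer intron lengths (nt).
#' @param bins Bin table from [length_bins()] or [scan_bins()].
#' @return List with `bin` (factor of bin labels, `NA` below the first
#'   edge, ordered as in `bins`) and `below_min` (indices of introns
#'   shorter than the first edge).
#' @export
bin_by_length <- function(lengths, bins = length_bins()) {
  if (any(lengths < 1)) stop("intron lengths must be >= 1")
  if (is.unsorted(bins$lower, strictly = TRUE)) stop("edges must be sorted")
  idx <- findInterval(lengths, c(bins$lower, bins$upper[nrow(bins)]))
  idx[idx == 0 | lengths >= bins$upper[nrow(bins)]] <- NA
  idx[!is.na(idx) & idx > nrow(bins)] <- NA
  list(bin = factor(bins$label[idx], levels = bins$label),
       below_min = which(lengths < bins$lower[1]))
}

#' Pairwise Wilcoxon rank-sum comparisons between bins
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum tests for every pair of bins.
#' The exact null distribution is enumerated when both samples have at most
#' `exact_max` values and no ties are present; otherwise the mid-rank
#' normal approximation (with continuity correction) is used.
#'
#' @param values_by_bin Named list of numeric vectors (one per bin).
#' @param exact_max Largest per-group size for which the exact test is used.
#' @return Symmetric matrix of p-values (diagonal `NA`); bins with no
#'   values are excluded with a warning.
#' @export
compare_bins <- function(values_by_bin, exact_max = 20L) {
  keep <- vapply(values_by_bin, function(v) sum(is.finite(v)) > 0, TRUE)
  if (any(!keep))
    warning("empty bins excluded: ",
            paste(names(values_by_bin)[!keep], collapse = ", "))
  values_by_bin <- lapply(values_by_bin[keep], function(v) v[is.finite(v)])
  nb <- length(values_by_bin)
  if (nb < 2) stop("at least two non-empty bins are required")
  p <- matrix(NA_real_, nb, nb,
              dimnames = list(names(values_by_bin), names(values_by_bin)))
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    x <- values_by_bin[[i]]; y <- values_by_bin[[j]]
    exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !anyDuplicated(c(x, y))
    pv <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact))$p.value
    p[i, j] <- p[j, i] <- pv
  }
  p
}

#' Length-stratified splicing-defect profile
#'
#' Joins intron lengths, condition summaries and categories, then reports
#' per length bin: the number of introns, median and quartiles of wild-type
#' IRS and of the IRS difference, the per-category composition (the input
#' of a stacked-bar view), and ECDF tables of both scores.
#'
#' @param summaries Data frame from [summarize_conditions()].
#' @param categories Data frame from [classify_introns()].
#' @param introns Intron table with `intron_id` and `length`.
#' @param bins Bin table from [length_bins()] or [scan_bins()].
#' @return List with `profile` (one row per bin), `composition` (bin x
#'   category counts), `ecdf_irs` and `ecdf_irs_diff` (per-bin ECDF tables).
#' @export
length_defect_profile <- function(summaries, categories, introns,
                                  bins = length_bins()) {
  d <- merge(summaries, introns[c("intron_id", "length")], by = "intron_id")
  d <- merge(d, categories[c("intron_id", "category")],
             by = "intron_id", all.x = TRUE)
  d <- d[is.finite(d$irs_diff), ]
  bb <- bin_by_length(d$length, bins)
  d$bin <- bb$bin
  d <- d[!is.na(d$bin), ]

  qfun <- function(x) quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 2)
  rows <- lapply(split(d, d$bin, drop = FALSE), function(g) {
    if (!nrow(g)) return(data.frame(n = 0L, irs_wt_q1 = NA_real_,
      irs_wt_median = NA_real_, irs_wt_q3 = NA_real_, irs_diff_q1 = NA_real_,
      irs_diff_median = NA_real_, irs_diff_q3 = NA_real_))
    qa <- qfun(g$mean_wt); qb <- qfun(g$irs_diff)
    data.frame(n = nrow(g), irs_wt_q1 = qa[1], irs_wt_median = qa[2],
               irs_wt_q3 = qa[3], irs_diff_q1 = qb[1],
               irs_diff_median = qb[2], irs_diff_q3 = qb[3])
  })
  profile <- cbind(bin = names(rows), do.call(rbind, rows))
  rownames(profile) <- NULL
  composition <- table(d$bin, d$category)
  list(profile = profile,
       composition = composition,
       ecdf_irs = group_irs_curves(d$mean_wt, as.character(d$bin)),
       ecdf_irs_diff = group_irs_curves(d$irs_diff, as.character(d$bin)))
}
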