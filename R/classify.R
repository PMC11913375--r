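#' Z-score quartile thresholds under the descending-sort convention
#'
#' The Z scores are conceptually sorted in descending order and divided into
#' quartiles: `q1_threshold` is the value above which the top 25% lie and
#' `q3_threshold` the value above which the top 75% lie. Midpoint
#' interpolation (quantile type 2) is the default rule; alternate base-R
#' quantile types can be supplied.
#'
#' @param z Numeric vector of at least 4 finite Z scores.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named numeric vector `c(q1_threshold, q3_threshold)`.
#' @examples
#' z_quartiles(8:1)  # q1 = 6.5, q3 = 2.5
#' @export
z_quartiles <- function(z, type = 2) {
  bad <- which(!is.finite(z))
  if (length(bad))
    stop("non-finite z scores at positions: ", paste(bad, collapse = ", "))
  if (length(z) < 4) stop("at least 4 z scores are required")
  q <- quantile(z, c(0.75, 0.25), type = type, names = FALSE)
  c(q1_threshold = q[1], q3_threshold = q[2])
}

#' Classify introns by splicing-defect severity
#'
#' Reproduces the categorization of tested introns into strongly affected,
#' mildly affected, unaffected and excluded sets:
#' \enumerate{
#'   \item Z-quartile thresholds are computed over all tested introns.
#'   \item Introns with negative `irs_diff` and negative `z_score` are set
#'     aside as `EXCLUDED_NEGATIVE` (likely false positives) and take no part
#'     in deriving the cutoff.
#'   \item The affected/unaffected cutoff `c` is the minimum `irs_diff` among
#'     remaining introns with `z_score > q1_threshold`.
#'   \item An intron is affected when `irs_diff >= c`, otherwise
#'     `UNAFFECTED`; affected introns with `irs_diff > strong_cut` are
#'     `STRONGLY_AFFECTED`, the rest `MILDLY_AFFECTED` (ties at the cut are
#'     mild, the split being strict).
#'   \item `high_confidence_z = z_score > q1_threshold` is recorded
#'     independently of the category, giving the alternative
#'     top-quartile definition of strongly affected introns used by the
#'     sequence-feature analyses.
#' }
#'
#' @param summaries Data frame from [summarize_conditions()]; rows with
#'   `tested = FALSE` (or missing statistics) are labelled `LOW_COVERAGE`.
#' @param strong_cut IRS-difference threshold separating strongly from
#'   mildly affected introns.
#' @param quantile_type Quantile convention, see [z_quartiles()].
#' @return Data frame `intron_id, category, z_score, irs_diff,
#'   high_confidence_z` with attributes `irs_diff_cutoff` and `z_thresholds`.
#' @export
classify_introns <- function(summaries, strong_cut = 2.0, quantile_type = 2) {
  s <- summaries
  if (is.null(s$tested)) s$tested <- is.finite(s$z_score)
  tested <- s[s$tested & is.finite(s$z_score), ]
  low <- setdiff(s$intron_id, tested$intron_id)

  qs <- z_quartiles(tested$z_score, type = quantile_type)
  excluded <- tested$irs_diff < 0 & tested$z_score < 0
  candidates <- tested[!excluded & tested$z_score > qs[["q1_threshold"]], ]
  if (nrow(candidates) == 0)
    stop("no introns above the first Z quartile; cannot derive cutoff")
  cutoff <- min(candidates$irs_diff)

  category <- ifelse(excluded, "EXCLUDED_NEGATIVE",
              ifelse(tested$irs_diff >= cutoff,
                     ifelse(tested$irs_diff > strong_cut,
                            "STRONGLY_AFFECTED", "MILDLY_AFFECTED"),
                     "UNAFFECTED"))
  out <- data.frame(
    intron_id = c(tested$intron_id, low),
    category = c(category, rep("LOW_COVERAGE", length(low))),
    z_score = c(tested$z_score, rep(NA_real_, length(low))),
    irs_diff = c(tested$irs_diff, rep(NA_real_, length(low))),
    high_confidence_z = c(tested$z_score > qs[["q1_threshold"]],
                          rep(NA, length(low)))
  )
  rownames(out) <- NULL
  attr(out, "irs_diff_cutoff") <- cutoff
  attr(out, "z_thresholds") <- qs
  out
}

#' Tabulate classification categories
#'
#' @param categories Result of [classify_introns()].
#' @return Named integer vector of category counts (all five categories,
#'   zero-filled).
#' @export
category_counts <- function(categories) {
  lev <- c("STRONGLY_AFFECTED", "MILDLY_AFFECTED", "UNAFFECTED",
           "EXCLUDED_NEGATIVE", "LOW_COVERAGE")
  table(factor(categories$category, levels = lev))
}
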