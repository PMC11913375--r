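#' Count junction reads per intron for one sample
#'
#' Classifies primary, mapped alignments against a set of introns. A gapped
#' alignment increments `eejr` of an intron when one of its N-operation gaps
#' equals the intron exactly and the aligned blocks flanking that gap each
#' cover at least `min_anchor` nt. A contiguous aligned block increments
#' `eijr` when it covers the donor-side window
#' `[start - min_anchor, start + min_anchor)` and `iejr` when it covers the
#' acceptor-side window `[end - min_anchor, end + min_anchor)` (0-based
#' half-open intron coordinates). A read may hit several introns but counts
#' for at most one junction type per intron, with precedence
#' exon-exon > exon-intron > intron-exon. Read strand is ignored.
#'
#' @param alignments Path to a SAM or BAM file, or a
#'   [GenomicAlignments::GAlignments] object. SAM input is converted with
#'   [Rsamtools::asBam()]; secondary, supplementary and unmapped records are
#'   excluded.
#' @param introns Intron table from [extract_introns()] (0-based half-open).
#' @param min_anchor Minimum aligned nt on each side of a junction.
#' @return Data frame with one row per intron: `intron_id, eejr, eijr, iejr`
#'   (zero-filled), with attribute `skipped` tallying records dropped for
#'   unsupported CIGAR operations or unknown chromosomes.
#' @export
count_junctions <- function(alignments, introns, min_anchor = 5L) {
  ga <- read_alignments(alignments)
  a <- as.integer(min_anchor)
  skipped <- c(unsupported_cigar = 0L, unknown_chrom = 0L)

  bad <- grepl("P", GenomicAlignments::cigar(ga), fixed = TRUE)
  skipped[["unsupported_cigar"]] <- sum(bad)
  ga <- ga[!bad]
  known <- as.character(GenomicAlignments::seqnames(ga)) %in% unique(introns$chrom)
  skipped[["unknown_chrom"]] <- sum(!known)

  intron_gr <- GenomicRanges::GRanges(
    introns$chrom, IRanges::IRanges(introns$start + 1L, introns$end))
  donor_win <- GenomicRanges::GRanges(
    introns$chrom, IRanges::IRanges(introns$start - a + 1L, introns$start + a))
  accept_win <- GenomicRanges::GRanges(
    introns$chrom, IRanges::IRanges(introns$end - a + 1L, introns$end + a))

  hits <- list()
  if (length(ga)) {
    # aligned blocks on the reference: split at N gaps only (D merged)
    bl <- GenomicAlignments::extractAlignmentRangesOnReference(
      GenomicAlignments::cigar(ga), GenomicAlignments::start(ga),
      drop.D.ranges = FALSE)
    nb <- S4Vectors::elementNROWS(bl)
    flat_w <- IRanges::width(unlist(bl, use.names = FALSE))

    junc <- GenomicAlignments::junctions(ga)
    nj <- S4Vectors::elementNROWS(junc)
    if (sum(nj)) {
      ujunc <- unlist(junc, use.names = FALSE)
      jread <- rep(seq_along(ga), nj)
      jrank <- sequence(nj)
      off <- cumsum(c(0L, nb))[jread]
      left_w <- flat_w[off + jrank]
      right_w <- flat_w[off + jrank + 1L]
      ee <- GenomicRanges::findOverlaps(ujunc, intron_gr, type = "equal",
                                        ignore.strand = TRUE)
      ok <- left_w[S4Vectors::queryHits(ee)] >= a &
            right_w[S4Vectors::queryHits(ee)] >= a
      qh <- S4Vectors::queryHits(ee)[ok]
      hits$ee <- data.frame(read = jread[qh],
                            intron = S4Vectors::subjectHits(ee)[ok],
                            type = rep(1L, length(qh)))
    }

    blgr <- GenomicRanges::GRanges(
      rep(GenomicAlignments::seqnames(ga), nb), unlist(bl, use.names = FALSE))
    bread <- rep(seq_along(ga), nb)
    ei <- GenomicRanges::findOverlaps(donor_win, blgr, type = "within",
                                      ignore.strand = TRUE)
    hits$ei <- data.frame(read = bread[S4Vectors::subjectHits(ei)],
                          intron = S4Vectors::queryHits(ei),
                          type = rep(2L, length(ei)))
    ie <- GenomicRanges::findOverlaps(accept_win, blgr, type = "within",
                                      ignore.strand = TRUE)
    hits$ie <- data.frame(read = bread[S4Vectors::subjectHits(ie)],
                          intron = S4Vectors::queryHits(ie),
                          type = rep(3L, length(ie)))
  }
  h <- do.call(rbind, hits)
  counts <- data.frame(intron_id = introns$intron_id,
                       eejr = 0L, eijr = 0L, iejr = 0L)
  if (!is.null(h) && nrow(h)) {
    h <- h[order(h$type), ]                     # precedence EE > EI > IE
    h <- h[!duplicated(h[c("read", "intron")]), ]
    tab <- table(factor(h$intron, levels = seq_len(nrow(introns))), h$type)
    for (ty in colnames(tab)) {
      col <- c("1" = "eejr", "2" = "eijr", "3" = "iejr")[[ty]]
      counts[[col]] <- as.integer(tab[, ty])
    }
  }
  attr(counts, "skipped") <- skipped
  counts
}

read_alignments <- function(alignments) {
  if (is(alignments, "GAlignments")) return(alignments)
  stopifnot(is.character(alignments), length(alignments) == 1L,
            file.exists(alignments))
  path <- alignments
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  GenomicAlignments::readGAlignments(path,
                                     param = Rsamtools::ScanBamParam(flag = flag))
}

#' Count junction reads across a sample sheet
#'
#' Runs [count_junctions()] for every alignment file in a sample sheet and
#' stacks the results into the long per-intron, per-sample count table used
#' by the retention-score stage.
#'
#' @param sample_sheet Data frame with columns `sample_id, condition,
#'   replicate, path`.
#' @param introns Intron table from [extract_introns()].
#' @param min_anchor Minimum aligned nt on each side of a junction.
#' @return Data frame: `intron_id, sample_id, condition, replicate, eejr,
#'   eijr, iejr`.
#' @export
count_samples <- function(sample_sheet, introns, min_anchor = 5L) {
  stopifnot(all(c("sample_id", "condition", "replicate", "path") %in%
                  names(sample_sheet)))
  out <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    cnt <- count_junctions(sample_sheet$path[i], introns, min_anchor)
    data.frame(intron_id = cnt$intron_id,
               sample_id = sample_sheet$sample_id[i],
               condition = sample_sheet$condition[i],
               replicate = sample_sheet$replicate[i],
               eejr = cnt$eejr, eijr = cnt$eijr, iejr = cnt$iejr)
  })
  do.call(rbind, out)
}

#' Filter introns with insufficient junction-read coverage
#'
#' An intron is kept when, in every condition, the sum of its junction reads
#' (`eejr + eijr + iejr`) over that condition's replicates reaches
#' `min_total`; introns failing the threshold in any condition (including
#' introns absent from the count table) are dropped as low-coverage. The
#' per-condition aggregation guarantees that the retention score is
#' estimable in both conditions before the Z test.
#'
#' @param counts Long count table from [count_samples()] or
#'   [simulate_junction_counts()].
#' @param min_total Minimum per-condition junction-read total (introns with
#'   fewer are filtered out; the boundary value itself is kept).
#' @param all_introns Optional character vector defining the intron universe
#'   (defaults to the introns present in `counts`).
#' @return List with character vectors `kept` and `dropped`.
#' @export
filter_low_coverage <- function(counts, min_total = 10L, all_introns = NULL) {
  tot <- counts$eejr + counts$eijr + counts$iejr
  agg <- stats::aggregate(tot,
                          by = list(intron_id = counts$intron_id,
                                    condition = counts$condition),
                          FUN = sum)
  per_intron <- tapply(agg$x, agg$intron_id, min)
  n_cond <- length(unique(counts$condition))
  cond_seen <- tapply(agg$condition, agg$intron_id,
                      function(x) length(unique(x)))
  kept <- names(per_intron)[per_intron >= min_total & cond_seen == n_cond]
  universe <- unique(c(all_introns, counts$intron_id))
  list(kept = kept, dropped = setdiff(universe, kept))
}
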