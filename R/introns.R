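#' Extract introns from exon annotation
#'
#' Derives one intron record per gap between consecutive exons of each
#' transcript in a GTF annotation (1-based inclusive exon features carrying
#' `gene_id` and `transcript_id`). Introns are deduplicated on
#' (chrom, start, end, strand) across the transcripts of a gene, and the
#' intron index is assigned in transcript orientation: for minus-strand
#' transcripts the highest-coordinate gap is index 1. Internally introns are
#' kept in 0-based half-open coordinates, so `length = end - start`.
#'
#' @param annotation Path to a GTF file, or a `GRanges` of exon features with
#'   `type`, `gene_id` and `transcript_id` metadata columns (as produced by
#'   [rtracklayer::import()] or [simulate_genome()]).
#' @return Data frame with columns `intron_id, chrom, start, end, strand,
#'   gene_id, transcript_id, index, length` (coordinates 0-based half-open).
#'   Zero-length gaps are skipped with a warning.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 151), c(100, 250)),
#'   strand = "+", type = "exon", gene_id = "g1", transcript_id = "g1.t1")
#' extract_introns(gr)
#' @export
extract_introns <- function(annotation) {
  if (is.character(annotation)) {
    check_gtf_lines(annotation)
    annotation <- rtracklayer::import(annotation, format = "gtf")
  }
  stopifnot(is(annotation, "GRanges"))
  mc <- S4Vectors::mcols(annotation)
  if (!is.null(mc$type)) annotation <- annotation[mc$type == "exon"]
  mc <- S4Vectors::mcols(annotation)
  if (is.null(mc$transcript_id)) stop("exon features must carry transcript_id")

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation),
    end = GenomicRanges::end(annotation),
    strand = as.character(GenomicRanges::strand(annotation)),
    gene_id = if (is.null(mc$gene_id)) mc$transcript_id else mc$gene_id,
    transcript_id = mc$transcript_id
  )
  out <- lapply(split(df, df$transcript_id), introns_of_transcript)
  out <- do.call(rbind, out[order(names(out))])
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(intron_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      index = integer(), length = integer()))
  }
  # deduplicate identical introns across transcripts of a gene
  key <- with(out, paste(gene_id, chrom, start, end, strand))
  out <- out[!duplicated(key), ]
  out$intron_id <- make.unique(sprintf("%s_i%d", out$gene_id, out$index),
                               sep = "_dup")
  rownames(out) <- NULL
  out[c("intron_id", "chrom", "start", "end", "strand", "gene_id",
        "transcript_id", "index", "length")]
}

introns_of_transcript <- function(ex) {
  ex <- ex[order(ex$start), ]
  n <- nrow(ex)
  if (n < 2) return(NULL)
  if (any(ex$start[-1] <= ex$end[-n]))
    stop("overlapping exons in transcript ", ex$transcript_id[1])
  g1 <- ex$end[-n] + 1L   # 1-based first intron base
  g2 <- ex$start[-1] - 1L # 1-based last intron base
  keep <- g2 >= g1
  if (!all(keep))
    warning("zero-length exon gap skipped in transcript ", ex$transcript_id[1])
  g1 <- g1[keep]; g2 <- g2[keep]
  if (!length(g1)) return(NULL)
  minus <- ex$strand[1] == "-"
  idx <- if (minus) rev(seq_along(g1)) else seq_along(g1)
  data.frame(chrom = ex$chrom[1], start = g1 - 1L, end = g2,
             strand = ex$strand[1], gene_id = ex$gene_id[1],
             transcript_id = ex$transcript_id[1], index = idx,
             length = g2 - g1 + 1L)
}

# Cheap structural validation so a malformed line is reported with its number
# before handing the file to the GTF parser.
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 9]
  if (length(bad))
    stop("malformed GTF line ", bad[1], " in ", path,
         " (fewer than 9 tab-separated fields)")
  invisible(TRUE)
}
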