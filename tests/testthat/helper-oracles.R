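# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the code paths they check: the SAM oracle
# parses CIGARs by hand and tests every (read, intron) pair with plain
# interval arithmetic.

# ---- SAM parsing and per-pair junction-count oracle -------------------------

oracle_parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    cig <- f[6]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    pos <- as.integer(f[4])          # 1-based
    cur <- pos
    blocks <- list(); gaps <- list()
    bstart <- cur
    for (k in seq_along(op)) {
      if (op[k] %in% c("M", "=", "X", "D")) {
        cur <- cur + n[k]
      } else if (op[k] == "N") {
        blocks[[length(blocks) + 1L]] <- c(bstart, cur - 1L)
        gaps[[length(gaps) + 1L]] <- c(cur, cur + n[k] - 1L)
        cur <- cur + n[k]
        bstart <- cur
      }
      # I, S, H consume no reference
    }
    blocks[[length(blocks) + 1L]] <- c(bstart, cur - 1L)
    list(chrom = f[3], flag = as.integer(f[2]),
         blocks = do.call(rbind, blocks),
         gaps = if (length(gaps)) do.call(rbind, gaps) else
           matrix(0L, 0, 2))
  })
}

# introns: data frame with intron_id, chrom, start, end (0-based half-open)
oracle_count <- function(sam_path, introns, min_anchor = 5L) {
  reads <- oracle_parse_sam(sam_path)
  a <- min_anchor
  out <- data.frame(intron_id = introns$intron_id,
                    eejr = 0L, eijr = 0L, iejr = 0L)
  covers <- function(blocks, from, to) {
    any(blocks[, 1] <= from & blocks[, 2] >= to)
  }
  for (rd in reads) {
    if (bitwAnd(rd$flag, 4L) > 0 || bitwAnd(rd$flag, 256L) > 0 ||
        bitwAnd(rd$flag, 2048L) > 0) next
    for (i in seq_len(nrow(introns))) {
      if (introns$chrom[i] != rd$chrom) next
      s1 <- introns$start[i] + 1L; e1 <- introns$end[i]  # 1-based inclusive
      hit <- NULL
      if (nrow(rd$gaps)) {
        for (g in seq_len(nrow(rd$gaps))) {
          if (rd$gaps[g, 1] == s1 && rd$gaps[g, 2] == e1 &&
              diff(rd$blocks[g, ]) + 1L >= a &&
              diff(rd$blocks[g + 1L, ]) + 1L >= a) {
            hit <- "eejr"; break
          }
        }
      }
      if (is.null(hit) && covers(rd$blocks, s1 - a, s1 + a - 1L)) hit <- "eijr"
      if (is.null(hit) && covers(rd$blocks, e1 - a + 1L, e1 + a)) hit <- "iejr"
      if (!is.null(hit)) out[[hit]][i] <- out[[hit]][i] + 1L
    }
  }
  out
}

# Random toy instance: non-overlapping introns on one contig plus random
# contiguous and gapped reads (some gaps match introns, some do not).
random_instance <- function(seed, n_introns = 20, n_reads = 500,
                            read_length = 60) {
  set.seed(seed)
  gap_sizes <- sample(20:120, n_introns, replace = TRUE)
  exon_sizes <- sample(30:150, n_introns + 1, replace = TRUE)
  starts0 <- cumsum(exon_sizes[-length(exon_sizes)]) +
    c(0, cumsum(gap_sizes))[seq_len(n_introns)]
  introns <- data.frame(intron_id = sprintf("i%03d", seq_len(n_introns)),
                        chrom = "chrT", start = starts0,
                        end = starts0 + gap_sizes, strand = "+")
  clen <- sum(exon_sizes) + sum(gap_sizes) + 200L
  recs <- character(n_reads)
  for (r in seq_len(n_reads)) {
    kind <- sample(c("contig", "exact", "offset"), 1,
                   prob = c(0.5, 0.3, 0.2))
    i <- sample(n_introns, 1)
    s1 <- introns$start[i] + 1L; e1 <- introns$end[i]
    if (kind == "contig") {
      pos <- max(1L, s1 + sample((-read_length):read_length, 1))
      cig <- paste0(read_length, "M")
    } else {
      L <- sample(1:(read_length - 1), 1)
      if (kind == "exact") {
        pos <- s1 - L
        gapw <- e1 - s1 + 1L
      } else {
        pos <- s1 - L + sample(c(-3:-1, 1:3), 1)
        gapw <- e1 - s1 + 1L + sample(-2:2, 1)
      }
      if (pos < 1L) pos <- 1L
      cig <- sprintf("%dM%dN%dM", L, gapw, read_length - L)
    }
    recs[r] <- paste(sprintf("r%04d", r), 0L, "chrT", pos, 255L, cig,
                     "*", 0L, 0L,
                     strrep("A", read_length), strrep("I", read_length),
                     sep = "\t")
  }
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:chrT\tLN:%d", clen), recs), sam)
  list(sam = sam, introns = introns)
}

# ---- exact statistical oracles ----------------------------------------------

# two-sided exact Wilcoxon rank-sum p by full enumeration of assignments
oracle_wilcox_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  idx <- utils::combn(n, nx)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  stats <- apply(idx, 2, function(ii) sum(r[ii]))
  lower <- mean(stats <= obs); upper <- mean(stats >= obs)
  min(1, 2 * min(lower, upper))
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_exact <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(d[d <= obs * (1 + 1e-7)])
}

# ---- misc --------------------------------------------------------------------

write_sam <- function(records, chroms) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms),
               records), path)
  path
}

sam_line <- function(qname, chrom, pos, cigar, flag = 0L, len = NULL) {
  if (is.null(len)) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIS=X]", cigar))[[1]]
    len <- sum(as.integer(sub("[A-Z=]", "", ops)))
  }
  paste(qname, flag, chrom, pos, 255L, cigar, "*", 0L, 0L,
        strrep("A", len), strrep("I", len), sep = "\t")
}

toy_introns <- function(starts, ends, chrom = "chrT") {
  data.frame(intron_id = sprintf("i%02d", seq_along(starts)),
             chrom = chrom, start = starts, end = ends, strand = "+")
}
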