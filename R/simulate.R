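#' Simulate a toy short-intron genome with annotation and ground truth
#'
#' Generates a multi-contig genome (one single-transcript gene per contig),
#' its exon annotation, and a per-intron truth table. Intron lengths are
#' drawn from the configured mixture, terminal dinucleotides are forced to
#' GT..AG when `canonical_sites`, and for every intron the last three exonic
#' nucleotides before the donor and the first exonic nucleotide after the
#' acceptor are planted according to the configured signature-group
#' proportions. Genes are placed on either strand; minus-strand genes are
#' written to the genome as the reverse complement of their transcript-
#' oriented sequence. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param outdir Optional directory; if given, writes `genome.fa` (60-column
#'   FASTA), `annotation.gtf` (1-based inclusive exon features with
#'   `gene_id`/`transcript_id`) and `truth.tsv`.
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet]),
#'   `exons` (a `GRanges` of exon features), `introns` (data frame of intron
#'   records, 0-based half-open coordinates), `truth` (data frame with
#'   signature group, length and true retention fractions per condition) and,
#'   when `outdir` is given, `paths`.
#' @seealso [simulate_alignments()], [simulate_junction_counts()]
#' @export
simulate_genome <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  pad <- 50L

  genes <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("g%04d", g)
    n_ex <- resample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
    ex_len <- resample(config$exon_length[1]:config$exon_length[2], n_ex)
    n_int <- n_ex - 1L
    bin <- sample.int(nrow(config$intron_length_mixture), n_int,
                      replace = TRUE,
                      prob = config$intron_length_mixture$weight)
    in_len <- mapply(function(lo, hi) resample(lo:hi, 1L),
                     config$intron_length_mixture$lower[bin],
                     config$intron_length_mixture$upper[bin])
    in_len <- as.integer(in_len)

    grp <- sample(names(config$signature_proportions), n_int, replace = TRUE,
                  prob = config$signature_proportions)
    sig <- lapply(grp, draw_signature)
    last3 <- vapply(sig, `[[`, "", 1L)
    first1 <- vapply(sig, `[[`, "", 2L)

    # transcript-oriented sequence: exon1 intron1 exon2 ... exonN
    ex_seq <- lapply(ex_len, function(n) sample(bases, n, replace = TRUE))
    in_seq <- lapply(in_len, function(n) sample(bases, n, replace = TRUE))
    for (j in seq_len(n_int)) {
      ex_seq[[j]][(ex_len[j] - 2L):ex_len[j]] <- strsplit(last3[j], "")[[1]]
      ex_seq[[j + 1L]][1L] <- first1[j]
      if (config$canonical_sites) {
        in_seq[[j]][1:2] <- c("G", "T")
        n <- in_len[j]
        in_seq[[j]][(n - 1L):n] <- c("A", "G")
      }
    }
    pieces <- vector("list", n_ex + n_int)
    pieces[seq(1L, by = 2L, length.out = n_ex)] <- ex_seq
    if (n_int > 0) pieces[seq(2L, by = 2L, length.out = n_int)] <- in_seq
    tx_seq <- unlist(pieces, use.names = FALSE)
    G <- length(tx_seq)

    # transcript coordinates of exons (1-based inclusive)
    piece_len <- vapply(pieces, length, 1L)
    piece_end <- cumsum(piece_len)
    piece_start <- piece_end - piece_len + 1L
    ex_idx <- seq(1L, by = 2L, length.out = n_ex)
    ts <- piece_start[ex_idx]; te <- piece_end[ex_idx]

    strand <- sample(c("+", "-"), 1L)
    chrom_seq <- c(sample(bases, pad, replace = TRUE),
                   if (strand == "+") tx_seq else rev(chartr("ACGT", "TGCA", tx_seq)),
                   sample(bases, pad, replace = TRUE))
    # map transcript interval [a,b] to genomic 1-based coordinates
    gmap <- function(a, b) {
      if (strand == "+") c(pad + a, pad + b) else c(pad + G - b + 1L, pad + G - a + 1L)
    }
    ex_g <- t(mapply(gmap, ts, te))
    genes[[g]] <- list(
      gene_id = gene_id, chrom = sprintf("chr%04d", g), strand = strand,
      seq = paste(chrom_seq, collapse = ""),
      exon_start = ex_g[, 1L], exon_end = ex_g[, 2L],
      intron_len = in_len, group = grp, last3 = last3, first1 = first1,
      ts = ts, te = te, G = G, pad = pad
    )
  }

  genome <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "seq"))
  names(genome) <- vapply(genes, `[[`, "", "chrom")

  exon_rows <- do.call(rbind, lapply(genes, function(gn) {
    n_ex <- length(gn$exon_start)
    ord <- if (gn$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    data.frame(chrom = gn$chrom,
               start = sort(gn$exon_start), end = sort(gn$exon_end),
               strand = gn$strand, gene_id = gn$gene_id,
               transcript_id = paste0(gn$gene_id, ".t1"),
               exon_number = ord[order(gn$exon_start)])
  }))
  exons <- GenomicRanges::GRanges(
    exon_rows$chrom,
    IRanges::IRanges(exon_rows$start, exon_rows$end),
    strand = exon_rows$strand,
    type = "exon", source = "irscore_sim",
    gene_id = exon_rows$gene_id, transcript_id = exon_rows$transcript_id,
    exon_number = exon_rows$exon_number
  )

  introns <- do.call(rbind, lapply(genes, function(gn) {
    n_int <- length(gn$intron_len)
    if (n_int == 0) return(NULL)
    # transcript-oriented intron j lies between exon j and j+1
    a <- gn$te[seq_len(n_int)] + 1L       # transcript 1-based first intron base
    b <- gn$ts[seq_len(n_int) + 1L] - 1L  # transcript 1-based last intron base
    if (gn$strand == "+") {
      g1 <- gn$pad + a; g2 <- gn$pad + b
    } else {
      g1 <- gn$pad + gn$G - b + 1L; g2 <- gn$pad + gn$G - a + 1L
    }
    data.frame(
      intron_id = sprintf("%s_i%d", gn$gene_id, seq_len(n_int)),
      chrom = gn$chrom, start = g1 - 1L, end = g2, strand = gn$strand,
      gene_id = gn$gene_id, index = seq_len(n_int),
      length = gn$intron_len,
      signature_group = gn$group, last3_exon = gn$last3,
      first1_exon3 = gn$first1
    )
  }))
  rownames(introns) <- NULL

  truth <- introns[c("intron_id", "chrom", "start", "end", "strand",
                     "signature_group", "last3_exon", "first1_exon3",
                     "length")]
  truth$rho_wt <- resolve_rho(config$rho_wt, truth$signature_group, truth$length)
  truth$rho_kd <- resolve_rho(config$rho_kd, truth$signature_group, truth$length)
  truth$eejr_mean_wt <- config$coverage_mean * (1 - truth$rho_wt)
  truth$eejr_mean_kd <- config$coverage_mean * (1 - truth$rho_kd)
  truth$eijr_mean_wt <- truth$iejr_mean_wt <- config$coverage_mean * truth$rho_wt / 2
  truth$eijr_mean_kd <- truth$iejr_mean_kd <- config$coverage_mean * truth$rho_kd / 2

  sim <- list(genome = genome, exons = exons, introns = introns, truth = truth,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(fasta = file.path(outdir, "genome.fa"),
               gtf = file.path(outdir, "annotation.gtf"),
               truth = file.path(outdir, "truth.tsv"))
    Biostrings::writeXStringSet(genome, paths[["fasta"]], width = 60L)
    rtracklayer::export(exons, paths[["gtf"]], format = "gtf")
    write_tsv(truth, paths[["truth"]])
    sim$paths <- paths
  }
  sim
}

# One concrete (last-3-exonic, first-exonic) pair consistent with a group.
# B = {C,G,T}, H = {A,C,T}; NNN_N is the complement of the first three rules.
draw_signature <- function(group) {
  B <- c("C", "G", "T"); H <- c("A", "C", "T"); N <- c("A", "C", "G", "T")
  switch(group,
    AAG_G = list("AAG", "G"),
    AAG_H = list("AAG", sample(H, 1L)),
    BBH_H = list(paste0(sample(B, 1L), sample(B, 1L), sample(H, 1L)),
                 sample(H, 1L)),
    NNN_N = repeat_until_nnn(N, H),
    stop("unknown signature group: ", group)
  )
}

repeat_until_nnn <- function(N, H) {
  repeat {
    l3 <- paste(sample(N, 3L, replace = TRUE), collapse = "")
    f1 <- sample(N, 1L)
    if (signature_group_of(l3, f1) == "NNN_N") return(list(l3, f1))
  }
}

#' Draw replicate-level junction counts from the generative model
#'
#' For every intron, condition and replicate draws the total number of
#' junction-spanning reads `N` from a negative binomial with mean
#' `coverage_mean` and size `dispersion`, the number of retained
#' (boundary-crossing) reads `K ~ Binomial(N, rho)`, splits `K` between the
#' donor and acceptor junctions with equal probability, and reports
#' `eejr = N - K`. In deterministic mode counts equal rounded expectations.
#' This is the count-level core of [simulate_alignments()]; it is also
#' useful on its own for statistical calibration at large intron numbers
#' without materializing reads.
#'
#' @param truth Truth table from [simulate_genome()] (needs `intron_id`,
#'   `rho_wt`, `rho_kd`), or any data frame with those columns.
#' @param config A [sim_config()].
#' @param seed Seed for the draws (defaults to `config$seed + 1`).
#' @return Data frame with one row per intron x condition x replicate:
#'   `intron_id, sample_id, condition, replicate, eejr, eijr, iejr`.
#' @export
simulate_junction_counts <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  conds <- c(WT = "rho_wt", KD = "rho_kd")
  out <- vector("list", 2L * config$n_replicates)
  k <- 0L
  n_int <- nrow(truth)
  for (cond in names(conds)) {
    rho <- truth[[conds[[cond]]]]
    for (r in seq_len(config$n_replicates)) {
      if (config$deterministic) {
        N <- rep_len(round(config$coverage_mean), n_int)
        K <- round(N * rho)
        eij <- floor(K / 2)
      } else {
        N <- rnbinom(n_int, mu = config$coverage_mean, size = config$dispersion)
        K <- rbinom(n_int, N, rho)
        eij <- rbinom(n_int, K, 0.5)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        intron_id = truth$intron_id,
        sample_id = sprintf("%s_rep%d", cond, r),
        condition = cond, replicate = r,
        eejr = as.integer(N - K), eijr = as.integer(eij),
        iejr = as.integer(K - eij)
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate spliced and retained alignments as SAM files
#'
#' Materializes the counts drawn by [simulate_junction_counts()] as reads:
#' spliced reads are gapped alignments whose N operation spans the intron
#' exactly, with at least `min_anchor` aligned nt on both sides; retained
#' reads are contiguous alignments crossing the donor or the acceptor
#' boundary with at least `min_anchor` nt on both sides of that boundary,
#' placed so that they never satisfy the anchor condition at the opposite
#' boundary of the same intron (so counting recovers the generator's table
#' exactly in deterministic mode). One SAM file is written per condition and
#' replicate. Deterministic given the seed.
#'
#' @param sim Result of [simulate_genome()].
#' @param outdir Directory for the SAM files (created if needed).
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @param seed Seed (defaults to `config$seed + 1`, so the realized counts
#'   equal those of [simulate_junction_counts()] at the same seed).
#' @return A list with `samples` (data frame: `sample_id, condition,
#'   replicate, path`) and `counts` (the realized per-intron count table the
#'   SAM files encode).
#' @export
simulate_alignments <- function(sim, outdir, config = sim$config,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  introns <- sim$introns
  if (any(introns$length > 5e8)) stop("intron longer than representable gap")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- simulate_junction_counts(sim$truth, config, seed = seed)

  chrom_str <- setNames(as.character(sim$genome), names(sim$genome))
  R <- config$read_length; a <- config$min_anchor
  idx <- match(counts$intron_id, introns$intron_id)
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sim$genome),
                      Biostrings::width(sim$genome)))

  samples <- unique(counts[c("sample_id", "condition", "replicate")])
  samples$path <- file.path(outdir, paste0(samples$sample_id, ".sam"))
  qual <- strrep("I", R)

  for (i in seq_len(nrow(samples))) {
    sel <- which(counts$sample_id == samples$sample_id[i])
    recs <- character(0)
    for (j in sel) {
      it <- introns[idx[j], ]
      s <- it$start; e <- it$end; len <- it$length
      nm <- paste(it$intron_id, samples$sample_id[i], sep = ".")
      # spliced reads: left flank L uniform within anchors and flanking exons
      n_ee <- counts$eejr[j]
      if (n_ee > 0) {
        L <- sample_int_range(a, R - a, n_ee)
        pos <- s + 1L - L                     # 1-based alignment start
        cig <- sprintf("%dM%dN%dM", L, len, R - L)
        seqs <- paste0(substring(chrom_str[[it$chrom]], pos, s),
                       substring(chrom_str[[it$chrom]], e + 1L, e + R - L))
        recs <- c(recs, sam_record(sprintf("%s.e%d", nm, seq_len(n_ee)),
                                   it$chrom, pos, cig, seqs, qual))
      }
      # donor-crossing reads, not reaching the acceptor window
      n_ei <- counts$eijr[j]
      if (n_ei > 0) {
        st0 <- sample_int_range(s + a - R, min(s - a, s + len + a - R - 1L), n_ei)
        pos <- st0 + 1L
        seqs <- substring(chrom_str[[it$chrom]], pos, st0 + R)
        recs <- c(recs, sam_record(sprintf("%s.d%d", nm, seq_len(n_ei)),
                                   it$chrom, pos, paste0(R, "M"), seqs, qual))
      }
      # acceptor-crossing reads, not reaching the donor window
      n_ie <- counts$iejr[j]
      if (n_ie > 0) {
        st0 <- sample_int_range(max(e - R + a, s - a + 1L), e - a, n_ie)
        pos <- st0 + 1L
        seqs <- substring(chrom_str[[it$chrom]], pos, st0 + R)
        recs <- c(recs, sam_record(sprintf("%s.a%d", nm, seq_len(n_ie)),
                                   it$chrom, pos, paste0(R, "M"), seqs, qual))
      }
    }
    writeLines(c(header, recs), samples$path[i])
  }
  rownames(samples) <- NULL
  list(samples = samples, counts = counts)
}

# sample with replacement, safe against the scalar expansion of sample()
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

sample_int_range <- function(lo, hi, n) {
  if (hi < lo) stop("empty placement interval")
  if (lo == hi) rep.int(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

sam_record <- function(qname, chrom, pos, cigar, seq, qual) {
  paste(qname, 0L, chrom, pos, 255L, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
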