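#' Extract splice-site sequence windows
#'
#' For each intron, extracts the donor-side window (`e5` exonic + `i5`
#' intronic nt around the 5' splice site) and the acceptor-side window
#' (`i3` intronic + `e3` exonic nt around the 3' splice site), both in
#' transcript orientation: minus-strand windows are reverse-complemented
#' genomic sequence taken from the opposite intron ends. Also reports the
#' last three exonic nt before the donor and the first exonic nt after the
#' acceptor, the inputs of [assign_signature_group()].
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param introns Intron table (0-based half-open) from [extract_introns()].
#' @param e5,i5,i3,e3 Window extents in nt (defaults cover exonic -3..-1,
#'   intronic positions 1..6 at the donor, intronic -6..-1 and exonic +1 at
#'   the acceptor).
#' @return Data frame `intron_id, five_prime_window, three_prime_window,
#'   last3_exon, first1_exon3, short_intron_overlap`; introns whose windows
#'   would leave the contig are dropped with a warning, and introns shorter
#'   than `i5 + i3` are flagged (`short_intron_overlap`) because their
#'   intronic contexts overlap.
#' @export
extract_site_windows <- function(genome, introns, e5 = 3L, i5 = 6L,
                                 i3 = 6L, e3 = 1L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (e5 < 3L) stop("e5 must be at least 3 (last-3-exon context)")
  if (e3 < 1L) stop("e3 must be at least 1 (first-exon-3 context)")
  missing <- setdiff(unique(introns$chrom), names(genome))
  if (length(missing))
    stop("chromosomes missing from FASTA: ", paste(missing, collapse = ", "))

  s <- introns$start; e <- introns$end
  minus <- introns$strand == "-"
  # 1-based genomic slices; donor side then acceptor side
  fp_from <- ifelse(minus, e - i5 + 1L, s - e5 + 1L)
  fp_to   <- ifelse(minus, e + e5,      s + i5)
  tp_from <- ifelse(minus, s - e3 + 1L, e - i3 + 1L)
  tp_to   <- ifelse(minus, s + i3,      e + e3)

  clen <- setNames(Biostrings::width(genome), names(genome))[introns$chrom]
  ok <- fp_from >= 1L & tp_from >= 1L & fp_to <= clen & tp_to <= clen
  if (!all(ok))
    warning(sum(!ok), " intron(s) too close to contig ends dropped")
  keep <- which(ok)

  slice <- function(from, to) {
    as.character(Biostrings::subseq(genome[introns$chrom[keep]],
                                    start = from[keep], end = to[keep]))
  }
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  fp <- slice(fp_from, fp_to)
  tp <- slice(tp_from, tp_to)
  m <- minus[keep]
  fp[m] <- rc(fp[m])
  tp[m] <- rc(tp[m])

  data.frame(
    intron_id = introns$intron_id[keep],
    five_prime_window = unname(fp),
    three_prime_window = unname(tp),
    last3_exon = substring(fp, e5 - 2L, e5),
    first1_exon3 = substring(tp, i3 + 1L, i3 + 1L),
    short_intron_overlap = introns$length[keep] < i5 + i3
  )
}

#' Position count/probability/information matrix from aligned windows
#'
#' Builds the numeric core of a sequence logo from equal-length sequence
#' windows: per-position base counts, probabilities, and information content
#' `2 + sum_b p log2 p` bits (with `0 log 0 = 0`). Ambiguous bases are
#' excluded from their column's count.
#'
#' @param windows Character vector of equal-length sequences over A/C/G/T.
#' @return Object of class `position_matrix`: list with `counts` (4 x L),
#'   `probabilities`, `information` (length-L bits in \[0, 2\]) and
#'   `n_sequences`.
#' @export
build_matrix <- function(windows) {
  windows <- as.character(windows)
  if (!length(windows)) stop("at least one window is required")
  if (length(unique(nchar(windows))) != 1L)
    stop("windows must have equal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4L, nchar(windows[1]), dimnames = list(bases, NULL))
  present <- intersect(bases, rownames(cm))
  counts[present, ] <- cm[present, , drop = FALSE]
  n_col <- colSums(counts)
  if (any(n_col == 0)) stop("a column contains no unambiguous bases")
  probs <- sweep(counts, 2L, n_col, "/")
  plogp <- ifelse(probs > 0, probs * log2(probs), 0)
  structure(list(counts = counts, probabilities = probs,
                 information = 2 + colSums(plogp),
                 n_sequences = length(windows)),
            class = "position_matrix")
}

#' Per-position divergence profile between two position matrices
#'
#' The numeric core of a differential logo: for each position, the
#' Jensen-Shannon divergence (base 2, hence in \[0, 1\] bit) between the two
#' base-probability vectors, together with the signed per-base probability
#' differences `p - q`.
#'
#' @param p,q `position_matrix` objects over the same window geometry.
#' @return List with `jsd` (per-position bits) and `diff` (4 x L signed
#'   probability differences).
#' @export
diff_matrix <- function(p, q) {
  stopifnot(inherits(p, "position_matrix"), inherits(q, "position_matrix"))
  if (!identical(dim(p$probabilities), dim(q$probabilities)))
    stop("window geometry mismatch between the two matrices")
  P <- p$probabilities; Q <- q$probabilities
  M <- (P + Q) / 2
  kl <- function(A, B) {
    term <- ifelse(A > 0, A * log2(A / B), 0)
    colSums(term)
  }
  jsd <- 0.5 * kl(P, M) + 0.5 * kl(Q, M)
  list(jsd = pmax(jsd, 0), diff = P - Q)
}

#' Fisher's exact test for base enrichment at one window position
#'
#' Tests whether membership of the base at `position` in `base_set` differs
#' between two groups of windows, via the two-sided Fisher exact test on the
#' 2x2 table (base in set vs not) x (group A vs group B). The reported odds
#' ratio is the conditional maximum-likelihood estimate from
#' [stats::fisher.test()].
#'
#' @param windows_a,windows_b Character vectors of equal-length windows.
#' @param position 1-based position within the window.
#' @param base_set Character vector of bases counting as "in set".
#' @return List with `odds_ratio`, `p_value`, `table` and
#'   `odds_ratio_type = "conditional_mle"`.
#' @export
position_fisher <- function(windows_a, windows_b, position, base_set) {
  if (!length(windows_a) || !length(windows_b))
    stop("both groups must be non-empty")
  L <- nchar(windows_a[1])
  if (position < 1 || position > L) stop("position out of window")
  in_set <- function(w) substring(w, position, position) %in% base_set
  tab <- rbind(A = c(sum(in_set(windows_a)), sum(!in_set(windows_a))),
               B = c(sum(in_set(windows_b)), sum(!in_set(windows_b))))
  colnames(tab) <- c("in_set", "other")
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       table = tab, odds_ratio_type = "conditional_mle")
}

#' Assign an intron's exonic signature group
#'
#' Classifies an intron by the last three exonic nucleotides before the 5'
#' splice site and the first exonic nucleotide after the 3' splice site,
#' with IUPAC sets B = \{C,G,T\} and H = \{A,C,T\} and precedence
#' AAG-G, AAG-H, BBH-H, then NNN-N (the complement of the first three
#' rules), so the four groups partition any intron set. Ambiguous bases fall
#' to NNN-N.
#'
#' @param last3_exon Character vector of 3-mers (exon end, 5'->3').
#' @param first1_exon3 Character vector of single bases (3' exon start).
#' @return Character vector over `AAG_G, AAG_H, BBH_H, NNN_N`.
#' @examples
#' assign_signature_group("AAG", "G")  # AAG_G
#' assign_signature_group("TTC", "A")  # BBH_H
#' @export
assign_signature_group <- function(last3_exon, first1_exon3) {
  if (any(nchar(last3_exon) != 3L) || any(nchar(first1_exon3) != 1L))
    stop("last3_exon must be 3-mers and first1_exon3 single bases")
  mapply(signature_group_of, toupper(last3_exon), toupper(first1_exon3),
         USE.NAMES = FALSE)
}

signature_group_of <- function(l3, f1) {
  B <- c("C", "G", "T"); H <- c("A", "C", "T")
  nt <- strsplit(l3, "")[[1]]
  if (!all(c(nt, f1) %in% c("A", "C", "G", "T"))) return("NNN_N")
  if (l3 == "AAG" && f1 == "G") return("AAG_G")
  if (l3 == "AAG" && f1 %in% H) return("AAG_H")
  if (all(nt[1:2] %in% B) && nt[3] %in% H && f1 %in% H) return("BBH_H")
  "NNN_N"
}

#' U5 snRNA loop1 pairing score for a 5'-exon terminus
#'
#' Counts base pairs formed when the last three exonic nucleotides (5'->3')
#' pair antiparallel against a U5 loop1 register (given 5'->3'; the
#' wild-type register is CUU, the rescue mutant GAA). Watson-Crick pairs
#' always count; G-U wobble pairs count only when `allow_wobble`. RNA and
#' DNA alphabets are both accepted (T is treated as U).
#'
#' @param last3_exon 3-mer exon terminus.
#' @param loop_register 3-mer loop1 register, 5'->3'.
#' @param allow_wobble Count G-U pairs as paired.
#' @return Integer 0..3.
#' @examples
#' u5_pairing_score("AAG", "CUU")  # 3
#' u5_pairing_score("UUC", "CUU")  # 0
#' u5_pairing_score("UUC", "GAA")  # 3
#' @export
u5_pairing_score <- function(last3_exon, loop_register = "CUU",
                             allow_wobble = FALSE) {
  norm <- function(x) {
    x <- chartr("tT", "uU", toupper(x))
    if (nchar(x) != 3L) stop("3-mers are required")
    strsplit(chartr("T", "U", x), "")[[1]]
  }
  ex <- norm(last3_exon)
  reg <- rev(norm(loop_register))   # antiparallel: register read 3'->5'
  wc <- function(a, b) (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  wob <- function(a, b) (a == "G" && b == "U") || (a == "U" && b == "G")
  paired <- mapply(function(a, b) wc(a, b) || (allow_wobble && wob(a, b)),
                   ex, reg)
  sum(paired)
}

#' Per-group empirical cumulative distribution tables
#'
#' Builds, for each group, the right-continuous empirical CDF of a score
#' (IRS or IRS difference), as plotted in cumulative-distribution
#' comparisons of intron classes.
#'
#' @param values Numeric vector of scores.
#' @param groups Group label per value.
#' @return Data frame `group, value, cum_frac` with one row per distinct
#'   value per group; within each group `cum_frac` increases to 1. Groups
#'   with no finite values are omitted with a warning.
#' @export
group_irs_curves <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- lapply(split(values, groups), function(v) {
    v <- sort(v[is.finite(v)])
    if (!length(v)) return(NULL)
    ux <- unique(v)
    data.frame(value = ux,
               cum_frac = cumsum(tabulate(match(v, ux))) / length(v))
  })
  empty <- vapply(out, is.null, TRUE)
  if (any(empty))
    warning("groups with no finite values omitted: ",
            paste(names(out)[empty], collapse = ", "))
  out <- out[!empty]
  res <- do.call(rbind, Map(cbind, group = names(out), out))
  rownames(res) <- NULL
  res
}
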