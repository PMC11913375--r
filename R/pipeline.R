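#' Pipeline run configuration
#'
#' Collects every tunable of the analysis with defaults matching the module
#' definitions: junction-count anchoring, the low-coverage filter, the IRS
#' pseudocount, the strong/mild IRS-difference cut, splice-site window
#' extents and length bins. Input is either the bundled simulation (a
#' [sim_config()]) or external files (`genome` FASTA, `gtf` annotation and a
#' `sample_sheet` data frame with `sample_id, condition, replicate, path`).
#' The configuration round-trips through JSON via [write_run_config()] /
#' [read_run_config()].
#'
#' @param sim A [sim_config()] used when no external inputs are given; its
#'   seed is overridden by `seed`.
#' @param genome,gtf,sample_sheet External inputs (all three required
#'   together); when `NULL` the simulation branch is used.
#' @param min_anchor,min_total,pseudocount,strong_cut,var_floor Stage
#'   parameters (see the stage functions for semantics).
#' @param window Named list of splice-site window extents `e5, i5, i3, e3`.
#' @param bins Length-bin table from [length_bins()].
#' @param seed Integer master seed for the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       genome = NULL, gtf = NULL, sample_sheet = NULL,
                       min_anchor = 5L, min_total = 10L, pseudocount = 1,
                       strong_cut = 2.0, var_floor = 1e-6,
                       window = list(e5 = 3L, i5 = 6L, i3 = 6L, e3 = 1L),
                       bins = length_bins(),
                       seed = 1L) {
  external <- !is.null(genome) || !is.null(gtf) || !is.null(sample_sheet)
  if (external && (is.null(genome) || is.null(gtf) || is.null(sample_sheet)))
    stop("genome, gtf and sample_sheet must be supplied together")
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, genome = genome, gtf = gtf,
                 sample_sheet = sample_sheet,
                 min_anchor = as.integer(min_anchor),
                 min_total = as.integer(min_total),
                 pseudocount = pseudocount, strong_cut = strong_cut,
                 var_floor = var_floor, window = window, bins = bins,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  if (is.function(x$sim$rho_wt) || is.function(x$sim$rho_kd))
    stop("function-valued rho cannot be serialized; use scalars or vectors")
  # named vectors must go out as JSON objects, not bare arrays
  for (nm in c("signature_proportions", "rho_wt", "rho_kd")) {
    if (!is.null(names(x$sim[[nm]]))) x$sim[[nm]] <- as.list(x$sim[[nm]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  sim_args <- x$sim
  for (nm in c("rho_wt", "rho_kd", "signature_proportions"))
    sim_args[[nm]] <- unlist(sim_args[[nm]])
  sim <- do.call(sim_config, sim_args)
  bins <- as.data.frame(x$bins)
  bins$upper <- suppressWarnings(as.numeric(bins$upper))
  bins$upper[is.na(bins$upper)] <- Inf  # JSON cannot carry Inf
  x$bins <- bins
  run_config(sim = sim, genome = x$genome, gtf = x$gtf,
             sample_sheet = x$sample_sheet,
             min_anchor = x$min_anchor, min_total = x$min_total,
             pseudocount = x$pseudocount, strong_cut = x$strong_cut,
             var_floor = x$var_floor, window = x$window,
             bins = as.data.frame(x$bins), seed = x$seed)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write_tsv(df, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full intron-retention analysis
#'
#' Executes the stages in dependency order: simulate (unless external inputs
#' are configured), junction counting, low-coverage filtering, IRS and
#' condition summaries, classification, splice-site sequence features and
#' the length-stratified defect profile. All stage tables are written as TSV
#' under `outdir` (atomically, rewritten on rerun), together with a
#' machine-readable `manifest.json` (parameters, input checksums, seed,
#' stage row counts) and a human-readable `summary.txt`. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param verbose Print one line per stage.
#' @return Invisibly, a list with the main stage tables and the manifest.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[irscore] ", ...)

  if (is.null(config$genome)) {
    say("stage simulate: ", config$sim$n_genes, " genes, seed ", config$seed)
    sim <- with_stage("simulate", {
      s <- simulate_genome(config$sim, outdir = file.path(outdir, "sim"))
      aln <- simulate_alignments(s, file.path(outdir, "sim"))
      s$samples <- aln$samples
      s
    })
    genome_path <- sim$paths[["fasta"]]
    gtf_path <- sim$paths[["gtf"]]
    sample_sheet <- sim$samples
    genome <- sim$genome
  } else {
    say("stage inputs: external genome/gtf/alignments")
    genome_path <- config$genome
    gtf_path <- config$gtf
    sample_sheet <- as.data.frame(config$sample_sheet)
    genome <- Biostrings::readDNAStringSet(genome_path)
    names(genome) <- sub("\\s.*", "", names(genome))
  }

  introns <- with_stage("extract_introns", extract_introns(gtf_path))
  say("stage extract_introns: ", nrow(introns), " introns")

  counts <- with_stage("count", {
    cnt <- count_samples(sample_sheet, introns, config$min_anchor)
    merge(introns[c("intron_id", "chrom", "start", "end", "strand", "length")],
          cnt, by = "intron_id")
  })
  counts <- counts[order(counts$intron_id, counts$sample_id), ]
  write_tsv_atomic(counts, file.path(outdir, "junction_counts.tsv"))
  say("stage count: ", nrow(counts), " intron x sample rows")

  filt <- with_stage("filter", filter_low_coverage(
    counts, config$min_total, all_introns = introns$intron_id))
  say("stage filter: ", length(filt$kept), " kept, ",
      length(filt$dropped), " low-coverage")

  irs <- with_stage("irs", compute_irs(
    counts[counts$intron_id %in% filt$kept, ], config$pseudocount))
  write_tsv_atomic(
    irs[c("intron_id", "sample_id", "condition", "replicate",
          "eejr", "eijr", "iejr", "retention_level", "irs")],
    file.path(outdir, "irs_per_sample.tsv"))

  summ <- with_stage("summarize", summarize_conditions(
    irs, var_floor = config$var_floor))
  write_tsv_atomic(summ, file.path(outdir, "irs_summary.tsv"))
  say("stage irs: ", nrow(summ), " introns summarized")

  cats <- with_stage("classify", classify_introns(
    summ, strong_cut = config$strong_cut))
  if (length(filt$dropped)) {
    cats <- rbind(cats, data.frame(
      intron_id = filt$dropped, category = "LOW_COVERAGE",
      z_score = NA_real_, irs_diff = NA_real_, high_confidence_z = NA))
  }
  cats <- cats[order(cats$intron_id), ]
  write_tsv_atomic(cats, file.path(outdir, "intron_categories.tsv"))
  ccounts <- category_counts(cats)
  say("stage classify: ", paste(names(ccounts), as.integer(ccounts),
                                sep = "=", collapse = ", "))

  feat <- with_stage("motifs", pipeline_motifs(genome, introns, summ, cats,
                                               config, outdir))
  say("stage motifs: ", nrow(feat$signatures), " introns with windows")

  len <- with_stage("lengths", {
    keep <- cats$intron_id[cats$category %in%
      c("STRONGLY_AFFECTED", "MILDLY_AFFECTED", "UNAFFECTED")]
    prof <- length_defect_profile(summ[summ$intron_id %in% keep, ],
                                  cats, introns, config$bins)
    write_tsv_atomic(config$bins, file.path(outdir, "length_bins.tsv"))
    write_tsv_atomic(prof$profile, file.path(outdir, "length_profiles.tsv"))
    vals <- split_by_bin(summ, cats, introns, config$bins)
    wm <- compare_bins(vals)
    wm_df <- data.frame(bin = rownames(wm), as.data.frame(wm),
                        check.names = FALSE)
    write_tsv_atomic(wm_df, file.path(outdir, "wilcoxon_matrix.tsv"))
    list(profile = prof, wilcoxon = wm)
  })
  say("stage lengths: ", nrow(len$profile$profile), " bins profiled")

  manifest <- list(
    parameters = list(min_anchor = config$min_anchor,
                      min_total = config$min_total,
                      pseudocount = config$pseudocount,
                      strong_cut = config$strong_cut,
                      var_floor = config$var_floor,
                      window = config$window),
    seed = config$seed,
    inputs = list(genome = unname(tools::md5sum(genome_path)),
                  gtf = unname(tools::md5sum(gtf_path)),
                  alignments = as.list(setNames(
                    unname(tools::md5sum(sample_sheet$path)),
                    sample_sheet$sample_id))),
    rows = list(introns = nrow(introns), counts = nrow(counts),
                kept = length(filt$kept), summaries = nrow(summ),
                categories = nrow(cats)),
    category_counts = as.list(setNames(as.integer(ccounts), names(ccounts)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary_lines <- c(
    "irscore pipeline summary",
    sprintf("introns annotated: %d; passing coverage filter: %d",
            nrow(introns), length(filt$kept)),
    sprintf("IRSdiff cutoff (affected vs unaffected): %.4f",
            attr(with_stage("classify", classify_introns(
              summ, strong_cut = config$strong_cut)), "irs_diff_cutoff")),
    "category counts:",
    sprintf("  %s: %d", names(ccounts), as.integer(ccounts)),
    "signature group counts:",
    sprintf("  %s: %d", names(feat$group_counts),
            as.integer(feat$group_counts)),
    "per-bin median IRSdiff:",
    sprintf("  %s: %s", len$profile$profile$bin,
            formatC(len$profile$profile$irs_diff_median, format = "g"))
  )
  writeLines(summary_lines, file.path(outdir, "summary.txt"))

  invisible(list(introns = introns, counts = counts, filter = filt,
                 summaries = summ, categories = cats, features = feat,
                 lengths = len, manifest = manifest))
}

split_by_bin <- function(summ, cats, introns, bins) {
  keep <- cats$intron_id[cats$category %in%
    c("STRONGLY_AFFECTED", "MILDLY_AFFECTED", "UNAFFECTED")]
  d <- merge(summ[summ$intron_id %in% keep, ],
             introns[c("intron_id", "length")], by = "intron_id")
  bb <- bin_by_length(d$length, bins)
  split(d$irs_diff, bb$bin, drop = FALSE)
}

# splice-site feature stage: windows, signature groups, position matrices,
# differential profile, per-position Fisher tests and per-group ECDFs
pipeline_motifs <- function(genome, introns, summ, cats, config, outdir) {
  w <- config$window
  win <- extract_site_windows(genome, introns, e5 = w$e5, i5 = w$i5,
                              i3 = w$i3, e3 = w$e3)
  win$signature_group <- assign_signature_group(win$last3_exon,
                                                win$first1_exon3)
  win$u5_pairing <- vapply(win$last3_exon, u5_pairing_score, 0L,
                           USE.NAMES = FALSE)
  write_tsv_atomic(win, file.path(outdir, "site_windows.tsv"))
  write_tsv_atomic(win[c("intron_id", "last3_exon", "first1_exon3",
                         "signature_group", "u5_pairing")],
                   file.path(outdir, "signature_groups.tsv"))
  group_counts <- table(factor(win$signature_group,
                               c("AAG_G", "AAG_H", "BBH_H", "NNN_N")))

  sets <- list(all = win$intron_id)
  strong <- cats$intron_id[!is.na(cats$high_confidence_z) &
                             cats$high_confidence_z]
  unaff <- cats$intron_id[cats$category == "UNAFFECTED"]
  if (length(strong)) sets$strong <- strong
  if (length(unaff)) sets$unaffected <- unaff
  pwms <- lapply(sets, function(ids) {
    sub <- win[win$intron_id %in% ids, ]
    list(fp = build_matrix(sub$five_prime_window),
         tp = build_matrix(sub$three_prime_window))
  })
  for (nm in names(pwms)) {
    write_tsv_atomic(pwm_long(pwms[[nm]]),
                     file.path(outdir, sprintf("pwm_%s.tsv", nm)))
  }

  fisher <- NULL
  if (!is.null(pwms$strong) && !is.null(pwms$unaffected)) {
    dl <- rbind(
      cbind(window = "five_prime",
            difflogo_long(diff_matrix(pwms$strong$fp, pwms$unaffected$fp))),
      cbind(window = "three_prime",
            difflogo_long(diff_matrix(pwms$strong$tp, pwms$unaffected$tp))))
    write_tsv_atomic(dl, file.path(outdir, "difflogo.tsv"))
    fisher <- fisher_scan(win, strong, unaff)
    write_tsv_atomic(fisher, file.path(outdir, "fisher_positions.tsv"))
  } else {
    warning("strongly-affected or unaffected set empty; ",
            "differential logo and Fisher scan skipped")
  }

  sg <- merge(win[c("intron_id", "signature_group")], summ, by = "intron_id")
  sg <- sg[is.finite(sg$irs_diff), ]
  ecdf_tab <- rbind(
    cbind(score = "irs_wt",
          group_irs_curves(sg$mean_wt, sg$signature_group)),
    cbind(score = "irs_diff",
          group_irs_curves(sg$irs_diff, sg$signature_group)))
  write_tsv_atomic(ecdf_tab, file.path(outdir, "group_ecdf.tsv"))

  list(windows = win, signatures = win, pwms = pwms, fisher = fisher,
       group_counts = group_counts, ecdf = ecdf_tab)
}

pwm_long <- function(pw) {
  one <- function(m, window) {
    L <- ncol(m$counts)
    data.frame(window = window,
               position = rep(seq_len(L), each = 4L),
               base = rep(rownames(m$counts), L),
               count = as.integer(m$counts),
               probability = as.numeric(m$probabilities),
               information = rep(m$information, each = 4L))
  }
  rbind(one(pw$fp, "five_prime"), one(pw$tp, "three_prime"))
}

difflogo_long <- function(dm) {
  L <- length(dm$jsd)
  data.frame(position = seq_len(L), jsd = dm$jsd,
             dA = dm$diff["A", ], dC = dm$diff["C", ],
             dG = dm$diff["G", ], dT = dm$diff["T", ])
}

fisher_scan <- function(win, strong_ids, unaff_ids) {
  wa <- win[win$intron_id %in% strong_ids, ]
  wb <- win[win$intron_id %in% unaff_ids, ]
  rows <- list()
  for (side in c("five_prime_window", "three_prime_window")) {
    L <- nchar(wa[[side]][1])
    for (pos in seq_len(L)) for (b in c("A", "C", "G", "T")) {
      ft <- position_fisher(wa[[side]], wb[[side]], pos, b)
      rows[[length(rows) + 1L]] <- data.frame(
        window = sub("_window", "", side), position = pos, base = b,
        odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }
  }
  do.call(rbind, rows)
}
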