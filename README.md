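# irscore — intron retention scoring from splice-junction reads

`irscore` quantifies genome-wide splicing efficiency, one annotated intron
at a time, from spliced RNA-seq alignments. It was built for short-intron-
rich fungal transcriptomes — the *Cryptococcus neoformans* genome, whose
introns average ~56 nt, is the motivating case — and for perturbation
designs such as conditional knockdown of the spliceosomal DEAH-box helicase
Prp16, where the question is *which* introns depend on the factor and what
sequence or length features set them apart.

## What it computes

For every intron and sample the package counts three junction-read classes
from SAM/BAM alignments against a GTF annotation:

* **EEJR** — gapped reads whose N gap spans the intron exactly (spliced
  mRNA evidence),
* **EIJR**/**IEJR** — contiguous reads crossing the donor/acceptor boundary
  (retained precursor evidence),

each with a minimum aligned anchor on both sides. Introns with fewer than
10 junction reads in either condition are filtered out. The per-replicate
**intron retention score** is

```
IRS = log2( (EIJR + IEJR + 2α) / (2 (EEJR + α)) ),   α = 1
```

and the knockdown effect per intron is `IRSdiff = mean IRS(KD) − mean
IRS(WT)`, tested with an unpooled two-sample Z statistic over replicates.
Introns are classified into strongly affected (`IRSdiff > 2`), mildly
affected, unaffected (below the minimum IRSdiff of the top Z quartile) and
an excluded negative/negative set. Downstream modules characterize
splice-site sequence features (position matrices, Jensen–Shannon
differential-logo profiles, per-position Fisher tests, AAG-G/AAG-H/BBH-H/
NNN-N exonic signature groups, U5 snRNA loop1 pairing scores) and the
dependence of the defect on intron length (20–40/40–60/60–100/100–500/>500
nt bins plus a 10-nt scan, with pairwise Wilcoxon rank-sum tests).

Because the original sequencing data are not publicly deposited, the
package ships a synthetic-data generator (`simulate_genome()`,
`simulate_alignments()`) that emulates the study design — a short-intron
genome with configurable splice-site consensus and signature composition,
wild-type vs knockdown retention fractions, three replicates per condition
— with known ground truth, against which every stage is validated.

## Worked example

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate.R` … `06_lengths.R`), writing their tables under `results/`.
Running them in order on the default configuration prints, among other
things:

```
$ Rscript analysis/01_simulate.R
simulated 150 genes / 390 introns on seed 1
mean intron length: 55.9 nt (ultra-short <60 nt: 76 %)

$ Rscript analysis/04_classify.R
IRSdiff cutoff (affected vs unaffected): 1.657
STRONGLY_AFFECTED   MILDLY_AFFECTED        UNAFFECTED EXCLUDED_NEGATIVE
              302                49                35                 4
90 % of classified introns are affected by the knockdown

$ Rscript analysis/05_motifs.R
5' exon position -3, base A: OR 7.89, p 1.02e-06
5' exon position -2, base A: OR 7.75, p 1.55e-06
5' exon position -1, base G: OR 8.16, p 8.92e-07
median IRSdiff by signature group:
AAG_G AAG_H BBH_H NNN_N
 0.00  1.22  2.68  2.35
```

Read: the simulated knockdown raises retention genome-wide (90% of introns
affected), introns whose 5' exons end in AAG and whose 3' exons start with
G — the ends that pair fully with U5 loop1 (CUU register) — are the least
affected, and A/A/G are significantly enriched at the exonic −3/−2/−1
positions of unaffected introns. The same structure can be computed in one
call with `run_pipeline(run_config(seed = 1), "outdir")`, which also writes
a run manifest (parameters, input checksums, seed, row counts) and is
byte-identical across reruns with the same seed.

The methods vignette (`vignettes/intron-retention-methods.Rmd`) documents
the score, the classification procedure and its caveats, the simulator's
scope, and all defaults.

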