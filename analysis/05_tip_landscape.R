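#!/usr/bin/env Rscript
# Stage 5 — centromere annotation and the TIP insertion landscape.
#
# Calls centromeres from the simulated repeat-hit track (100-kb windows,
# >6 hits at >70% similarity, pericentromere = 10% of the chromosome),
# simulates a 12-accession TIP panel with planted compartment bias
# (groups 1/3 centromere-biased, group 2 arm-biased), applies the
# >5-supporting-reads filter, classifies each TIP by compartment and
# +/-2000-bp genic context, and summarises sharing and per-group burden.

suppressPackageStartupMessages(library(mobilomekit))

hits <- read.delim("scratch/simdata/line_hits.bed", header = FALSE,
                   col.names = c("chrom", "start", "end", "name",
                                 "similarity"))
genes <- rtracklayer::import("scratch/simdata/genes.gff3")
cfg <- sim_config(seed = 42)
lens <- setNames(rep(cfg$genome_length, cfg$n_chromosomes),
                 paste0("chr", seq_len(cfg$n_chromosomes)))

ann <- call_centromeres(hits, lens)
truth <- read.delim("scratch/simdata/centromere_truth.tsv")
dir.create("results", showWarnings = FALSE)
write.table(as.data.frame(ann), "results/compartments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (ch in unique(truth$chrom)) {
  called <- ann[ann$chrom == ch & ann$compartment == "centromere", ]
  cat(sprintf("%s: called centromere %d-%d (truth %d-%d)\n", ch,
              min(called$start), max(called$end),
              truth$start[truth$chrom == ch],
              truth$end[truth$chrom == ch]))
}

tips <- simulate_tips(cfg, ann, seed = 45)
kept <- filter_tips(tips, min_support = 5)
cat(sprintf("TIPs: %d simulated, %d retained by the >5-read filter\n",
            nrow(tips), nrow(kept)))
kept <- annotate_tips(kept, ann, genes, flank = 2000)
write.table(kept, "results/tips_annotated.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Compartment distribution by group (fractions):\n")
print(round(prop.table(table(kept$group, kept$compartment), 1), 2))
cat("Genic fraction by group:\n")
print(round(tapply(kept$genic == "genic", kept$group, mean), 2))

ss <- sharing_spectrum(kept, n_accessions = cfg$n_accessions)
write.table(ss$spectrum, "results/tip_sharing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Fraction of TIPs in 1-2 accessions: %.3f\n",
            ss$fraction_le2))

gs <- group_summary(kept)
write.table(gs$summary, "results/tip_group_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gs$tests, "results/tip_group_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Per-group TIPs per accession (mean +/- sd):\n")
print(transform(gs$summary,
                label = sprintf("%.1f +/- %.1f", mean, sd)))
print(gs$tests)
cat("Wrote results/compartments.tsv, tips_annotated.tsv,",
    "tip_sharing.tsv, tip_group_summary.tsv, tip_group_tests.tsv\n")
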