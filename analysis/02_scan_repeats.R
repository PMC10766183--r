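#!/usr/bin/env Rscript
# Stage 2: enumerate the interrupted inverted repeats available in the
# contig -- the "potential" baseline against which junction usage is
# compared -- and summarize their density, sizes and spacing.

suppressPackageStartupMessages(library(odira))

genome <- read_sequences("scratch/genome.fa")
cfg <- run_config(seed = 42L)
log_config(cfg, "scan")

iirs <- scan_iirs(genome[[1]], min_arm = cfg$min_arm,
                  max_arm = cfg$max_arm, max_spacer = cfg$max_spacer)
# the full enumeration runs to ~1e6 rows; keep it in scratch/ and put
# only the summaries under results/
write_iir_table(iirs, "scratch/potential_iirs.tsv")
write_iir_table(iirs[iirs$arm_len >= 8, ], "results/potential_iirs_arm8plus.tsv")

dens <- bin_density(iirs, bin = 1000, region = c(0, nchar(genome[[1]])))
write.table(dens, "results/iir_density_1kb.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hists <- size_spacing_histograms(iirs, normalize = TRUE)
write.table(hists$arm, "results/iir_arm_freq.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(hists$spacer, "results/iir_spacer_freq.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(hists$total, "results/iir_total_len_freq.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Found %d IIRs (arms %d-%d bp, spacer <= %d bp): %.1f per kb on average.\n",
            nrow(iirs), cfg$min_arm, cfg$max_arm, cfg$max_spacer,
            mean(dens$count)))
by_arm <- table(iirs$arm_len)
cat("Counts fall steeply with arm length (2 bp arms vs >= 8 bp arms):",
    sum(by_arm[as.integer(names(by_arm)) == 2]), "vs",
    sum(by_arm[as.integer(names(by_arm)) >= 8]), "\n")
cat("Wrote scratch/potential_iirs.tsv and the density/size tables under results/.\n")
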