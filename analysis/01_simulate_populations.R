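#!/usr/bin/env Rscript
# Stage 1: build the synthetic chromosome-end contig and define the
# subclonal populations.
#
# The contig emulates an ~80 kb chromosome-end region carrying a
# selectable locus (placed at 40 kb) with four planted interrupted
# inverted repeats around it. Six populations mix the unrearranged
# chromosome with ODIRA products at set frequencies: inverted linears
# carry only a centromere-proximal fold, triplications and dimeric
# circles carry a CJ/TJ pair. Reads themselves are (re)generated
# deterministically by stage 3 from the seeds recorded here; this stage
# writes the genome, the truth tables and the population design.

suppressPackageStartupMessages(library(odira))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- run_config(seed = 42L, depth = 80)
log_config(cfg, "simulate")

iirs <- data.frame(arm_len = c(7, 4, 5, 9),
                   spacer_len = c(55, 61, 48, 47),
                   position = c(26000, 30000, 34000, 46000))
genome <- build_genome(seed = cfg$seed, length = 80000, iir_specs = iirs)
verify_truth_iirs(genome)
write_sequences(genome$contigs, "scratch/genome.fa")
write_iir_table(genome$truth, "results/planted_iirs.tsv")

wt <- make_wild_type(genome)
il1 <- make_inverted_linear(genome, 1)
il2 <- make_inverted_linear(genome, 2)
trp <- make_triplication(genome, 3, 4)
crc <- make_dimeric_circle(genome, 3, 4)

populations <- list(
  pop01 = list(subclones = list(list(molecule = wt, frequency = 1))),
  pop02 = list(subclones = list(list(molecule = wt, frequency = 0.7),
                                list(molecule = il1, frequency = 0.3))),
  pop03 = list(subclones = list(list(molecule = wt, frequency = 0.6),
                                list(molecule = trp, frequency = 0.4))),
  pop04 = list(subclones = list(list(molecule = wt, frequency = 0.55),
                                list(molecule = il1, frequency = 0.25),
                                list(molecule = trp, frequency = 0.2))),
  pop05 = list(subclones = list(list(molecule = wt, frequency = 0.7),
                                list(molecule = crc, frequency = 0.3))),
  pop06 = list(subclones = list(list(molecule = wt, frequency = 0.8),
                                list(molecule = il1, frequency = 0.1),
                                list(molecule = il2, frequency = 0.1))))

design <- do.call(rbind, lapply(names(populations), function(p) {
  sc <- populations[[p]]$subclones
  data.frame(population = p,
             molecule = vapply(sc, function(s) s$molecule$label,
                               character(1)),
             frequency = vapply(sc, function(s) s$frequency, numeric(1)),
             seed = cfg$seed + match(p, names(populations)))
}))
write.table(design, "results/population_design.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth_all <- do.call(rbind, lapply(names(populations), function(p) {
  ms <- molecule_set(lapply(populations[[p]]$subclones, `[[`, "molecule"),
                     vapply(populations[[p]]$subclones, `[[`, numeric(1),
                            "frequency"))
  tj <- ms$truth_junctions
  if (nrow(tj)) cbind(population = p, tj) else NULL
}))
write.table(truth_all, "results/truth_junctions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Contig: %d bp with %d planted IIRs; %d populations, %d truth junctions in total.\n",
            nchar(genome$contigs[[1]]), nrow(genome$truth),
            length(populations), nrow(truth_all)))
cat("Wrote results/planted_iirs.tsv, results/population_design.tsv, results/truth_junctions.tsv\n")
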