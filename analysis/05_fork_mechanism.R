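#!/usr/bin/env Rscript
# Stage 5: the replication-fork constraints. (a) Which repeat spacings
# can template-switch, given that the spacer must exceed the self-hairpin
# threshold yet fit inside the transient lagging-strand gap (bounded by
# the 165 bp Okazaki fragment). (b) Which positions have the fork
# direction required for a productive junction, under a nearest-active-
# origin replication model of the chromosome-end region.

suppressPackageStartupMessages(library(odira))
dir.create("results", showWarnings = FALSE)

params <- fork_params()    # Okazaki 165 bp, uniform gap, threshold 40 bp
s <- 0:250
dens <- productive_spacer_density(s, params)
write.table(data.frame(spacer = s, productivity = dens),
            "results/productive_spacer_density.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Productive spacer support: %d-%d bp, mode at %d bp.\n",
            min(s[dens > 0]), max(s[dens > 0]), s[which.max(dens)]))

# origin map of a chromosome-end region (positions in kb): two strong
# origins flanking the selected locus, plus a minor origin
origins_major <- data.frame(position = c(743, 796),
                            active = c(TRUE, TRUE))
origins_minor <- rbind(origins_major,
                       data.frame(position = 752, active = TRUE))
write_origin_table(origins_minor, "results/origins.tsv")

pos <- seq(740, 800, by = 0.5)
dir_major <- fork_direction(pos, origins_major)
dir_minor <- fork_direction(pos, origins_minor)
write.table(data.frame(position = pos, major_only = dir_major,
                       with_minor = dir_minor),
            "results/fork_direction.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cj_blocked <- pos[dir_major == "RIGHTWARD" & pos < 796]
cat(sprintf("With the two strong origins only, CJs cannot form in %.1f-%.1f kb (rightward fork).\n",
            min(cj_blocked), max(cj_blocked)))
rescued <- pos[dir_major == "RIGHTWARD" & dir_minor == "LEFTWARD"]
cat(sprintf("Adding the minor origin at 752 kb rescues CJs in %.1f-%.1f kb.\n",
            min(rescued), max(rescued)))

# annotate the called junctions (positions are on the synthetic contig):
# one strong origin far to the left and one adjacent to the selected
# locus, so the inter-junction region is replicated by diverging forks
jx <- read_junction_table("results/called_junctions.tsv")
origins_contig <- data.frame(position = c(10000, 42000),
                             active = c(TRUE, TRUE))
prod <- jx$orientation %in% c("CJ", "TJ")
jx$fork_compatible <- NA
jx$fork_compatible[prod] <- junction_fork_compatibility(
  jx$orientation[prod], jx$pos[prod], origins_contig)
write_junction_table(jx, "results/called_junctions_fork.tsv")
cat(sprintf("%d/%d productive junctions are fork-compatible under the two-origin contig map.\n",
            sum(jx$fork_compatible, na.rm = TRUE), sum(prod)))
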