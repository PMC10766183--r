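# odira

Foldback-junction discovery and mechanistic models of
**O**rigin-**D**ependent **I**nverted **R**epeat **A**mplification
(ODIRA) in R.

## The problem

Interstitial inverted triplications — a triplicated segment whose
center copy is inverted, embedded between duplicated flanks
(DUP-TRP/INV-DUP in the human CNV literature) — arise repeatedly at
selectable loci in budding yeast, e.g. the sulfate-transporter locus
under sulfate limitation. The ODIRA mechanism explains them by template
switching between the nascent leading strand and the lagging-strand
template at a replication fork, at short **interrupted inverted
repeats** (IIRs): two reverse-complementary arms of 2–14 bp separated
by a spacer of up to ~250 bp. One switch at the centromere-proximal
fork yields a hairpin-capped, then fully duplex, **inverted linear**
carrying a single centromere-proximal junction (CJ); a second switch
adds the telomere-proximal junction (TJ); recombination produces the
triplication. The package is for people analyzing (or simulating)
short-read population sequencing and aCGH data for this class of
rearrangement.

An IIR with arms `A1 = S[l1..l2)`, `A2 = S[r1..r2) = revcomp(A1)` and
spacer `s = r1 - l2` leaves a diagnostic **foldback read**: a 150 bp
read mapping to the same contig on opposite strands, whose breakpoint
homology equals the arm length `a` and whose segments are separated by
`s` on the reference. Junction support is counted in unique sequenced
fragments, and junctions with fewer than two unique fragments are
discarded as PCR artifacts. Two mechanistic constraints are modeled:
the productive spacer density `f(s) = 1[s >= t_h] · max(0, 1 - s/165)`
(lagging-strand gap bounded by the 165 bp Okazaki fragment, hairpin
threshold `t_h = 40` bp), and fork-direction compatibility (a CJ needs
a centromere-bound fork). A forward model of array-CGH labeling
reproduces the "waterfall" ramp
`c(d) = c_far - k · max(0, 1 - 2d/L)` that palindromic junctions
produce when DNA is sheared after labeling.

## What is in the package

| Module | Functions |
| --- | --- |
| synthetic data | `build_genome`, `make_inverted_linear`, `make_triplication`, `make_dimeric_circle`, `simulate_reads`, `simulate_population` |
| IIR scanner | `scan_iirs`, `bin_density`, `size_spacing_histograms` |
| junction caller | `map_reads`, `find_split_reads`, `classify_split_read`, `characterize_inverted_junction`, `dedupe_and_threshold`, `orient_relative_to_locus`, `call_junctions`, `binned_depth` |
| aCGH model | `labeling_model`, `expected_profile`, `simulate_labeling`, `detect_waterfall` |
| fork model | `fork_params`, `classify_switch`, `productive_spacer_density`, `fork_direction`, `junction_fork_compatibility` |
| statistics | `usage_ratio`, `mann_whitney`, `chi_squared`, `cj_tj_balance` |
| I/O | FASTA/FASTQ (Biostrings), BED (rtracklayer), junction/IIR/origin TSV tables, `run_config` |

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate_populations.R` … `06_population_stats.R`); each is a thin
narrative script over the package functions that writes its tables
under `results/`.

## Worked example

Plant the worked-example repeat — TGGC arms separated by a 61 nt
interruption — in a 20 kb contig, build the inverted linear, sequence
it at 60x with 0.1% errors, and call junctions:

```r
library(odira)
genome <- build_genome(seed = 42, length = 20000,
                       iir_specs = data.frame(arm_len = 4, spacer_len = 61,
                                              position = 10000,
                                              arm_seq = "TGGC"))
il <- make_inverted_linear(genome, 1)
reads <- simulate_reads(molecule_set(list(il), 1), depth = 60,
                        error_rate = 0.001, seed = 43)
call_junctions(reads, genome, focal_locus = 15000)
#>   contig     pos arm_len spacer_len loop_side orientation n_reads
#> 1   chrS 10034.5       4         61      LEFT          CJ      45
#>   n_unique_fragments secondary_deletion
#> 1                 39              FALSE
```

One junction is called: at the spacer midpoint (position 10034.5 =
(10004 + 10065)/2, 0-based), with the planted arm (4 bp) and spacer
(61 nt) recovered exactly, the hairpin loop on the LEFT, hence a
productive centromere-proximal junction (CJ) for a locus at 15 kb —
supported by 45 reads from 39 distinct fragments, comfortably past the
two-fragment artifact threshold. The same contig carries 234,558
spontaneous IIRs (arms 2–14 bp, spacer ≤ 250 bp) — the "potential"
baseline that `scan_iirs()` enumerates and against which junction usage
is compared. And the aCGH model's expected signal across a 1→3
junction with 20 kb fragments:

```r
expected_profile(labeling_model(), c(0, 5000, 10000))
#> [1] 1 2 3
```

the copy-number ramp rises linearly from 1 at the junction to 3 at
10 kb — the "waterfall".

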