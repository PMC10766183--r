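---
title: "Models and methods behind the odira pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the odira pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odira)
```

# The problem

Interstitial inverted triplications — a tandem triplication whose center
copy is inverted, flanked by single-copy sequence (the human-genetics
DUP-TRP/INV-DUP configuration) — recur at selectable loci in budding
yeast, most famously at the sulfate-transporter locus during growth in
sulfate-limited chemostats. The ODIRA model (origin-dependent inverted
repeat amplification) explains them by a template switch at a
replication fork: the nascent leading strand anneals to the
lagging-strand template at a short **interrupted inverted repeat**
(IIR) — two reverse-complementary arms of a few base pairs separated by
a short spacer. A switch at the centromere-proximal fork expels a
hairpin-capped linear that replicates into an **inverted linear**
molecule carrying a single foldback (the centromere-proximal junction,
CJ); a second switch, possibly in a later cell cycle, creates the
telomere-proximal junction (TJ), and recombination back into the
chromosome yields the triplication. Simultaneous switches at diverging
forks instead expel an **inverted dimeric circle** carrying both
junctions.

The package implements the computations this model makes testable on
short-read population sequencing data: foldback-junction discovery from
split reads, enumeration of the genomic IIR substrate, the array-CGH
signature of palindromic junctions, and the replication-fork constraints
on which IIRs can be used — all exercised on synthetic data whose truth
is known by construction.

# Coordinates and notation

All coordinates are 0-based, half-open. An IIR on contig sequence `S`
has left arm `A1 = S[l1..l2)`, spacer `P = S[l2..r1)`, right arm
`A2 = S[r1..r2)` with `A2 = revcomp(A1)`; arm length `a = l2 - l1`,
spacer `s = r1 - l2`. A junction's reported position is the midpoint of
the spacer interval, `(l2 + r1)/2`, which may end in `.5`.

# Synthetic data: what it emulates and what it does not

`build_genome()` draws an i.i.d. uniform A/C/G/T contig (default 80 kb,
a chromosome-end scale) and plants IIRs at requested positions;
`telomeric_ends` adds tandem `C(1-3)A` / `G(1-3)T` arrays at the ends.
Two deliberate choices:

* **Planted arms are made maximal.** The bases immediately outside each
  arm pair and the first/last spacer bases are resampled so they cannot
  extend the arm match. Without this, a random flanking base would
  occasionally lengthen the planted arm, and exact-recovery tests would
  measure the generator's sloppiness rather than the caller's accuracy.
  The planted `(a, s)` is therefore the unique maximal geometry at that
  site.
* **Background IIRs are tolerated.** A uniform 80 kb sequence contains
  on the order of 10^6 spontaneous IIRs with 2 bp arms within 250 bp
  spacers; tests assert that planted junctions are recovered, not that
  no other repeats exist (none of them produce foldback *reads*, so the
  caller is unaffected).

Product molecules follow the mechanism's anatomy exactly. With
`E` the contig end and flanking notation as above:

* inverted linear: `IL = revcomp(S[r2..E)) . S[l1..E)` — the
  telomere-side flank twice in inverted orientation, arms and spacer
  once each at the fold;
* triplication:
  `T = S[0..t_l1) . Jt . revcomp(S[c_r2..t_l1)) . Jc . S[c_r2..E)`,
  where `Jc`/`Jt` are the full arm-spacer-arm IIR sequences — the
  captured segment three times, center copy inverted;
* dimeric circle: `C = Jc . S[c_r2..t_l1) . Jt . revcomp(S[c_r2..t_l1))`,
  circular.

The doubly inverted linear (the transient two-fold intermediate) is not
modeled: its end structure (telomere status at both ends) is not
constrained by the data the pipeline analyzes, and its junction content
is identical to an IL plus a TJ-side fold.

Read simulation is single-end by default: the junction evidence lives
entirely within one 150 bp read, so the second mate adds nothing to
junction characterization and only the fragment signature (outer 5'
mapping coordinate and strand) would change in paired mode. Coverage is
`depth x abundance` per molecule with uniform starts (circular
molecules sampled with wraparound by sequence doubling), uniform
strand, and i.i.d. substitution errors at `error_rate` (default 0.001).
Not modeled: indels, quality-score structure, GC or replication-timing
coverage bias, chimeric library artifacts other than the singleton
foldbacks described next.

PCR-artifact junctions are injected by `simulate_population()` as blunt
chimeric foldback reads at distinct random positions — each artifact
junction is supported by exactly one fragment, which is precisely the
class of event the two-fragment threshold is designed to remove.

# The IIR scanner

An IIR is a maximal run of complementary base pairs `(p, q)` along an
anti-diagonal `p + q = const` of the sequence-against-itself comparison;
the innermost pair fixes the spacer, the run length is the arm.
`scan_iirs()` (C++ core) walks each anti-diagonal from the innermost
admissible pair outward, which visits every maximal run exactly once in
`O(n x max_spacer)` time. Maximality means the arm can be extended
neither outward nor inward; sub-arms of a longer perfect arm are not
reported separately, which avoids quadratic double counting. No
mismatches are allowed within arms (junction repeats are exact-sequence
features), N never matches, perfect palindromes (`s = 0`) are included,
and arms longer than `max_arm` are measured at their true length before
the bound filters them — the 2–14 bp range is an observed property of
used repeats, not a mechanism limit, so the filter is exposed. The test
suite holds the scanner to an independent brute-force oracle
(per-innermost-pair extension with explicit maximality checks) on random
sequences up to 3 kb.

# The split-read junction caller

Mapping is exact-match anchor-and-extend: the maximal exact prefix and
suffix matches of each read are found on either strand via a k-mer index
(`k = 20`). This is sufficient for 150 bp reads against sub-megabase
references because the junctions of interest are exact-sequence
features; no scoring matrix or gapped alignment is involved, and reads
whose two matches are consistent with a single placement (substitution
errors only) are not split. Ties in maximal extension break toward the
lower coordinate so identical junctions canonicalize identically.

For a foldback read (segments on opposite strands of one contig), the
breakpoint homology `h` between prefix and suffix matches *is* the
inverted-repeat arm — the reference carries reverse-complement copies of
those `h` bases at the two segment ends. Which segment carries which arm
copy depends on the read's sequencing orientation, so the junction tuple
is canonicalized from the ordered fold-side endpoints of the two
segments; both orientations of the same fold then yield the same
`(position, arm, spacer, loop side)`. The loop side is LEFT when the
read folds back toward higher coordinates (prefix segment on the minus
strand). Degenerate inputs behave predictably: a blunt foldback gives
`arm = 0, spacer = 0`, and chance homology at an artifact fold can give
a small negative spacer (overlapping arms), which is reported as
computed — such junctions never survive the support threshold.

Support is counted in **unique fragments**, approximated by the read's
outer 5' mapping coordinate and strand: duplicate reads of one fragment
count once, and junctions under `min_support = 2` unique fragments are
removed as presumptive PCR artifacts. Orientation relative to a focal
locus follows the productive-geometry rule: left of the locus with loop
LEFT is a CJ, right of the locus with loop RIGHT is a TJ, anything else
is NONPRODUCTIVE. Junctions with spacers over 1 kb are flagged
`secondary_deletion` (an arm was likely lost after the event) and are
excluded from spacing statistics.

Classification precedence when a read is not a clean same-contig split:
telomere-motif rules (de novo telomere, telomere translocation) are
tested before the repeat-annotation rule (internal translocation),
because the repetitive-element class is the least specific; INVERTED and
DIRECT require both segments uniquely mapped.

# The aCGH waterfall model

Labeling genomic DNA by random priming *before* shearing lets any
fragment that spans a palindromic junction snap back into an
intramolecular duplex on denaturation: the region within
`min(distance to either fragment end)` of the junction re-anneals with
its own reverse complement and cannot be primed. With fixed fragment
length `L` and uniform junction phase, the exclusion probability at
distance `d` is `max(0, 1 - 2d/L)`, so the expected signal is

```
c(d) = c_far - k * max(0, 1 - 2d/L)
```

with `k` the number of junction-adjacent palindromic copies (default 2
for a 1-to-3 triplication junction: two of the three copies meet at the
palindrome; the parameter is exposed because neochromosome geometries
differ). The ramp starts at `c_far - k = c_near` and completes exactly
at `d = L/2` — 10 kb for 20 kb fragments. Shearing *before* labeling
replaces `L` with the shear size (default 500 bp), confining the
exclusion to 250 bp and collapsing the waterfall to a step: the
diagnostic contrast between the two protocols. Fixed fragment length is
the default because it is what the ramp geometry reflects; the
Monte-Carlo simulator samples the fragment phase per probe and is held
to the closed form within three standard errors in the tests. Signal is
on the linear copy-number scale (a `log2` convenience transform is
provided).

`detect_waterfall()` fits the piecewise-linear family
`c_near + (c_far - c_near) * clamp((x - x0)/W, 0, 1)` by grid search
over junction position and ramp width (closed-form least squares for the
two copy numbers at each grid point) polished with Nelder-Mead. A
profile whose fitted step is below 0.5 copies returns a "no junction"
result rather than an error.

# The fork model

Two hard, exposed thresholds stand in for quantities the mechanism does
not pin down exactly:

* `hairpin_threshold` (40 bp): below this spacer the displaced repeats
  self-hybridize on the leading strand instead of annealing across the
  fork. There is no mechanistic formula for hairpin propensity, so a
  hard threshold at the observed lower edge of productive spacings is
  used.
* `okazaki_len` (165 bp): the lagging-strand gap is taken uniform on
  `[0, okazaki_len]` — the mechanism constrains only the range, and the
  uniform choice makes the productivity density a transparent integral
  of the classifier: `1[s >= t_h] * max(0, 1 - s/165)`, supported on
  [40, 165] bp with its mode at 40 bp.

Fork direction uses a deterministic nearest-active-origin rule (equal
speeds, simultaneous firing; firing-time and efficiency differences are
out of scope). Conventions at measure-zero points are fixed and tested:
a position exactly at an origin is RIGHTWARD, an exact inter-origin
midpoint is LEFTWARD. A CJ is compatible only with a LEFTWARD
(centromere-bound) fork and a TJ only with a RIGHTWARD one, which makes
an inter-origin region replicated rightward a dead zone for CJs until a
minor origin on its right is added — the signature the analysis scripts
reproduce.

# Statistics

`usage_ratio()` compares used junction repeats against the scanner's
potential baseline, stratified by arm length or 20 bp spacer bins
(matching the granularity at which spacing preferences are visible);
strata with zero potential are reported missing rather than dividing by
zero. `mann_whitney()` implements the rank-sum test with midranks, exact
enumeration for pooled sizes up to 12 (exact p-values with ties are
needed there, which the standard large-sample machinery does not give)
and a tie-corrected normal approximation with continuity correction
otherwise; `chi_squared()` delegates to `stats::chisq.test` without
continuity correction. No multiple-testing adjustment is applied — the
pipeline reports single planned tests. `cj_tj_balance()` classifies each
population as MATCHED (equal positive CJ and TJ counts), UNBALANCED, or
NO_INVERTED; unbalanced counts are the population-level signature of
free inverted-linear intermediates.

# Problem sizes and numerical choices

The shipped tests and drivers use an 80 kb contig, ~125-fold coverage of
150 bp reads, 0.001 substitution errors, 1% artifact reads, ten
populations with three planted junctions each, and 10^5 Monte-Carlo
fragments per probe for the labeling model — sizes chosen so a desk
machine reproduces every number in minutes while keeping all the
qualitative regimes (multiple subclones, sub-threshold artifacts,
errors) present. Determinism contracts: every stochastic function takes
a seed; the same seed and configuration give byte-identical outputs.

# Known limitations

* Exact-match anchoring cannot place a junction whose read has a
  sequencing error inside a 20 bp anchor or at the fold; at 125x this
  costs support, not junctions, but at very low coverage the support
  threshold will bite first.
* The scanner reports exact-arm repeats only; mismatch-tolerant
  palindromes are out of scope.
* The fork model is descriptive: whether the 40–80 bp spacing enrichment
  reflects gap geometry alone or additional selection is left open, and
  the density is not fitted to data.
* aCGH modeling omits dye bias, GC effects and segmentation; it is a
  forward model for junction geometry, not an array-processing pipeline.
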