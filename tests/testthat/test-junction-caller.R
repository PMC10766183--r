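test_that("contiguous reads are not reported as split, with or without
errors", {
  set.seed(601)
  S <- random_dna(4000)
  ref <- c(chrS = S)
  exact <- substr(S, 1001, 1150)
  m <- map_reads(exact, ref)
  expect_identical(m$status, "full")
  expect_equal(nrow(find_split_reads(exact, ref)), 0L)

  withsub <- exact
  substr(withsub, 70, 70) <- if (substr(withsub, 70, 70) == "A") "C" else "A"
  m2 <- map_reads(withsub, ref)
  expect_identical(m2$status, "contiguous")

  expect_error(map_reads(exact, ref, k = 200), "k exceeds")
})

test_that("a read across an inverted-linear fold is a split read with
segments on opposite strands", {
  st <- toy_il_setup(seed = 602, len = 6000, arm = 4, spacer = 61,
                     pos = 3000, depth = 0.1)
  # construct one fold-crossing read directly: fold at E - r2 in the IL
  tr <- st$genome$truth
  fold <- 6000 - tr$r2
  read <- substr(st$il$seq, fold - 74, fold + 75)
  sr <- find_split_reads(read, st$genome)
  expect_equal(nrow(sr), 1L)
  expect_identical(sr$status, "split")
  expect_true(sr$p_strand != sr$s_strand)
  expect_identical(classify_split_read(sr)$category, "INVERTED")
})

test_that("a read across a direct-repeat seam has both segments on the
same strand", {
  set.seed(603)
  S <- random_dna(5000)
  ref <- c(chrS = S)
  mol <- paste0(substr(S, 1, 2000), substr(S, 2501, 5000))  # S[0..x) S[y..E)
  read <- substr(mol, 1931, 2080)                            # spans the seam
  sr <- find_split_reads(read, ref)
  expect_equal(nrow(sr), 1L)
  expect_true(sr$p_strand == sr$s_strand)
  expect_identical(classify_split_read(sr)$category, "DIRECT")
})

test_that("unmapped telomeric tails and cross-contig segments classify by
the stated precedence", {
  set.seed(604)
  S1 <- random_dna(3000)
  S2 <- random_dna(3000)
  ref <- c(chrA = S1, chrB = S2)

  # de novo telomere: mapped prefix + pure C(1-3)A tail
  tail <- substr(telomere_repeat(80, "left"), 1, 70)
  read_tel <- paste0(substr(S1, 501, 580), tail)
  sr <- find_split_reads(read_tel, ref)
  expect_equal(nrow(sr), 1L)
  expect_identical(sr$status, "partial")
  expect_identical(classify_split_read(sr)$category, "DE_NOVO_TELOMERE")

  # same anatomy with a random (non-telomeric) tail stays unclassified
  read_junk <- paste0(substr(S1, 501, 580), strrep("ACGGT", 14))
  sr0 <- find_split_reads(read_junk, ref)
  expect_identical(classify_split_read(sr0)$category, "UNCLASSIFIED")

  # cross-contig junction: telomere annotation outranks repeat annotation
  read_x <- paste0(substr(S1, 501, 575), substr(S2, 2001, 2075))
  srx <- find_split_reads(read_x, ref)
  expect_equal(nrow(srx), 1L)
  tel <- data.frame(contig = "chrB", start = 1900L, end = 2200L)
  rep_ann <- data.frame(contig = "chrB", start = 1900L, end = 2200L)
  expect_identical(classify_split_read(srx, telomeres = tel,
                                       repeats = rep_ann)$category,
                   "TELOMERE_TRANSLOCATION")
  expect_identical(classify_split_read(srx, repeats = rep_ann)$category,
                   "INTERNAL_TRANSLOCATION")
  expect_identical(classify_split_read(srx)$category, "UNCLASSIFIED")
})

test_that("every split read receives exactly one category", {
  set.seed(605)
  st <- toy_il_setup(seed = 606, len = 8000, arm = 5, spacer = 50,
                     pos = 4000, depth = 10)
  sr <- find_split_reads(st$reads, st$genome)
  sr <- classify_split_read(sr)
  tokens <- c("INVERTED", "DIRECT", "DE_NOVO_TELOMERE",
              "TELOMERE_TRANSLOCATION", "INTERNAL_TRANSLOCATION",
              "UNCLASSIFIED")
  expect_true(all(sr$category %in% tokens))
  expect_equal(length(sr$category), nrow(sr))
})

test_that("characterization recovers the planted arm and spacer exactly", {
  st <- toy_il_setup(seed = 607, len = 20000, arm = 4, spacer = 61,
                     pos = 10000, arm_seq = "TGGC", depth = 40)
  jx <- call_junctions(st$reads, st$genome)
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$arm_len, 4L)
  expect_equal(jx$spacer_len, 61)
  expect_identical(jx$loop_side, "LEFT")
  expect_equal(jx$pos, (st$genome$truth$l2 + st$genome$truth$r1) / 2)
})

test_that("a blunt foldback characterizes as arm 0, spacer 0", {
  set.seed(608)
  S <- random_dna(4000)
  # choose a fold point with no chance homology on either side
  q <- 2000
  while (substr(S, q, q) == revcomp(substr(S, q + 1, q + 1))) q <- q + 1
  read <- paste0(revcomp(substring(S, q + 1, q + 70)),
                 substring(S, q + 1, q + 80))
  sr <- find_split_reads(read, c(chrS = S))
  jr <- characterize_inverted_junction(sr)
  expect_equal(jr$arm_len, 0L)
  expect_equal(jr$spacer_len, 0)
  expect_equal(jr$pos, q)
})

test_that("arm and spacer are exact across many planted geometries", {
  for (seed in 1:10) {
    a <- sample(2:14, 1)
    s <- sample(40:80, 1)
    st <- toy_il_setup(seed = 700 + seed, len = 8000, arm = a, spacer = s,
                       pos = 4000, depth = 40)
    jx <- call_junctions(st$reads, st$genome)
    expect_equal(nrow(jx), 1L)
    expect_equal(jx$arm_len, a)
    expect_equal(jx$spacer_len, s)
    expect_identical(jx$loop_side, "LEFT")
  }
})

test_that("characterization rejects non-foldback input", {
  set.seed(609)
  S1 <- random_dna(2000); S2 <- random_dna(2000)
  ref <- c(chrA = S1, chrB = S2)
  read_x <- paste0(substr(S1, 501, 575), revcomp(substr(S2, 1001, 1075)))
  srx <- find_split_reads(read_x, ref)
  expect_error(characterize_inverted_junction(srx), "different contigs")
})

test_that("deduplication counts unique fragments and enforces the
two-fragment threshold", {
  jr <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    contig = "chrS",
    pos = c(100, 200, 200, 300, 300),
    arm_len = 4L, spacer_len = 50,
    loop_side = "LEFT",
    fragment_sig = c("1:10", "1:20", "1:20", "1:30", "-1:95"),
    stringsAsFactors = FALSE)
  out <- dedupe_and_threshold(jr, min_support = 2)
  # pos 100: one read -> removed; pos 200: two reads, same signature ->
  # one fragment -> removed; pos 300: two distinct fragments -> kept
  expect_equal(out$pos, 300)
  expect_equal(out$n_reads, 2L)
  expect_equal(out$n_unique_fragments, 2L)
})

test_that("orientation relative to the focal locus follows the loop-side
rule", {
  jx <- data.frame(contig = "chrS",
                   pos = c(770, 820, 770, 820),
                   loop_side = c("LEFT", "RIGHT", "RIGHT", "LEFT"),
                   stringsAsFactors = FALSE)
  out <- orient_relative_to_locus(jx, locus = 800)
  expect_identical(out$orientation,
                   c("CJ", "TJ", "NONPRODUCTIVE", "NONPRODUCTIVE"))
  out2 <- orient_relative_to_locus(cbind(jx, row = 1:4), locus = 800,
                                   contig = "chrZ")
  expect_true(all(is.na(out2$orientation)))
})

test_that("an unrearranged genome yields no junctions passing the
threshold", {
  g <- build_genome(seed = 610, length = 20000,
                    iir_specs = data.frame(arm_len = 6, spacer_len = 60,
                                           position = 10000))
  ms <- molecule_set(list(make_wild_type(g)), 1)
  reads <- simulate_reads(ms, depth = 40, error_rate = 0, seed = 611)
  jx <- call_junctions(reads, g)
  expect_equal(nrow(jx), 0L)
})

test_that("binned depth is ~1 on a single-copy contig and ~1+2f over a
triplication at frequency f", {
  g <- build_genome(seed = 612, length = 30000,
                    iir_specs = data.frame(arm_len = c(5, 6),
                                           spacer_len = c(50, 60),
                                           position = c(10000, 20000)))
  ms <- molecule_set(list(make_wild_type(g)), 1)
  reads <- simulate_reads(ms, depth = 100, error_rate = 0, seed = 613)
  m <- map_reads(reads, g)
  d <- binned_depth(m, g, bin = 500)
  interior <- d$copy_number[d$bin_start >= 2000 & d$bin_start < 28000]
  expect_true(all(abs(interior - 1) < 0.25))
  expect_lt(abs(mean(interior) - 1), 0.05)

  f <- 0.3
  tr <- make_triplication(g, 1, 2)
  pop <- simulate_population(
    g, list(list(molecule = make_wild_type(g), frequency = 1 - f),
            list(molecule = tr, frequency = f)),
    depth = 100, error_rate = 0, seed = 614)
  d2 <- binned_depth(map_reads(pop$reads, g), g, bin = 500)
  amp <- d2$copy_number[d2$bin_start >= 12000 & d2$bin_start < 19000]
  expect_lt(abs(mean(amp) - (1 + 2 * f)), 0.15)

  expect_error(binned_depth(m[0, ], g), "no mapped reads")
})
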