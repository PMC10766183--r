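test_that("build_genome plants IIRs that verify their reverse-complement
identity and is deterministic", {
  g <- build_genome(seed = 42, length = 20000,
                    iir_specs = data.frame(arm_len = 4, spacer_len = 61,
                                           position = 5000,
                                           arm_seq = "TGGC"))
  expect_equal(g$truth$arm_len, 4L)
  expect_equal(g$truth$spacer_len, 61L)
  expect_equal(g$truth$l1, 5000L)
  expect_true(verify_truth_iirs(g))
  s <- g$contigs[[1]]
  expect_identical(substr(s, 5001, 5004), "TGGC")
  expect_identical(substr(s, 5066, 5069), "GCCA")

  g2 <- build_genome(seed = 42, length = 20000,
                     iir_specs = data.frame(arm_len = 4, spacer_len = 61,
                                            position = 5000,
                                            arm_seq = "TGGC"))
  expect_identical(g$contigs, g2$contigs)

  g0 <- build_genome(seed = 1, length = 1000)
  expect_equal(nrow(g0$truth), 0L)
  expect_equal(nchar(g0$contigs[[1]]), 1000L)
})

test_that("build_genome rejects invalid specs", {
  expect_error(build_genome(seed = 1, length = 1000,
                            iir_specs = data.frame(arm_len = 1,
                                                   spacer_len = 10,
                                                   position = 100)),
               "at least 2 bp")
  expect_error(build_genome(seed = 1, length = 1000,
                            iir_specs = data.frame(arm_len = c(4, 4),
                                                   spacer_len = c(50, 50),
                                                   position = c(100, 120))),
               "overlap")
  expect_error(build_genome(seed = 1, length = 500,
                            iir_specs = data.frame(arm_len = 4,
                                                   spacer_len = 50,
                                                   position = 480)),
               "outside")
})

test_that("telomeric ends are tandem repeats and shift truth coordinates", {
  g <- build_genome(seed = 9, length = 5000, telomeric_ends = TRUE,
                    iir_specs = data.frame(arm_len = 6, spacer_len = 40,
                                           position = 2000))
  s <- g$contigs[[1]]
  expect_gt(nchar(s), 5200)
  expect_true(is_telomere_seq(substr(s, 1, 100)))
  expect_true(is_telomere_seq(substr(s, nchar(s) - 99, nchar(s))))
  expect_true(verify_truth_iirs(g))   # coordinates still valid after shift
  expect_gt(g$truth$l1, 2000)
})

test_that("inverted linear has the required length, fold anatomy and
palindrome symmetry", {
  # toy contig, a = 2, s = 3
  g <- build_genome(seed = 3, length = 60,
                    iir_specs = data.frame(arm_len = 2, spacer_len = 3,
                                           position = 20))
  tr <- g$truth
  il <- make_inverted_linear(g, 1)
  E <- 60
  expect_equal(nchar(il$seq), 2 * (E - tr$r2) + (tr$r2 - tr$l1))
  # direct string construction oracle
  S <- g$contigs[[1]]
  expect_identical(il$seq, paste0(revcomp(substr(S, tr$r2 + 1, E)),
                                  substr(S, tr$l1 + 1, E)))
  # revcomp(IL) differs from IL only inside the central spacer window
  rc <- revcomp(il$seq)
  flank <- E - tr$r2
  n <- nchar(il$seq)
  expect_identical(substr(rc, 1, flank + 2), substr(il$seq, 1, flank + 2))
  expect_identical(substr(rc, flank + 2 + 3 + 1, n),
                   substr(il$seq, flank + 2 + 3 + 1, n))
})

test_that("an inverted linear over an s = 0 IIR is a perfect palindrome", {
  g <- build_genome(seed = 4, length = 80,
                    iir_specs = data.frame(arm_len = 2, spacer_len = 0,
                                           position = 30))
  il <- make_inverted_linear(g, 1)
  expect_identical(revcomp(il$seq), il$seq)
})

test_that("make_inverted_linear rejects an IIR outside the contig", {
  g <- build_genome(seed = 5, length = 100,
                    iir_specs = data.frame(arm_len = 3, spacer_len = 5,
                                           position = 40))
  bad <- g$truth
  bad$r2 <- 100
  expect_error(make_inverted_linear(g, bad), "left of the contig end")
})

test_that("triplication satisfies its substring-count invariants", {
  # toy 100 bp contig, CJ (a=2, s=2) at 20, TJ (a=2, s=2) at 60
  g <- build_genome(seed = 12, length = 100,
                    iir_specs = data.frame(arm_len = c(2, 2),
                                           spacer_len = c(2, 2),
                                           position = c(20, 60)))
  cj <- g$truth[1, ]; tj <- g$truth[2, ]
  tr <- make_triplication(g, 1, 2)
  S <- g$contigs[[1]]
  seg30 <- substr(S, cj$r2 + 1, cj$r2 + 30)   # 30-mer at c_r2
  expect_equal(count_occurrences(tr$seq, seg30), 3L)
  # direct string-construction oracle
  Jc <- substr(S, cj$l1 + 1, cj$r2)
  Jt <- substr(S, tj$l1 + 1, tj$r2)
  mid <- substr(S, cj$r2 + 1, tj$l1)
  want <- paste0(substr(S, 1, tj$l1), Jt, revcomp(mid), Jc,
                 substr(S, cj$r2 + 1, 100))
  expect_identical(tr$seq, want)
  flank <- substr(S, cj$r2 + 1, 100)
  expect_equal(count_occurrences(tr$seq, flank), 1L)
  # one extra copy each of the two IIRs, two extra copies of the middle
  # segment
  expect_equal(nchar(tr$seq),
               100 + 2 * (tj$l1 - cj$r2) + nchar(Jc) + nchar(Jt))
})

test_that("each full IIR occurs twice in a triplication (long-arm toy)", {
  g <- build_genome(seed = 15, length = 400,
                    iir_specs = data.frame(arm_len = c(6, 7),
                                           spacer_len = c(8, 10),
                                           position = c(80, 250)))
  cj <- g$truth[1, ]; tj <- g$truth[2, ]
  tr <- make_triplication(g, 1, 2)
  S <- g$contigs[[1]]
  Jc <- substr(S, cj$l1 + 1, cj$r2)
  Jt <- substr(S, tj$l1 + 1, tj$r2)
  expect_equal(count_occurrences(tr$seq, Jc), 2L)
  expect_equal(count_occurrences(tr$seq, Jt), 2L)
})

test_that("degenerate or misordered IIR pairs are rejected", {
  g <- build_genome(seed = 13, length = 200,
                    iir_specs = data.frame(arm_len = c(3, 3),
                                           spacer_len = c(4, 4),
                                           position = c(50, 120)))
  expect_error(make_triplication(g, 1, 1), "distinct")
  expect_error(make_triplication(g, 2, 1), "left of")
  expect_error(make_dimeric_circle(g, 1, 1), "distinct")
})

test_that("dimeric circle length arithmetic and wraparound sampling hold", {
  g <- build_genome(seed = 14, length = 400,
                    iir_specs = data.frame(arm_len = c(3, 4),
                                           spacer_len = c(10, 8),
                                           position = c(50, 250)))
  cj <- g$truth[1, ]; tj <- g$truth[2, ]
  circ <- make_dimeric_circle(g, 1, 2)
  expect_identical(circ$topology, "circular")
  expect_equal(nchar(circ$seq),
               2 * (tj$l1 - cj$r2) + (cj$r2 - cj$l1) + (tj$r2 - tj$l1))
  ms <- molecule_set(list(circ), 1)
  reads <- simulate_reads(ms, depth = 30, read_len = 150, error_rate = 0,
                          seed = 2)
  # every read must be a substring of the doubled circle or its revcomp
  doubled <- paste0(circ$seq, circ$seq)
  hit <- vapply(reads$seq, function(r) {
    grepl(r, doubled, fixed = TRUE) || grepl(revcomp(r), doubled,
                                             fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
  # wraparound: some reads start within read_len of the end of the circle
  starts <- as.integer(vapply(strsplit(reads$read_id, "|", fixed = TRUE),
                              `[[`, character(1), 2))
  expect_true(any(starts > nchar(circ$seq) - 150))
})

test_that("error-free reads are exact substrings and coverage matches the
requested depth", {
  g <- build_genome(seed = 21, length = 50000)
  wt <- make_wild_type(g)
  ms <- molecule_set(list(wt), 1)
  reads <- simulate_reads(ms, depth = 100, read_len = 150, error_rate = 0,
                          seed = 3)
  idx <- sample.int(nrow(reads), 200)
  S <- g$contigs[[1]]
  hit <- vapply(reads$seq[idx], function(r) {
    grepl(r, S, fixed = TRUE) || grepl(revcomp(r), S, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
  # mean per-base coverage in the interior within 5% of depth
  starts <- as.integer(vapply(strsplit(reads$read_id, "|", fixed = TRUE),
                              `[[`, character(1), 2))
  cov <- tabulate(unlist(Map(seq.int, starts + 1L, starts + 150L)),
                  nbins = 50000L)
  interior <- cov[5000:45000]
  expect_lt(abs(mean(interior) - 100) / 100, 0.05)
})

test_that("read simulation is deterministic given the seed", {
  g <- build_genome(seed = 30, length = 5000)
  ms <- molecule_set(list(make_wild_type(g)), 1)
  r1 <- simulate_reads(ms, depth = 20, error_rate = 0.01, seed = 99)
  r2 <- simulate_reads(ms, depth = 20, error_rate = 0.01, seed = 99)
  expect_identical(r1, r2)
})

test_that("simulate_population pools subclones and records the expected
truth junctions", {
  g <- build_genome(seed = 31, length = 30000,
                    iir_specs = data.frame(arm_len = c(4, 5, 6),
                                           spacer_len = c(61, 50, 44),
                                           position = c(8000, 12000, 20000)))
  il <- make_inverted_linear(g, 1)
  tr <- make_triplication(g, 2, 3)
  wt <- make_wild_type(g)
  pop <- simulate_population(
    g, list(list(molecule = wt, frequency = 0.6),
            list(molecule = il, frequency = 0.3),
            list(molecule = tr, frequency = 0.1)),
    depth = 20, error_rate = 0, seed = 5)
  expect_equal(nrow(pop$truth), 3L)
  expect_equal(sum(pop$truth$loop_side == "LEFT"), 2L)   # two CJ-type folds
  expect_equal(sum(pop$truth$loop_side == "RIGHT"), 1L)  # one TJ-type fold

  wt_only <- simulate_population(
    g, list(list(molecule = wt, frequency = 1)), depth = 5, seed = 6)
  expect_equal(nrow(wt_only$truth), 0L)

  expect_error(simulate_population(
    g, list(list(molecule = wt, frequency = -0.1),
            list(molecule = il, frequency = 1.1)), depth = 5),
    "negative")
})

test_that("revcomp is an involution on generated sequences", {
  set.seed(77)
  for (i in 1:20) {
    x <- random_dna(sample(10:500, 1))
    expect_identical(revcomp(revcomp(x)), x)
  }
})
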