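test_that("usage ratios are equal when every repeat is used once and flag
missing strata", {
  iirs <- data.frame(arm_len = rep(2:6, each = 3),
                     spacer_len = rep(c(10, 50, 90), 5))
  used <- iirs
  tab <- usage_ratio(used, iirs, stratify_by = "arm_len")
  expect_true(all(tab$ratio == 1))
  expect_error(usage_ratio(used, iirs[0, ]), "empty potential")

  # a stratum present among used but absent from potential is missing
  used2 <- rbind(used, data.frame(arm_len = 9, spacer_len = 10))
  tab2 <- usage_ratio(used2, iirs, stratify_by = "arm_len")
  expect_true(is.na(tab2$ratio[tab2$stratum == 9]))
})

test_that("secondary-deletion junctions are excluded from usage tables", {
  iirs <- data.frame(arm_len = c(4, 4, 5), spacer_len = c(50, 60, 70))
  jx <- data.frame(arm_len = c(4, 5), spacer_len = c(50, 1500),
                   secondary_deletion = c(FALSE, TRUE))
  tab <- usage_ratio(jx, iirs, stratify_by = "arm_len")
  expect_equal(tab$used[tab$stratum == 5], 0L)
  expect_equal(tab$used[tab$stratum == 4], 1L)
})

test_that("uniformly drawn usage is flat and arm-weighted usage increases
with arm length", {
  set.seed(808)
  iirs <- data.frame(arm_len = sample(2:14, 2000, TRUE),
                     spacer_len = sample(0:250, 2000, TRUE))
  # null: used drawn uniformly from potential
  used <- iirs[sample.int(2000, 200), ]
  tab <- usage_ratio(used, iirs, stratify_by = "arm_len")
  p <- 200 / 2000
  se <- sqrt(p * (1 - p) / tab$potential)
  expect_true(all(abs(tab$ratio - p) <= 4 * se))

  # planted effect: usage probability proportional to arm length
  w <- iirs$arm_len / sum(iirs$arm_len)
  used2 <- iirs[sample.int(2000, 300, prob = w), ]
  tab2 <- usage_ratio(used2, iirs, stratify_by = "arm_len")
  expect_gt(cor(tab2$stratum, tab2$ratio, method = "spearman"), 0)
})

test_that("null usage draws reject a rank trend at roughly the nominal
rate", {
  set.seed(809)
  iirs <- data.frame(arm_len = sample(2:14, 1500, TRUE),
                     spacer_len = sample(0:250, 1500, TRUE))
  n_sim <- 200L
  rej <- 0L
  for (i in seq_len(n_sim)) {
    used <- iirs[sample.int(1500, 150), ]
    tab <- usage_ratio(used, iirs, stratify_by = "arm_len")
    ct <- suppressWarnings(
      stats::cor.test(tab$stratum, tab$ratio, method = "spearman",
                      exact = FALSE))
    if (ct$p.value < 0.05) rej <- rej + 1L
  }
  expect_lt(rej / n_sim, 0.12)
})

test_that("mann_whitney handles ties, separation and agrees with the
permutation oracle", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)
  expect_gte(r$p.value, 0.9)

  r2 <- mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r2$statistic, 0)

  set.seed(810)
  for (i in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:4, na, TRUE)   # small pool forces ties
    b <- sample(1:4, nb, TRUE)
    got <- mann_whitney(a, b)
    want <- oracle_mann_whitney(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value)
  }
})

test_that("the large-sample path matches wilcox.test's corrected normal
approximation", {
  set.seed(811)
  a <- rnorm(20); b <- rnorm(25, 0.4)
  got <- mann_whitney(a, b)
  want <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_identical(got$method, "normal")
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("chi-squared matches the textbook formula and is symmetric", {
  h <- chi_squared(matrix(c(10, 10, 10, 10), 2))
  expect_equal(h$statistic, 0)
  expect_equal(h$p.value, 1)

  # inverted vs direct clone counts with and without replication stress
  tab <- matrix(c(11, 3, 39, 73), nrow = 2)   # rows: no-HU, HU
  got <- chi_squared(tab)
  expect_equal(got$statistic, oracle_chi_squared(tab), tolerance = 1e-10)
  expect_equal(got$df, 1)
  perm <- chi_squared(tab[, 2:1])
  expect_equal(perm$statistic, got$statistic)

  expect_error(chi_squared(matrix(c(0, 0, 5, 7), 2)), "zero row or column")
})

test_that("population junction balance classifies and conserves", {
  jx <- data.frame(
    population = c("p1", "p1", "p1", "p2", "p2", "p3"),
    orientation = c("CJ", "CJ", "TJ", "CJ", "TJ", "NONPRODUCTIVE"),
    stringsAsFactors = FALSE)
  out <- cj_tj_balance(jx, populations = c("p1", "p2", "p3", "p4"))
  per <- out$per_population
  expect_identical(per$balance[per$population == "p1"], "UNBALANCED")
  expect_identical(per$balance[per$population == "p2"], "MATCHED")
  expect_identical(per$balance[per$population == "p3"], "NO_INVERTED")
  expect_identical(per$balance[per$population == "p4"], "NO_INVERTED")
  expect_equal(sum(out$totals), 4)
})

test_that("an inverted-linear-only population is UNBALANCED end to end", {
  g <- build_genome(seed = 812, length = 20000,
                    iir_specs = data.frame(arm_len = 6, spacer_len = 55,
                                           position = 8000))
  pop <- simulate_population(
    g, list(list(molecule = make_wild_type(g), frequency = 0.7),
            list(molecule = make_inverted_linear(g, 1), frequency = 0.3)),
    depth = 40, error_rate = 0, seed = 813)
  jx <- call_junctions(pop$reads, g, focal_locus = 15000)
  jx$population <- "c1"
  out <- cj_tj_balance(jx)
  expect_identical(out$per_population$balance, "UNBALANCED")
  expect_equal(out$per_population$cj, 1L)
  expect_equal(out$per_population$tj, 0L)
})
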