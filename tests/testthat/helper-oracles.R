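# Independent oracles used across the test files. These deliberately take
# different computational routes than the package implementations.

# Brute-force IIR scan: for every candidate innermost pair (one position
# per left-arm end, one spacer), extend the arm outward by direct character
# comparison and apply the maximality conditions explicitly. O(n * spacer)
# with per-pair extension; fine for sequences up to a few kb.
oracle_scan_iirs <- function(seq, min_arm = 2L, max_arm = 14L,
                             max_spacer = 250L) {
  x <- strsplit(toupper(seq), "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cx <- unname(comp[x])            # NA for N
  n <- length(x)
  pair_ok <- function(p, q) !is.na(cx[p]) && cx[p] == x[q]
  out <- list()
  for (p in seq_len(n - 1L)) {     # 1-based innermost left position
    qmax <- min(n, p + 1L + max_spacer)
    qs <- (p + 1L):qmax
    hit <- !is.na(cx[p]) & x[qs] == cx[p]
    for (q in qs[hit]) {
      s <- q - p - 1L
      # inner maximality: skip if the pair just inside also matches
      if (s >= 2L && pair_ok(p + 1L, q - 1L)) next
      a <- 1L
      while (p - a >= 1L && q + a <= n && pair_ok(p - a, q + a)) a <- a + 1L
      if (a < min_arm || a > max_arm) next
      out[[length(out) + 1L]] <-
        c(l1 = p - a, l2 = p, r1 = q - 1L, r2 = q - 1L + a,
          arm_len = a, spacer_len = s)   # 0-based half-open
    }
  }
  if (length(out) == 0L)
    return(data.frame(l1 = integer(0), l2 = integer(0), r1 = integer(0),
                      r2 = integer(0), arm_len = integer(0),
                      spacer_len = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$l1, df$r1, df$arm_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Mann-Whitney permutation oracle: U computed by direct pairwise counting
# (not ranks); p by full enumeration of group assignments.
oracle_mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(ix) {
    g1 <- pooled[ix]; g2 <- pooled[-ix]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  U <- u_of(seq_len(na))
  mu <- na * nb / 2
  sel <- utils::combn(na + nb, na)
  us <- apply(sel, 2L, u_of)
  p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  list(statistic = U, p.value = p)
}

# Textbook Pearson chi-squared statistic from marginals.
oracle_chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp)^2 / exp)
}

# A small genome + single planted IIR + inverted linear, shared by several
# caller tests.
toy_il_setup <- function(seed, len = 20000L, arm = 4L, spacer = 61L,
                         pos = 10000L, arm_seq = NULL, depth = 60,
                         error_rate = 0) {
  g <- build_genome(seed = seed, length = len,
                    iir_specs = data.frame(arm_len = arm,
                                           spacer_len = spacer,
                                           position = pos,
                                           arm_seq = if (is.null(arm_seq))
                                             NA_character_ else arm_seq))
  il <- make_inverted_linear(g, 1)
  ms <- molecule_set(list(il), 1)
  reads <- simulate_reads(ms, depth = depth, read_len = 150L,
                          error_rate = error_rate, seed = seed + 1L)
  list(genome = g, il = il, molecules = ms, reads = reads,
       truth = ms$truth_junctions)
}
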