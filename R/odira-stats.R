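# Statistical layer: used-vs-potential repeat enrichment, rank-sum and
# chi-squared tests, per-population junction balance.

#' Used-versus-potential IIR usage table
#'
#' Compares the repeats found at inverted junctions ("used") with all
#' repeats available in the scanned region ("potential"), stratified by
#' arm length or by spacer bin. Junctions flagged as secondary deletions
#' (spacer > 1 kb) are excluded, since the initiating repeat geometry
#' cannot be deduced for them. Strata with zero potential are reported
#' with a missing ratio.
#'
#' @param junctions junction table (columns `arm_len`, `spacer_len`,
#'   optionally `secondary_deletion`).
#' @param iirs potential IIR table from [scan_iirs()].
#' @param stratify_by `"arm_len"` or `"spacer_bin"`.
#' @param spacer_bin_width width of spacer bins in bp (default 20).
#' @return data frame with `stratum`, `potential`, `used`, `ratio`.
#' @export
usage_ratio <- function(junctions, iirs,
                        stratify_by = c("arm_len", "spacer_bin"),
                        spacer_bin_width = 20L) {
  stratify_by <- match.arg(stratify_by)
  if (nrow(iirs) == 0L) stop("empty potential IIR table")
  if (!is.null(junctions$secondary_deletion))
    junctions <- junctions[!junctions$secondary_deletion, , drop = FALSE]
  strat <- function(df) {
    if (stratify_by == "arm_len") df$arm_len
    else floor(df$spacer_len / spacer_bin_width) * spacer_bin_width
  }
  sp <- strat(iirs)
  su <- strat(junctions)
  levels <- sort(unique(c(sp, su)))
  pot <- as.integer(table(factor(sp, levels = levels)))
  used <- as.integer(table(factor(su, levels = levels)))
  ratio <- ifelse(pot > 0L, used / pot, NA_real_)
  data.frame(stratum = levels, potential = pot, used = used, ratio = ratio)
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with midrank tie handling. The two-sided p-value is exact
#' (enumeration of all group assignments of the pooled sample) when
#' `n_a + n_b <= exact_limit`, and a tie-corrected normal approximation
#' with continuity correction otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_limit pooled-size limit for exact enumeration (default
#'   12).
#' @return list with `statistic` (U for sample `a`), `p.value`, and
#'   `method` ("exact" or "normal").
#' @export
mann_whitney <- function(a, b, exact_limit = 12L) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)                       # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= exact_limit) {
    sel <- utils::combn(n, na)
    ua <- apply(sel, 2L, function(ix) sum(rk[ix])) - na * (na + 1) / 2
    p <- mean(abs(ua - mu) >= abs(U - mu) - 1e-9)
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0)
    return(list(statistic = U, p.value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = U, p.value = p, method = "normal")
}

#' Pearson chi-squared test on a contingency table
#'
#' Wraps `stats::chisq.test` (no continuity correction). Tables with a
#' zero row or column are rejected, as are tables with non-positive
#' expected counts.
#'
#' @param table matrix of counts (e.g. 2 x k).
#' @return list with `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero row or column")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(res$expected <= 0)) stop("non-positive expected count")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected)
}

#' Centromere-/telomere-proximal junction balance per population
#'
#' A population with equal positive numbers of CJs and TJs is `MATCHED`
#' (consistent with a complete triplication or circle); unequal counts
#' are `UNBALANCED` (evidence of free inverted-linear intermediates);
#' populations with no inverted junctions are `NO_INVERTED`.
#'
#' @param junctions junction table with columns `population` and
#'   `orientation` (CJ/TJ; other orientations are ignored).
#' @param populations optional vector of population ids to report (so
#'   that populations with no junctions are included).
#' @return list with `per_population` (data frame `population`, `cj`,
#'   `tj`, `balance`) and `totals` (named counts of the three classes).
#' @export
cj_tj_balance <- function(junctions, populations = NULL) {
  if (is.null(populations)) populations <- unique(junctions$population)
  per <- do.call(rbind, lapply(populations, function(p) {
    j <- junctions[junctions$population == p, , drop = FALSE]
    cj <- sum(j$orientation == "CJ", na.rm = TRUE)
    tj <- sum(j$orientation == "TJ", na.rm = TRUE)
    balance <- if (cj == 0L && tj == 0L) "NO_INVERTED"
               else if (cj == tj) "MATCHED" else "UNBALANCED"
    data.frame(population = p, cj = cj, tj = tj, balance = balance,
               stringsAsFactors = FALSE)
  }))
  totals <- c(MATCHED = sum(per$balance == "MATCHED"),
              UNBALANCED = sum(per$balance == "UNBALANCED"),
              NO_INVERTED = sum(per$balance == "NO_INVERTED"))
  list(per_population = per, totals = totals)
}
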