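#' Scan a sequence for interrupted inverted repeats
#'
#' Enumerates every maximal-arm interrupted inverted repeat (IIR): two
#' reverse-complementary arms of `min_arm`-`max_arm` bp separated by a
#' spacer of at most `max_spacer` bp. Arms are exact matches (no
#' mismatches; N never matches) and maximal: the match can be extended
#' neither outward nor inward, so sub-arms of a longer perfect arm are not
#' separately reported. Arm runs longer than `max_arm` are measured at
#' their true length and then filtered by the bound. Perfect palindromes
#' (spacer 0) are included; self-overlapping arm pairs are excluded by
#' construction.
#'
#' @param sequence a DNA string, or an `odira_genome` (first contig).
#' @param min_arm,max_arm arm length bounds in bp (defaults 2 and 14).
#' @param max_spacer maximum spacer in bp (default 250).
#' @return data frame sorted by `l1` with columns `l1`, `l2`, `r1`, `r2`
#'   (0-based half-open arm coordinates), `arm_len`, `spacer_len` and
#'   `total_len` (= `r2 - l1`).
#' @export
scan_iirs <- function(sequence, min_arm = 2L, max_arm = 14L,
                      max_spacer = 250L) {
  if (inherits(sequence, "odira_genome")) sequence <- sequence$contigs[[1L]]
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (min_arm < 1L) stop("min_arm must be at least 1")
  stopifnot(max_arm >= min_arm, max_spacer >= 0L)
  if (nchar(sequence) < 2L * min_arm)
    stop("sequence shorter than twice the minimum arm length")
  res <- cpp_scan_iirs(toupper(sequence), as.integer(min_arm),
                       as.integer(max_spacer))
  res <- res[res$arm_len <= max_arm, , drop = FALSE]
  res <- res[order(res$l1, res$r1, res$arm_len), , drop = FALSE]
  res$total_len <- res$r2 - res$l1
  rownames(res) <- NULL
  res
}

#' Bin IIR density along a region
#'
#' Counts IIRs per fixed-width bin (by the bin of their left-arm start
#' `l1`), optionally stratified by arm length.
#'
#' @param iirs data frame from [scan_iirs()].
#' @param bin bin width in bp (default 1000).
#' @param region numeric length-2 vector `c(start, end)` (0-based
#'   half-open) covering all IIRs; default spans from 0 to the last `r2`.
#' @param by_arm if TRUE return a matrix of counts with one row per arm
#'   length.
#' @return data frame with `bin_start` and `count` (or a count matrix when
#'   `by_arm`).
#' @export
bin_density <- function(iirs, bin = 1000L, region = NULL, by_arm = FALSE) {
  if (bin <= 0L) stop("bin width must be positive")
  if (is.null(region)) {
    region <- c(0, if (nrow(iirs)) max(iirs$r2) else bin)
  }
  if (nrow(iirs) && (any(iirs$l1 < region[1L]) || any(iirs$l1 >= region[2L])))
    stop("region does not cover all IIRs")
  start0 <- floor(region[1L] / bin) * bin
  nbins <- ceiling((region[2L] - start0) / bin)
  starts <- start0 + bin * (seq_len(nbins) - 1L)
  idx <- floor((iirs$l1 - starts[1L]) / bin) + 1L
  if (by_arm) {
    arms <- sort(unique(iirs$arm_len))
    m <- matrix(0L, nrow = length(arms), ncol = length(starts),
                dimnames = list(arm_len = arms, bin_start = starts))
    for (i in seq_along(arms)) {
      t <- tabulate(idx[iirs$arm_len == arms[i]], nbins = length(starts))
      m[i, ] <- t
    }
    return(m)
  }
  data.frame(bin_start = starts,
             count = tabulate(idx, nbins = length(starts)))
}

#' Histograms of IIR arm length, spacer length and total length
#'
#' Total interrupted-repeat length is `r2 - l1` = 2 x arm + spacer.
#'
#' @param iirs data frame from [scan_iirs()].
#' @param normalize if TRUE, report frequencies summing to 1 instead of
#'   counts.
#' @return list of three data frames: `arm` (`arm_len`, `count`), `spacer`
#'   (`spacer_len`, `count`) and `total` (`total_len`, `count`); the count
#'   column is named `freq` when normalized.
#' @export
size_spacing_histograms <- function(iirs, normalize = FALSE) {
  one <- function(v, nm) {
    if (length(v) == 0L)
      return(setNames(data.frame(integer(0), numeric(0)),
                      c(nm, if (normalize) "freq" else "count")))
    t <- table(v)
    out <- data.frame(as.integer(names(t)), as.numeric(t))
    names(out) <- c(nm, "count")
    if (normalize) {
      out$count <- out$count / sum(out$count)
      names(out)[2L] <- "freq"
    }
    out
  }
  list(arm = one(iirs$arm_len, "arm_len"),
       spacer = one(iirs$spacer_len, "spacer_len"),
       total = one(iirs$total_len, "total_len"))
}
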