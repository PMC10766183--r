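# Split-read detection and inverted-junction characterization.
#
# Mapping is exact-match anchor-and-extend: the maximal exact prefix match
# and maximal exact suffix match of each read are found on either strand of
# any contig via a k-mer index (k = 20 by default). A read whose two
# maximal matches cannot be explained by one contiguous placement is a
# split read. This is sufficient for 150 bp reads against <= 1 Mb
# references; the junctions of interest are exact-sequence features, so no
# scoring matrix or gapped alignment is used.

#' Map reads and detect split reads
#'
#' @param reads data frame with `read_id` and `seq` (all reads the same
#'   length), or a character vector of sequences.
#' @param reference named character vector of contigs, or an
#'   `odira_genome`.
#' @param k anchor k-mer length (default 20); must not exceed the read
#'   length.
#' @return `map_reads` returns one row per read with the maximal
#'   prefix/suffix match of each (contig, strand, 0-based half-open
#'   interval, matched length, number of best-scoring placements) plus a
#'   `status` of `"full"`, `"contiguous"` (one placement with substitution
#'   errors), `"split"`, `"partial"` (one side unmapped) or `"unmapped"`.
#'   `find_split_reads` returns the subset with junction evidence (status
#'   split or partial) together with the fragment signature used for
#'   deduplication (the 5' outer mapping coordinate and strand of the
#'   read).
#' @export
map_reads <- function(reads, reference, k = 20L) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = sprintf("r%d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  if (inherits(reference, "odira_genome")) reference <- reference$contigs
  stopifnot(is.character(reference), length(reference) >= 1L)
  L <- unique(nchar(reads$seq))
  if (length(L) > 1L) stop("reads must all have the same length")
  if (length(L) == 0L) L <- 0L
  if (k > L && nrow(reads) > 0L) stop("k exceeds the read length")

  if (nrow(reads) == 0L) {
    m <- data.frame(read_id = character(0))
  } else {
    m <- as.data.frame(cpp_map_reads(reads$seq, unname(reference),
                                     as.integer(k)),
                       stringsAsFactors = FALSE)
    m$read_id <- reads$read_id
  }
  cn <- names(reference)
  m$p_contig <- cn[m$p_contig]
  m$s_contig <- cn[m$s_contig]
  m$seq <- reads$seq

  pm <- m$p_len > 0L
  sm <- m$s_len > 0L
  full <- pm & m$p_len == L
  # contiguous-with-substitutions: same contig/strand, consistent offset
  contig_plus <- pm & sm & !full & m$p_strand == 1L & m$s_strand == 1L &
    m$p_contig == m$s_contig & m$p_lo == (m$s_hi - L)
  contig_minus <- pm & sm & !full & m$p_strand == -1L & m$s_strand == -1L &
    m$p_contig == m$s_contig & m$p_hi == (m$s_lo + L)
  contiguous <- contig_plus | contig_minus
  contiguous[is.na(contiguous)] <- FALSE

  status <- rep("unmapped", nrow(m))
  status[pm & sm & !full & !contiguous] <- "split"
  status[xor(pm, sm)] <- "partial"
  status[contiguous] <- "contiguous"
  status[full] <- "full"
  m$status <- status
  m$read_len <- L
  m
}

#' @rdname map_reads
#' @export
find_split_reads <- function(reads, reference, k = 20L) {
  m <- map_reads(reads, reference, k)
  sr <- m[m$status %in% c("split", "partial"), , drop = FALSE]
  # fragment signature: 5' outer mapping coordinate + strand of the read
  sig_pos <- ifelse(!is.na(sr$p_strand) & sr$p_strand == 1L, sr$p_lo,
                    sr$p_hi)
  sig_pos[is.na(sig_pos)] <- ifelse(
    !is.na(sr$s_strand[is.na(sig_pos)]) & sr$s_strand[is.na(sig_pos)] == 1L,
    sr$s_lo[is.na(sig_pos)], sr$s_hi[is.na(sig_pos)])
  sr$fragment_sig <- paste(ifelse(is.na(sr$p_strand), "NA", sr$p_strand),
                           sig_pos, sep = ":")
  rownames(sr) <- NULL
  sr
}

#' Classify split reads into junction categories
#'
#' The five categories: `INVERTED` (segments on opposite strands of the
#' same contig), `DIRECT` (same strand of the same contig,
#' non-contiguous), `DE_NOVO_TELOMERE` (a mapped segment plus an unmapped
#' tail of tandem C(1-3)A / G(1-3)T telomere repeat),
#' `TELOMERE_TRANSLOCATION` (second segment inside an annotated telomere),
#' `INTERNAL_TRANSLOCATION` (second segment inside an annotated repetitive
#' element), and `UNCLASSIFIED` otherwise. Telomere-motif rules take
#' precedence over the repeat-annotation rule; INVERTED/DIRECT require
#' both segments uniquely mapped.
#'
#' @param split_reads data frame from [find_split_reads()].
#' @param telomeres optional data frame of telomere intervals (`contig`,
#'   `start`, `end`, 0-based half-open).
#' @param repeats optional data frame of repetitive-element intervals in
#'   the same format (e.g. read from BED with [read_bed()]).
#' @return the input with a `category` column appended.
#' @export
classify_split_read <- function(split_reads, telomeres = NULL,
                                repeats = NULL) {
  r <- split_reads
  n <- nrow(r)
  cat <- rep("UNCLASSIFIED", n)

  both <- r$p_len > 0L & r$s_len > 0L
  uniq <- both & r$p_nhit == 1L & r$s_nhit == 1L
  same <- uniq & r$p_contig == r$s_contig
  same[is.na(same)] <- FALSE
  cat[same & r$p_strand != r$s_strand] <- "INVERTED"
  cat[same & r$p_strand == r$s_strand] <- "DIRECT"

  onesided <- xor(r$p_len > 0L, r$s_len > 0L)
  if (any(onesided)) {
    # the unmapped tail is the read minus the mapped part
    tail_seq <- ifelse(r$p_len > 0L,
                       substr(r$seq, r$p_len + 1L, r$read_len),
                       substr(r$seq, 1L, r$read_len - r$s_len))
    cat[onesided & is_telomere_seq(tail_seq)] <- "DE_NOVO_TELOMERE"
  }

  # both mapped but cross-contig or multi-mapping: annotation lookups
  in_ann <- function(ann, contig, lo, hi) {
    if (is.null(ann) || nrow(ann) == 0L || is.na(contig)) return(FALSE)
    any(ann$contig == contig & lo < ann$end & hi > ann$start)
  }
  for (i in which(both & cat == "UNCLASSIFIED")) {
    tel2 <- in_ann(telomeres, r$p_contig[i], r$p_lo[i], r$p_hi[i]) ||
      in_ann(telomeres, r$s_contig[i], r$s_lo[i], r$s_hi[i])
    if (tel2) { cat[i] <- "TELOMERE_TRANSLOCATION"; next }
    rep2 <- in_ann(repeats, r$p_contig[i], r$p_lo[i], r$p_hi[i]) ||
      in_ann(repeats, r$s_contig[i], r$s_lo[i], r$s_hi[i])
    if (rep2) cat[i] <- "INTERNAL_TRANSLOCATION"
  }
  split_reads$category <- cat
  split_reads
}

#' Characterize inverted (foldback) junctions from split reads
#'
#' For a read whose two segments lie on opposite strands of the same
#' contig, the breakpoint homology h between the maximal prefix and suffix
#' matches is the inverted-repeat arm (the reference carries
#' reverse-complement copies of it at the two segment ends); the spacer is
#' the distance between the two arm copies' inner boundaries on the
#' reference, and the junction position is the midpoint of the spacer
#' interval. The loop side is LEFT when the read folds back toward higher
#' coordinates (prefix segment on the minus strand) and RIGHT when it
#' folds toward lower coordinates.
#'
#' @param split_reads data frame from [find_split_reads()] (rows with both
#'   segments mapped to the same contig on opposite strands; others are
#'   rejected).
#' @return data frame with one row per read: `read_id`, `contig`, `pos`,
#'   `arm_len`, `spacer_len`, `loop_side`, `fragment_sig`.
#' @export
characterize_inverted_junction <- function(split_reads) {
  sr <- split_reads
  if (nrow(sr) == 0L)
    return(data.frame(read_id = character(0), contig = character(0),
                      pos = numeric(0), arm_len = integer(0),
                      spacer_len = numeric(0), loop_side = character(0),
                      fragment_sig = character(0), stringsAsFactors = FALSE))
  if (any(is.na(sr$p_contig) | is.na(sr$s_contig)))
    stop("all reads must have both segments mapped")
  if (any(sr$p_contig != sr$s_contig))
    stop("segments on different contigs: not a foldback")
  if (any(sr$p_strand == sr$s_strand))
    stop("segments on the same strand: not an inverted junction")

  L <- sr$read_len
  h <- sr$p_len + sr$s_len - L          # breakpoint homology = arm
  keep <- h >= 0L                       # a gap in read coverage (errors
  sr <- sr[keep, , drop = FALSE]        # near the fold) is uninformative
  h <- h[keep]
  left_loop <- sr$p_strand == -1L       # prefix on minus: fold at low end

  # The h homologous bases sit at the fold-side end of both segments (the
  # low ends for a leftward fold, the high ends for a rightward fold).
  # Which segment carries which arm copy depends on the sequencing
  # orientation of the read, so the junction tuple is canonicalized from
  # the ordered pair of fold-side endpoints: left arm = [lo_min, lo_min+h),
  # right arm starts at lo_max (loop LEFT), and mirrored for loop RIGHT.
  pos <- numeric(nrow(sr))
  spacer <- numeric(nrow(sr))
  i <- left_loop
  lo_min <- pmin(sr$p_lo[i], sr$s_lo[i])
  lo_max <- pmax(sr$p_lo[i], sr$s_lo[i])
  pos[i] <- (lo_min + h[i] + lo_max) / 2
  spacer[i] <- lo_max - (lo_min + h[i])
  i <- !left_loop
  hi_min <- pmin(sr$p_hi[i], sr$s_hi[i])
  hi_max <- pmax(sr$p_hi[i], sr$s_hi[i])
  pos[i] <- (hi_min + hi_max - h[i]) / 2
  spacer[i] <- (hi_max - h[i]) - hi_min

  data.frame(read_id = sr$read_id, contig = sr$p_contig, pos = pos,
             arm_len = as.integer(h), spacer_len = spacer,
             loop_side = ifelse(left_loop, "LEFT", "RIGHT"),
             fragment_sig = sr$fragment_sig, stringsAsFactors = FALSE)
}

#' Collapse per-read junction calls and apply the fragment-support
#' threshold
#'
#' Reads are grouped by the canonical junction tuple (contig, position,
#' arm, spacer, loop side). Reads with identical fragment signatures
#' (outer 5' mapping coordinate and strand) are copies of the same
#' sequenced fragment and count once; junctions supported by fewer than
#' `min_support` unique fragments are removed as presumptive PCR
#' artifacts.
#'
#' @param junction_reads data frame from
#'   [characterize_inverted_junction()].
#' @param min_support minimum unique fragments (default 2).
#' @return junction table with `n_reads` and `n_unique_fragments` per
#'   junction, sorted by position.
#' @export
dedupe_and_threshold <- function(junction_reads, min_support = 2L) {
  if (nrow(junction_reads) == 0L) {
    out <- .empty_junction_table()
    out$orientation <- NULL
    return(out)
  }
  key <- paste(junction_reads$contig, junction_reads$pos,
               junction_reads$arm_len, junction_reads$spacer_len,
               junction_reads$loop_side, sep = "\r")
  n_reads <- tapply(key, key, length)
  n_frag <- tapply(junction_reads$fragment_sig, key,
                   function(s) length(unique(s)))
  first <- junction_reads[!duplicated(key), , drop = FALSE]
  fkey <- key[!duplicated(key)]
  out <- data.frame(contig = first$contig, pos = first$pos,
                    arm_len = first$arm_len, spacer_len = first$spacer_len,
                    loop_side = first$loop_side,
                    n_reads = as.integer(n_reads[fkey]),
                    n_unique_fragments = as.integer(n_frag[fkey]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_unique_fragments >= min_support, , drop = FALSE]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient inverted junctions relative to a focal locus
#'
#' With the centromere at lower coordinates, a junction left of the locus
#' is a productive centromere-proximal junction (CJ) only if its
#' single-stranded loop is on the LEFT, and a junction right of the locus
#' is a productive telomere-proximal junction (TJ) only if its loop is on
#' the RIGHT; the remaining combinations cannot participate in
#' amplification of the locus and are NONPRODUCTIVE.
#'
#' @param junctions junction table (with `contig`, `pos`, `loop_side`).
#' @param locus focal locus position (bp).
#' @param contig contig of the locus; junctions on other contigs get
#'   orientation `NA`.
#' @return the junction table with an `orientation` column
#'   (CJ/TJ/NONPRODUCTIVE/NA).
#' @export
orient_relative_to_locus <- function(junctions, locus, contig = NULL) {
  if (nrow(junctions) == 0L) {
    junctions$orientation <- character(0)
    return(junctions)
  }
  same <- if (is.null(contig)) rep(TRUE, nrow(junctions))
          else junctions$contig == contig
  orient <- ifelse(junctions$pos < locus & junctions$loop_side == "LEFT",
                   "CJ",
            ifelse(junctions$pos > locus & junctions$loop_side == "RIGHT",
                   "TJ", "NONPRODUCTIVE"))
  orient[!same] <- NA_character_
  junctions$orientation <- orient
  junctions
}

#' Call inverted junctions from reads against a reference
#'
#' Full pipeline: map and split, keep INVERTED reads, characterize,
#' deduplicate, threshold, and (optionally) orient relative to a focal
#' locus. Junctions whose spacer exceeds 1 kb are flagged
#' `secondary_deletion` (one inverted arm likely lost after the event) and
#' should be excluded from spacing statistics.
#'
#' @param reads data frame with `read_id`, `seq`.
#' @param reference named character vector of contigs or `odira_genome`.
#' @param config an [run_config()] (supplies `k` and `min_support`).
#' @param focal_locus optional locus position for CJ/TJ orientation.
#' @param telomeres,repeats optional annotations for
#'   [classify_split_read()].
#' @return junction table with columns `contig`, `pos`, `arm_len`,
#'   `spacer_len`, `loop_side`, `orientation`, `n_reads`,
#'   `n_unique_fragments`, `secondary_deletion`.
#' @export
call_junctions <- function(reads, reference, config = run_config(),
                           focal_locus = NULL, telomeres = NULL,
                           repeats = NULL) {
  sr <- find_split_reads(reads, reference, k = config$k)
  sr <- classify_split_read(sr, telomeres = telomeres, repeats = repeats)
  inv <- sr[sr$category == "INVERTED", , drop = FALSE]
  jr <- characterize_inverted_junction(inv)
  jx <- dedupe_and_threshold(jr, min_support = config$min_support)
  if (!is.null(focal_locus)) {
    jx <- orient_relative_to_locus(jx, focal_locus)
  } else {
    jx$orientation <- rep(NA_character_, nrow(jx))
  }
  jx$secondary_deletion <- jx$spacer_len > 1000
  jx <- jx[, c("contig", "pos", "arm_len", "spacer_len", "loop_side",
               "orientation", "n_reads", "n_unique_fragments",
               "secondary_deletion")]
  jx
}

#' Binned, median-normalized read depth
#'
#' Per-bin coverage from mapped reads (full, contiguous and split
#' placements all contribute their mapped intervals), divided by the
#' genome-wide median bin coverage to give a copy-number estimate.
#'
#' @param mapped data frame from [map_reads()].
#' @param reference named character vector of contigs or `odira_genome`.
#' @param bin bin width in bp (default 500).
#' @return data frame with `contig`, `bin_start`, `coverage` (mean fold
#'   coverage in the bin) and `copy_number`.
#' @export
binned_depth <- function(mapped, reference, bin = 500L) {
  if (inherits(reference, "odira_genome")) reference <- reference$contigs
  segs <- .placement_intervals(mapped)
  if (nrow(segs) == 0L) stop("no mapped reads")
  out <- do.call(rbind, lapply(names(reference), function(cn) {
    len <- nchar(reference[[cn]])
    starts <- seq(0L, len - 1L, by = bin)
    cov <- numeric(length(starts))
    s <- segs[segs$contig == cn, , drop = FALSE]
    if (nrow(s) > 0L) {
      # clip and spread each interval over the bins it overlaps
      lo <- pmax(s$lo, 0); hi <- pmin(s$hi, len)
      b1 <- pmin(floor(lo / bin), length(starts) - 1L)
      b2 <- pmin(floor((hi - 1) / bin), length(starts) - 1L)
      same <- b1 == b2
      if (any(same)) {
        add <- rowsum((hi - lo)[same], b1[same])
        cov[as.integer(rownames(add)) + 1L] <-
          cov[as.integer(rownames(add)) + 1L] + add[, 1L]
      }
      if (any(!same)) {
        for (i in which(!same)) {
          bs <- b1[i]:b2[i]
          seg_lo <- pmax(lo[i], starts[bs + 1L])
          seg_hi <- pmin(hi[i], starts[bs + 1L] + bin)
          cov[bs + 1L] <- cov[bs + 1L] + (seg_hi - seg_lo)
        }
      }
    }
    width <- pmin(starts + bin, len) - starts
    data.frame(contig = cn, bin_start = starts, coverage = cov / width,
               stringsAsFactors = FALSE)
  }))
  med <- median(out$coverage)
  if (med == 0) stop("zero median coverage; cannot normalize")
  out$copy_number <- out$coverage / med
  rownames(out) <- NULL
  out
}

# mapped intervals contributed by each read, by status
.placement_intervals <- function(mapped) {
  m <- mapped
  res <- list()
  f <- m$status == "full"
  if (any(f))
    res$full <- data.frame(contig = m$p_contig[f], lo = m$p_lo[f],
                           hi = m$p_hi[f], stringsAsFactors = FALSE)
  cg <- m$status == "contiguous"
  if (any(cg)) {
    plus <- m$p_strand[cg] == 1L
    lo <- ifelse(plus, m$p_lo[cg], m$p_hi[cg] - m$read_len[cg])
    res$contig <- data.frame(contig = m$p_contig[cg], lo = lo,
                             hi = lo + m$read_len[cg],
                             stringsAsFactors = FALSE)
  }
  sp <- m$status == "split"
  if (any(sp)) {
    res$split1 <- data.frame(contig = m$p_contig[sp], lo = m$p_lo[sp],
                             hi = m$p_hi[sp], stringsAsFactors = FALSE)
    res$split2 <- data.frame(contig = m$s_contig[sp], lo = m$s_lo[sp],
                             hi = m$s_hi[sp], stringsAsFactors = FALSE)
  }
  pt <- m$status == "partial"
  if (any(pt)) {
    pm <- pt & m$p_len > 0L
    if (any(pm))
      res$part1 <- data.frame(contig = m$p_contig[pm], lo = m$p_lo[pm],
                              hi = m$p_hi[pm], stringsAsFactors = FALSE)
    sm <- pt & m$s_len > 0L
    if (any(sm))
      res$part2 <- data.frame(contig = m$s_contig[sm], lo = m$s_lo[sm],
                              hi = m$s_hi[sm], stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(contig = character(0), lo = numeric(0),
                      hi = numeric(0)))
  do.call(rbind, res)
}
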