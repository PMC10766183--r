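# ODIRA product molecules built from a synthetic genome.
#
# Notation (0-based half-open, S = source contig, E = contig end):
# an IIR has left arm A1 = S[l1..l2), spacer P = S[l2..r1), right arm
# A2 = S[r1..r2), with A2 = revcomp(A1).

.iir_row <- function(genome, iir, contig) {
  if (is.numeric(iir) && length(iir) == 1L) {
    stopifnot(iir >= 1, iir <= nrow(genome$truth))
    genome$truth[iir, , drop = FALSE]
  } else {
    as.data.frame(iir, stringsAsFactors = FALSE)
  }
}

.junction_pos <- function(l2, r1) (l2 + r1) / 2  # midpoint of the spacer

.molecule <- function(label, seq, topology, junctions) {
  structure(list(label = label, seq = seq, topology = topology,
                 junctions = junctions), class = "odira_molecule")
}

#' Construct an inverted linear (hairpin-derived) molecule
#'
#' A single template switch at the fork moving toward the centromere
#' produces a hairpin-capped linear extending to the telomere; after
#' replication it persists as a fully duplex inverted linear
#' `IL = revcomp(S[r2..E)) . S[l1..E)`. The telomere-side flank appears
#' exactly twice in inverted orientation; the two arm copies and the spacer
#' appear once each at the central fold.
#'
#' @param genome an `odira_genome`.
#' @param iir a row index into `genome$truth` or a one-row data frame with
#'   columns `l1`, `l2`, `r1`, `r2`.
#' @param contig contig name (default the first contig).
#' @return an `odira_molecule` (linear) whose `junctions` element is the
#'   truth entry for the fold: position at the spacer midpoint, loop side
#'   LEFT.
#' @export
make_inverted_linear <- function(genome, iir, contig = names(genome$contigs)[1L]) {
  ir <- .iir_row(genome, iir, contig)
  S <- genome$contigs[[contig]]
  E <- nchar(S)
  if (ir$r2 >= E) stop("IIR must lie left of the contig end")
  if (ir$l1 < 0L) stop("IIR outside contig")
  flank <- substr(S, ir$r2 + 1L, E)            # S[r2..E)
  body <- substr(S, ir$l1 + 1L, E)             # S[l1..E) = A1 P A2 flank
  seq <- paste0(revcomp(flank), body)
  jx <- data.frame(contig = contig, pos = .junction_pos(ir$l2, ir$r1),
                   arm_len = ir$l2 - ir$l1, spacer_len = ir$r1 - ir$l2,
                   loop_side = "LEFT", stringsAsFactors = FALSE)
  .molecule(sprintf("IL_%d", ir$l1), seq, "linear", jx)
}

.check_two_iirs <- function(cj, tj) {
  if (cj$l1 == tj$l1 && cj$r2 == tj$r2)
    stop("CJ and TJ IIRs must be distinct")
  if (!(cj$r2 <= tj$l1))
    stop("CJ IIR must lie entirely left of the TJ IIR")
}

#' Construct an interstitial inverted triplication
#'
#' The final chromosomal ODIRA product: the segment between the two IIRs is
#' present three times with the center copy inverted,
#' `T = S[0..t_l1) . Jt . revcomp(S[c_r2..t_l1)) . Jc . S[c_r2..E)`
#' where `Jc`/`Jt` are the full centromere-/telomere-proximal IIRs
#' (arm-spacer-arm). Reads across the two seams show a centromere-proximal
#' junction (loop LEFT) and a telomere-proximal junction (loop RIGHT).
#'
#' @param genome an `odira_genome`.
#' @param cj_iir,tj_iir IIRs (row index or one-row data frame); the CJ IIR
#'   must lie entirely left of the TJ IIR.
#' @param contig contig name.
#' @return an `odira_molecule` (linear) with two truth junctions.
#' @export
make_triplication <- function(genome, cj_iir, tj_iir,
                              contig = names(genome$contigs)[1L]) {
  cj <- .iir_row(genome, cj_iir, contig)
  tj <- .iir_row(genome, tj_iir, contig)
  .check_two_iirs(cj, tj)
  S <- genome$contigs[[contig]]
  E <- nchar(S)
  if (tj$r2 >= E) stop("TJ IIR must lie left of the contig end")
  left <- substr(S, 1L, tj$l1)                       # S[0..t_l1)
  Jt <- substr(S, tj$l1 + 1L, tj$r2)                 # A1t Pt A2t
  mid <- substr(S, cj$r2 + 1L, tj$l1)                # S[c_r2..t_l1)
  Jc <- substr(S, cj$l1 + 1L, cj$r2)                 # A1c Pc A2c
  right <- substr(S, cj$r2 + 1L, E)                  # S[c_r2..E)
  seq <- paste0(left, Jt, revcomp(mid), Jc, right)
  jx <- data.frame(
    contig = contig,
    pos = c(.junction_pos(cj$l2, cj$r1), .junction_pos(tj$l2, tj$r1)),
    arm_len = c(cj$l2 - cj$l1, tj$l2 - tj$l1),
    spacer_len = c(cj$r1 - cj$l2, tj$r1 - tj$l2),
    loop_side = c("LEFT", "RIGHT"), stringsAsFactors = FALSE)
  .molecule(sprintf("TRP_%d_%d", cj$l1, tj$l1), seq, "linear", jx)
}

#' Construct an inverted dimeric circle
#'
#' Simultaneous template switches at both diverging forks expel a closed
#' self-complementary molecule; after replication it is the circular duplex
#' `C = Jc . S[c_r2..t_l1) . Jt . revcomp(S[c_r2..t_l1))` carrying two
#' inverted copies of the captured segment. Reads crossing either seam give
#' CJ- and TJ-type junctions.
#'
#' @inheritParams make_triplication
#' @return an `odira_molecule` with `topology = "circular"`.
#' @export
make_dimeric_circle <- function(genome, cj_iir, tj_iir,
                                contig = names(genome$contigs)[1L]) {
  cj <- .iir_row(genome, cj_iir, contig)
  tj <- .iir_row(genome, tj_iir, contig)
  .check_two_iirs(cj, tj)
  S <- genome$contigs[[contig]]
  if (tj$r2 >= nchar(S)) stop("TJ IIR must lie left of the contig end")
  Jc <- substr(S, cj$l1 + 1L, cj$r2)
  mid <- substr(S, cj$r2 + 1L, tj$l1)
  Jt <- substr(S, tj$l1 + 1L, tj$r2)
  seq <- paste0(Jc, mid, Jt, revcomp(mid))
  jx <- data.frame(
    contig = contig,
    pos = c(.junction_pos(cj$l2, cj$r1), .junction_pos(tj$l2, tj$r1)),
    arm_len = c(cj$l2 - cj$l1, tj$l2 - tj$l1),
    spacer_len = c(cj$r1 - cj$l2, tj$r1 - tj$l2),
    loop_side = c("LEFT", "RIGHT"), stringsAsFactors = FALSE)
  .molecule(sprintf("CIRC_%d_%d", cj$l1, tj$l1), seq, "circular", jx)
}

#' Construct a wild-type (unrearranged) molecule from a contig
#'
#' @param genome an `odira_genome`.
#' @param contig contig name.
#' @return an `odira_molecule` with no junctions.
#' @export
make_wild_type <- function(genome, contig = names(genome$contigs)[1L]) {
  .molecule("WT", genome$contigs[[contig]], "linear",
            data.frame(contig = character(0), pos = numeric(0),
                       arm_len = integer(0), spacer_len = numeric(0),
                       loop_side = character(0), stringsAsFactors = FALSE))
}

#' Bundle molecules with subclone abundances
#'
#' @param molecules list of `odira_molecule` objects.
#' @param abundances numeric vector of the same length; must be
#'   non-negative and sum to 1.
#' @return an object of class `odira_molecules` with elements `molecules`,
#'   `abundances` and `truth_junctions` (the union of the molecules'
#'   junction tables, deduplicated, with a `loop_side` per junction).
#' @export
molecule_set <- function(molecules, abundances) {
  stopifnot(length(molecules) == length(abundances))
  if (any(abundances < 0)) stop("negative abundance")
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  truth <- do.call(rbind, lapply(molecules, `[[`, "junctions"))
  if (is.null(truth) || nrow(truth) == 0L) {
    truth <- data.frame(contig = character(0), pos = numeric(0),
                        arm_len = integer(0), spacer_len = numeric(0),
                        loop_side = character(0), stringsAsFactors = FALSE)
  } else {
    truth <- unique(truth)
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
  }
  structure(list(molecules = molecules, abundances = abundances,
                 truth_junctions = truth), class = "odira_molecules")
}

#' @export
print.odira_molecules <- function(x, ...) {
  cat("odira molecule set:\n")
  for (i in seq_along(x$molecules)) {
    m <- x$molecules[[i]]
    cat(sprintf("  %-14s %8d bp  %-8s abundance %.3f\n",
                m$label, nchar(m$seq), m$topology, x$abundances[i]))
  }
  cat(sprintf("  %d truth junction(s)\n", nrow(x$truth_junctions)))
  invisible(x)
}

#' Count occurrences of a pattern in a molecule (forward + reverse
#' complement)
#'
#' Overlap-aware exact substring counting, used to verify the construction
#' invariants of synthetic molecules on small examples.
#'
#' @param seq subject DNA string.
#' @param pattern query DNA string.
#' @return integer count of forward plus reverse-complement occurrences.
#' @export
count_occurrences <- function(seq, pattern) {
  cnt <- function(s, p) {
    n <- nchar(s); m <- nchar(p)
    if (m > n) return(0L)
    starts <- seq_len(n - m + 1L)
    sum(substring(s, starts, starts + m - 1L) == p)
  }
  rc <- revcomp(pattern)
  k <- cnt(seq, pattern)
  if (rc != pattern) k <- k + cnt(seq, rc)
  k
}
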