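#' Simulate single-end short reads from a molecule set
#'
#' Read start positions are uniform per molecule, with the number of reads
#' per molecule proportional to abundance x length so that a molecule at
#' abundance f receives f x `depth` fold coverage. Strand is uniform.
#' Substitution errors are injected at `error_rate` per base. Circular
#' molecules are sampled with wraparound (sequence-doubling trick). Read
#' names encode the source molecule, 0-based start and strand
#' (`label|start|strand|i`), which serves as the truth annotation in tests.
#'
#' @param molecules an [molecule_set()] object.
#' @param depth total fold coverage (default 125).
#' @param read_len read length in bp (default 150).
#' @param error_rate per-base substitution probability (default 0.001).
#' @param seed optional integer seed.
#' @return data frame with columns `read_id`, `seq`.
#' @export
simulate_reads <- function(molecules, depth = 125, read_len = 150L,
                           error_rate = 0.001, seed = NULL) {
  stopifnot(inherits(molecules, "odira_molecules"))
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  read_len <- as.integer(read_len)

  all_ids <- character(0)
  all_seqs <- character(0)
  for (i in seq_along(molecules$molecules)) {
    m <- molecules$molecules[[i]]
    ab <- molecules$abundances[i]
    if (ab == 0) next
    len <- nchar(m$seq)
    circular <- identical(m$topology, "circular")
    if (!circular && len < read_len) {
      warning("molecule ", m$label, " shorter than read length; skipped")
      next
    }
    n <- round(depth * ab * len / read_len)
    if (n < 1L) next
    template <- if (circular) {
      paste0(m$seq, substr(m$seq, 1L, read_len))  # wraparound
    } else {
      m$seq
    }
    max_start <- if (circular) len else len - read_len + 1L
    starts <- sample.int(max_start, n, replace = TRUE)      # 1-based
    fwd <- runif(n) < 0.5
    seqs <- substring(template, starts, starts + read_len - 1L)
    if (any(!fwd)) seqs[!fwd] <- revcomp(seqs[!fwd])
    ids <- sprintf("%s|%d|%s|%d", m$label, starts - 1L,
                   ifelse(fwd, "+", "-"), seq_len(n))
    all_ids <- c(all_ids, ids)
    all_seqs <- c(all_seqs, seqs)
  }

  reads <- data.frame(read_id = all_ids, seq = all_seqs,
                      stringsAsFactors = FALSE)
  if (error_rate > 0 && nrow(reads) > 0L)
    reads$seq <- .inject_errors(reads$seq, read_len, error_rate)
  reads
}

# substitution errors: Binomial(total bases, rate) positions, each replaced
# by a uniformly drawn different base
.inject_errors <- function(seqs, read_len, error_rate) {
  n <- length(seqs)
  k <- rbinom(1L, n * read_len, error_rate)
  if (k == 0L) return(seqs)
  at <- sample.int(n * read_len, k)
  ri <- ((at - 1L) %/% read_len) + 1L
  pos <- ((at - 1L) %% read_len) + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    old <- substr(seqs[ri[j]], pos[j], pos[j])
    new <- sample(setdiff(bases, old), 1L)
    substr(seqs[ri[j]], pos[j], pos[j]) <- new
  }
  seqs
}

#' Simulate population sequencing of subclones carrying ODIRA products
#'
#' Pools reads across subclones of one culture and injects singleton
#' PCR-artifact foldback reads: `artifact_rate x N` chimeric reads, each
#' constructed as a blunt foldback at a distinct random reference position,
#' so that every artifact junction is supported by exactly one fragment and
#' must be removed by the two-fragment threshold.
#'
#' @param genome an `odira_genome` (the artifact reads are drawn from its
#'   first contig).
#' @param subclones list of `list(molecule =, frequency =)` entries;
#'   frequencies must be non-negative and sum to 1.
#' @param depth,read_len,error_rate as in [simulate_reads()].
#' @param artifact_rate fraction of reads that are chimeric artifacts
#'   (default 0).
#' @param seed optional integer seed.
#' @return list with `reads` (data frame), `truth` (junction truth table),
#'   and `molecules` (the [molecule_set()]).
#' @export
simulate_population <- function(genome, subclones, depth = 125,
                                read_len = 150L, error_rate = 0.001,
                                artifact_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- vapply(subclones, function(s) s$frequency, numeric(1))
  if (any(freqs < 0)) stop("negative subclone frequency")
  if (abs(sum(freqs) - 1) > 1e-8) stop("subclone frequencies must sum to 1")
  mols <- molecule_set(lapply(subclones, `[[`, "molecule"), freqs)
  reads <- simulate_reads(mols, depth = depth, read_len = read_len,
                          error_rate = error_rate)
  n_art <- round(artifact_rate * nrow(reads))
  if (n_art > 0L) {
    art <- .artifact_reads(genome$contigs[[1L]], n_art, read_len)
    reads <- rbind(reads, art)
  }
  list(reads = reads, truth = mols$truth_junctions, molecules = mols)
}

# blunt chimeric foldbacks at distinct random positions; split point far
# enough from the read ends that both anchors are mappable
.artifact_reads <- function(S, n, read_len) {
  E <- nchar(S)
  lo <- read_len + 50L
  hi <- E - read_len - 50L
  q <- sample(seq.int(lo, hi), n, replace = FALSE)       # distinct junctions
  u <- sample(seq.int(30L, read_len - 30L), n, replace = TRUE)
  left_raw <- substring(S, q + 1L, q + u)                # S[q .. q+u)
  seqs <- paste0(revcomp(left_raw),
                 substring(S, q + 1L, q + (read_len - u)))
  data.frame(read_id = sprintf("ARTIFACT|%d|+|%d", q, seq_len(n)),
             seq = seqs, stringsAsFactors = FALSE)
}
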