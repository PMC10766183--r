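#' Build a synthetic chromosome-end contig with planted interrupted
#' inverted repeats
#'
#' Generates a uniform-composition contig and plants interrupted inverted
#' repeats (IIRs): a random arm of `arm_len` bp at offset `position`, its
#' reverse complement `spacer_len` bp downstream. The bases immediately
#' inside and outside each planted arm pair are constrained so the arm
#' match can be extended neither outward nor inward -- the planted
#' (arm, spacer) is therefore the maximal, uniquely recoverable geometry.
#' Spontaneous background IIRs elsewhere in the contig are expected and
#' tolerated.
#'
#' @param seed integer random seed (the generator is deterministic given
#'   `seed` and the spec list).
#' @param length contig length in bp (default 80000, a chromosome-end
#'   scale).
#' @param iir_specs data frame (or list coercible to one) with columns
#'   `arm_len`, `spacer_len`, `position` (0-based offset of the left arm
#'   start). Optional column `arm_seq` fixes the arm sequence.
#' @param telomeric_ends if TRUE, prepend >= 100 bp of tandem C(1-3)A
#'   repeat at the left end and append G(1-3)T at the right end; planted
#'   coordinates in the truth table are shifted accordingly.
#' @param contig_name name of the contig (default "chrS").
#' @return an object of class `odira_genome`: a list with `contigs`
#'   (named character vector), `truth` (data frame of planted IIRs with
#'   columns `contig`, `l1`, `l2`, `r1`, `r2`, `arm_len`, `spacer_len`)
#'   and `telomeric` (logical).
#' @export
build_genome <- function(seed, length = 80000L, iir_specs = NULL,
                         telomeric_ends = FALSE, contig_name = "chrS") {
  set.seed(seed)
  length <- as.integer(length)

  specs <- if (is.null(iir_specs) || NROW(iir_specs) == 0L) {
    data.frame(arm_len = integer(0), spacer_len = integer(0),
               position = integer(0))
  } else {
    as.data.frame(iir_specs, stringsAsFactors = FALSE)
  }
  n_spec <- nrow(specs)
  if (n_spec > 0L) {
    stopifnot(all(c("arm_len", "spacer_len", "position") %in% names(specs)))
    if (any(specs$arm_len < 2L))
      stop("planted IIR arms must be at least 2 bp")
    if (any(specs$spacer_len < 0L)) stop("negative spacer")
    span_end <- specs$position + 2L * specs$arm_len + specs$spacer_len
    if (any(specs$position < 1L) || any(span_end > length - 1L))
      stop("planted IIR outside contig (1 bp boundary margin required)")
    o <- order(specs$position)
    specs <- specs[o, , drop = FALSE]
    if (n_spec > 1L) {
      # require a 1 bp guard between consecutive IIR spans so the
      # maximality fix-up of one cannot touch another
      ends <- specs$position + 2L * specs$arm_len + specs$spacer_len
      if (any(specs$position[-1L] <= ends[-n_spec]))
        stop("planted IIRs overlap")
    }
  }

  x <- sample(c("A", "C", "G", "T"), length, replace = TRUE)

  plant_one <- function(x, a, s, pos, arm_seq = NULL) {
    arm <- if (is.null(arm_seq) || is.na(arm_seq)) {
      paste(sample(c("A", "C", "G", "T"), a, replace = TRUE), collapse = "")
    } else {
      toupper(arm_seq)
    }
    stopifnot(nchar(arm) == a)
    l1 <- pos; l2 <- pos + a; r1 <- l2 + s; r2 <- r1 + a  # 0-based half-open
    x[(l1 + 1L):l2] <- strsplit(arm, "")[[1L]]
    x[(r1 + 1L):r2] <- strsplit(revcomp(arm), "")[[1L]]
    # arm maximality: break any chance outward extension ...
    if (l1 >= 1L && r2 + 1L <= length(x)) {
      while (.comp_match(x[l1], x[r2 + 1L]))
        x[r2 + 1L] <- sample(c("A", "C", "G", "T"), 1L)
    }
    # ... and any chance inward extension (spacer of >= 2 only; a 1 bp
    # spacer base would have to pair with itself, which cannot happen)
    if (s >= 2L) {
      while (.comp_match(x[l2 + 1L], x[r1]))
        x[r1] <- sample(c("A", "C", "G", "T"), 1L)
    }
    list(x = x, arm = arm, l1 = l1, l2 = l2, r1 = r1, r2 = r2)
  }

  truth <- data.frame(contig = character(0), l1 = integer(0),
                      l2 = integer(0), r1 = integer(0), r2 = integer(0),
                      arm_len = integer(0), spacer_len = integer(0),
                      arm_seq = character(0), stringsAsFactors = FALSE)
  if (n_spec > 0L) {
    for (i in seq_len(n_spec)) {
      p <- plant_one(x, specs$arm_len[i], specs$spacer_len[i],
                     specs$position[i],
                     if ("arm_seq" %in% names(specs)) specs$arm_seq[i])
      x <- p$x
      truth <- rbind(truth, data.frame(
        contig = contig_name, l1 = p$l1, l2 = p$l2, r1 = p$r1, r2 = p$r2,
        arm_len = specs$arm_len[i], spacer_len = specs$spacer_len[i],
        arm_seq = p$arm, stringsAsFactors = FALSE))
    }
  }

  seq <- paste(x, collapse = "")
  if (telomeric_ends) {
    tel_l <- telomere_repeat(120L, "left")
    tel_r <- telomere_repeat(120L, "right")
    shift <- nchar(tel_l)
    seq <- paste0(tel_l, seq, tel_r)
    if (nrow(truth) > 0L) {
      truth$l1 <- truth$l1 + shift; truth$l2 <- truth$l2 + shift
      truth$r1 <- truth$r1 + shift; truth$r2 <- truth$r2 + shift
    }
  }

  g <- list(contigs = setNames(seq, contig_name), truth = truth,
            telomeric = telomeric_ends)
  class(g) <- "odira_genome"
  g
}

#' @export
print.odira_genome <- function(x, ...) {
  cat(sprintf("odira synthetic genome: %d contig(s), %d planted IIR(s)%s\n",
              length(x$contigs), nrow(x$truth),
              if (x$telomeric) ", telomeric ends" else ""))
  for (nm in names(x$contigs))
    cat(sprintf("  %s: %d bp\n", nm, nchar(x$contigs[[nm]])))
  invisible(x)
}

#' Verify the reverse-complement identity of planted IIRs
#'
#' Checks that for every truth entry `S[r1:r2] == revcomp(S[l1:l2])`.
#'
#' @param genome an `odira_genome`.
#' @return TRUE (invisibly) or an error.
#' @export
verify_truth_iirs <- function(genome) {
  tr <- genome$truth
  for (i in seq_len(nrow(tr))) {
    s <- genome$contigs[[tr$contig[i]]]
    left <- substr(s, tr$l1[i] + 1L, tr$l2[i])
    right <- substr(s, tr$r1[i] + 1L, tr$r2[i])
    if (right != revcomp(left))
      stop("truth IIR ", i, " fails its reverse-complement identity")
  }
  invisible(TRUE)
}
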