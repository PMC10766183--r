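#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TGGC")  # "GCCA"
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

#' Random uniform DNA sequence
#'
#' Background composition is i.i.d. uniform over A, C, G, T.
#'
#' @param n sequence length in bp.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# complement lookup for single characters; N complements nothing
.comp_vec <- c(A = "T", C = "G", G = "C", T = "A")

# TRUE if b is the Watson-Crick complement of a (N never matches)
.comp_match <- function(a, b) {
  ca <- .comp_vec[a]
  !is.na(ca) & ca == b
}

#' Tandem telomere repeat sequence
#'
#' Yeast telomeres are irregular tandem repeats of C(1-3)A on the
#' left-end strand and G(1-3)T on the right. Used both to decorate
#' synthetic contig ends and as the motif for de novo telomere detection.
#'
#' @param n approximate length in bp (the last repeat unit is kept whole).
#' @param side `"left"` (C-rich) or `"right"` (G-rich).
#' @return a DNA string of length >= `n`.
#' @export
telomere_repeat <- function(n, side = c("left", "right")) {
  side <- match.arg(side)
  units <- character(0)
  len <- 0L
  while (len < n) {
    m <- sample(1:3, 1L)
    u <- if (side == "left") paste0(strrep("C", m), "A")
         else                paste0(strrep("G", m), "T")
    units <- c(units, u)
    len <- len + nchar(u)
  }
  paste(units, collapse = "")
}

#' Test whether a sequence is pure tandem telomere repeat
#'
#' Matches C(1-3)A or G(1-3)T tandem arrays (at least `min_len` bases,
#' allowing a trailing partial unit) in either reading orientation.
#'
#' @param x character vector of DNA strings.
#' @param min_len minimum length to count as telomeric (default 12).
#' @return logical vector.
#' @export
is_telomere_seq <- function(x, min_len = 12L) {
  ok_len <- nchar(x) >= min_len
  pat_c <- "^(C{1,3}A)+C{0,3}$"
  pat_g <- "^(G{1,3}T)+G{0,3}$"
  pat_c2 <- "^A?(C{1,3}A)+C{0,3}$"   # tolerate a leading partial unit
  pat_g2 <- "^T?(G{1,3}T)+G{0,3}$"
  hit <- grepl(pat_c, x) | grepl(pat_g, x) | grepl(pat_c2, x) | grepl(pat_g2, x)
  rc <- revcomp(x)
  hit_rc <- grepl(pat_c, rc) | grepl(pat_g, rc) |
    grepl(pat_c2, rc) | grepl(pat_g2, rc)
  ok_len & (hit | hit_rc)
}
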