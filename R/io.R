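#' Read DNA sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA strings, in file order.
#'   Sequences may contain only A, C, G, T, N after uppercasing.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence contains letters other than A,C,G,T,N: ",
         names(seqs)[bad][1L])
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ read sets
#'
#' Reads are stored as a data frame with columns `read_id` and `seq`.
#' Qualities are written as a constant Sanger 'I' (Q40); the pipeline's read
#' model has no per-base quality.
#'
#' @param reads data frame with columns `read_id`, `seq`.
#' @param path FASTQ path.
#' @return `read_fastq` returns the read data frame; `write_fastq` returns
#'   `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

.junction_cols <- c("contig", "pos", "arm_len", "spacer_len", "loop_side",
                    "orientation", "n_reads", "n_unique_fragments")
.loop_tokens <- c("LEFT", "RIGHT")
.orient_tokens <- c("CJ", "TJ", "NONPRODUCTIVE", "NA")

#' Write and read inverted-junction tables
#'
#' Tab-separated tables with one row per characterized inverted junction.
#' Coordinates are 0-based (stated in the header comment); `pos` is the
#' midpoint of the spacer interval and may end in .5.
#'
#' @param junctions data frame with columns `contig`, `pos`, `arm_len`,
#'   `spacer_len`, `loop_side` (LEFT/RIGHT), `orientation`
#'   (CJ/TJ/NONPRODUCTIVE/NA), `n_reads`, `n_unique_fragments`. Extra
#'   columns are preserved.
#' @param path TSV path.
#' @return `read_junction_table` returns the junction data frame;
#'   `write_junction_table` returns `path` invisibly.
#' @export
write_junction_table <- function(junctions, path) {
  if (nrow(junctions) > 0L) {
    stopifnot(all(.junction_cols %in% names(junctions)))
    stopifnot(all(junctions$loop_side %in% .loop_tokens))
    stopifnot(all(as.character(junctions$orientation) %in% .orient_tokens |
                    is.na(junctions$orientation)))
    junctions <- junctions[, c(.junction_cols,
                               setdiff(names(junctions), .junction_cols)),
                           drop = FALSE]
  } else {
    junctions <- .empty_junction_table()
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# odira junction table; coordinates 0-based half-open", con)
  write.table(junctions, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_table
#' @export
read_junction_table <- function(path) {
  if (!file.exists(path)) stop("junction table not found: ", path)
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(.empty_junction_table())
  stopifnot(all(.junction_cols %in% names(x)))
  x$orientation <- as.character(x$orientation)
  if (!all(x$loop_side %in% .loop_tokens))
    stop("unknown loop_side token in ", path)
  bad <- !(x$orientation %in% .orient_tokens) & !is.na(x$orientation)
  if (any(bad))
    stop("unknown orientation token '", x$orientation[bad][1L], "' in ", path)
  x
}

.empty_junction_table <- function() {
  data.frame(contig = character(0), pos = numeric(0),
             arm_len = integer(0), spacer_len = numeric(0),
             loop_side = character(0), orientation = character(0),
             n_reads = integer(0), n_unique_fragments = integer(0),
             stringsAsFactors = FALSE)
}

#' Write and read interrupted inverted repeat tables
#'
#' @param iirs data frame as returned by [scan_iirs()].
#' @param path TSV path.
#' @return the IIR data frame (`read_iir_table`) or `path` invisibly.
#' @export
write_iir_table <- function(iirs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# odira IIR table; coordinates 0-based half-open", con)
  write.table(iirs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_iir_table
#' @export
read_iir_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write BED interval files
#'
#' Standard 0-based half-open BED, handled through rtracklayer. Used for
#' repeat annotations, telomere annotations and junction export.
#'
#' @param path BED path.
#' @param intervals data frame with columns `contig`, `start`, `end`
#'   (0-based half-open) and optionally `name`.
#' @return `read_bed` returns such a data frame.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) df$name <- nm
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$contig,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  if (!is.null(intervals$name)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write replication origin tables
#'
#' @param origins data frame with columns `position` (bp) and `active`
#'   (logical).
#' @param path TSV path.
#' @return the origin data frame, or `path` invisibly.
#' @export
read_origin_table <- function(path) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("position", "active") %in% names(x)))
  x$active <- as.logical(x$active)
  x[order(x$position), , drop = FALSE]
}

#' @rdname read_origin_table
#' @export
write_origin_table <- function(origins, path) {
  write.table(origins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
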