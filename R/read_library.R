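#' Construct a read library
#'
#' A read library holds sequencing reads as three parallel components:
#' read identifiers, nucleotide sequences over the alphabet `A,C,G,T,N`,
#' and per-base Phred quality scores.
#'
#' @param id Character vector of unique, non-empty read identifiers.
#' @param seq Character vector of nucleotide sequences (upper-cased on
#'   input; only `A,C,G,T,N` are allowed).
#' @param qual List of integer vectors of Phred scores (range 0-60), one
#'   vector per read, each the same length as its sequence.
#'
#' @return An object of class `read_library`: a list with elements `id`,
#'   `seq` and `qual`.
#' @export
#' @examples
#' lib <- read_library("r1", "ACGT", list(c(30L, 30L, 20L, 10L)))
#' length(lib)
read_library <- function(id, seq, qual) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (!is.list(qual)) qual <- list(qual)
  qual <- lapply(qual, function(q) as.integer(q))
  if (length(id) != length(seq) || length(id) != length(qual))
    stop("id, seq and qual must have the same length")
  if (any(!nzchar(id))) stop("read ids must be non-empty")
  if (anyDuplicated(id)) stop("read ids must be unique within a library")
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequences may only contain A, C, G, T, N")
  if (any(nchar(seq) != lengths(qual)))
    stop("each quality vector must match its sequence length")
  bad_q <- vapply(qual, function(q) length(q) > 0 && (min(q) < 0 || max(q) > 60),
                  logical(1))
  if (any(bad_q)) stop("Phred scores must lie in [0, 60]")
  structure(list(id = id, seq = seq, qual = qual), class = "read_library")
}

#' @export
length.read_library <- function(x) length(x$id)

#' @export
`[.read_library` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i]),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  n <- length(x)
  cat("read_library with", n, "reads\n")
  if (n > 0) {
    len <- nchar(x$seq)
    cat(sprintf("  length: min %d, median %.0f, max %d\n",
                min(len), stats::median(len), max(len)))
    show <- utils::head(seq_len(n), 3)
    for (i in show)
      cat(sprintf("  %s  %s%s (%d bp)\n", x$id[i],
                  substr(x$seq[i], 1, 40),
                  if (nchar(x$seq[i]) > 40) "..." else "", len[i]))
    if (n > 3) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTQ file into a read library
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @param quality_offset ASCII offset of the quality encoding; 33 for
#'   standard Sanger/Illumina 1.8+ Phred encoding, 64 for legacy
#'   Illumina 1.3-1.7 data.
#' @return A [read_library].
#' @export
read_fastq <- function(path, quality_offset = 33) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  seqs <- as.character(x)
  qstr <- as.character(S4Vectors::mcols(x)$qualities)
  qual <- lapply(qstr, function(s) {
    if (!nzchar(s)) return(integer(0))
    as.integer(charToRaw(s)) - as.integer(quality_offset)
  })
  read_library(names(x), seqs, qual)
}

#' Write a read library to a FASTQ file
#'
#' @param lib A [read_library].
#' @param path Output file path.
#' @param quality_offset ASCII offset of the quality encoding (see
#'   [read_fastq]).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(lib, path, quality_offset = 33) {
  stopifnot(inherits(lib, "read_library"))
  qstr <- vapply(lib$qual, function(q) {
    if (length(q) == 0) return("")
    rawToChar(as.raw(q + as.integer(quality_offset)))
  }, character(1))
  x <- Biostrings::DNAStringSet(lib$seq)
  names(x) <- lib$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

# Reverse complement of plain character sequences (A,C,G,T,N).
revcomp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq)))
  unname(out)
}
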