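#' Quality-control parameters
#'
#' Thresholds for read preprocessing. The defaults reproduce the standard
#' PRINSEQ-style settings for 454 pyrosequencing libraries: reads shorter
#' than 200 bp, with mean Phred quality below 20, with more than 1%
#' ambiguous bases (N), or with a DUST low-complexity score above 7 are
#' removed, and 3'-terminal bases with quality below 10 are trimmed first.
#'
#' @param min_len Minimum read length in bases after trimming (removal is
#'   strict: `length < min_len`).
#' @param min_mean_q Minimum mean Phred quality (removal if mean `< min_mean_q`).
#' @param max_n_frac Maximum tolerated fraction of N bases (removal if
#'   fraction `> max_n_frac`).
#' @param dust_max Maximum tolerated DUST score on the 0-100 scale
#'   (removal if score `> dust_max`).
#' @param trim_q 3'-trim threshold: trailing bases with quality
#'   `< trim_q` are removed.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_len = 200, min_mean_q = 20, max_n_frac = 0.01,
                      dust_max = 7, trim_q = 10) {
  stopifnot(min_len >= 0, min_mean_q >= 0,
            max_n_frac >= 0, max_n_frac <= 1,
            dust_max >= 0, dust_max <= 100, trim_q >= 0)
  structure(list(min_len = min_len, min_mean_q = min_mean_q,
                 max_n_frac = max_n_frac, dust_max = dust_max,
                 trim_q = trim_q),
            class = "qc_params")
}

#' Trim low-quality 3' tails from reads
#'
#' Removes the trailing run of bases whose quality score is below
#' `trim_q`; all bases before that run are left untouched. A read whose
#' every base falls below the threshold becomes empty.
#'
#' @param lib A [read_library].
#' @param trim_q Phred threshold; trailing bases with quality `< trim_q`
#'   are dropped.
#' @return The trimmed [read_library] (sequence and qualities trimmed
#'   together; ids unchanged).
#' @export
trim_three_prime <- function(lib, trim_q = 10) {
  stopifnot(inherits(lib, "read_library"))
  keep_len <- vapply(lib$qual, function(q) {
    ok <- which(q >= trim_q)
    if (length(ok) == 0) 0L else max(ok)
  }, integer(1))
  seq <- substr(lib$seq, 1L, keep_len)
  qual <- mapply(function(q, k) q[seq_len(k)], lib$qual, keep_len,
                 SIMPLIFY = FALSE)
  structure(list(id = lib$id, seq = seq, qual = qual),
            class = "read_library")
}

#' Mean Phred quality per read
#'
#' @param lib A [read_library] with no empty reads.
#' @return Numeric vector of arithmetic mean qualities, one per read.
#' @export
mean_quality <- function(lib) {
  stopifnot(inherits(lib, "read_library"))
  if (any(lengths(lib$qual) == 0))
    stop("mean quality is undefined for empty reads")
  vapply(lib$qual, function(q) mean(q), numeric(1))
}

#' Fraction of ambiguous (N) bases
#'
#' @param seq Character vector of non-empty nucleotide sequences.
#' @return Numeric vector: count of `N` divided by sequence length.
#' @export
ambiguous_fraction <- function(seq) {
  seq <- toupper(as.character(seq))
  len <- nchar(seq)
  if (any(len == 0)) stop("ambiguous fraction is undefined for empty sequences")
  n_count <- nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))
  n_count / len
}

#' DUST low-complexity score
#'
#' Whole-read triplet-frequency score on a 0-100 scale. With `m = L - 2`
#' overlapping 3-mers and per-3-mer counts `c_k`, the raw score is
#' `S = sum c_k (c_k - 1) / 2` and the reported score is
#' `100 * S / (m (m - 1) / 2)`. A homopolymer (a single repeated triplet)
#' scores 100; a read whose triplets are all distinct scores 0. Reads with
#' fewer than two triplets (length < 4) carry no repeat signal and score 0.
#'
#' @param seq Character vector of sequences of length >= 3.
#' @return Numeric vector of scores in `[0, 100]`.
#' @export
dust_score <- function(seq) {
  seq <- toupper(as.character(seq))
  if (any(nchar(seq) < 3))
    stop("DUST score requires sequences of length >= 3")
  vapply(seq, function(s) {
    L <- nchar(s)
    m <- L - 2L
    if (m < 2L) return(0)
    tri <- substring(s, seq_len(m), seq_len(m) + 2L)
    cnt <- tabulate(match(tri, unique(tri)))
    s_raw <- sum(cnt * (cnt - 1)) / 2
    100 * s_raw / (m * (m - 1) / 2)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Find artificial replicate reads
#'
#' Reads with identical sequences, and reads that are exact reverse
#' complements of one another (which implies equal length), are treated
#' as artificial replicates of a single template. Within every such
#' group the first read in input order is kept as the representative and
#' all other ids are returned for discarding.
#'
#' @param lib A [read_library] (typically after 3' trimming).
#' @return Character vector of read ids to discard (possibly empty).
#' @export
find_artificial_replicates <- function(lib) {
  stopifnot(inherits(lib, "read_library"))
  if (length(lib) == 0) return(character(0))
  rc <- revcomp(lib$seq)
  canon <- ifelse(lib$seq <= rc, lib$seq, rc)
  lib$id[duplicated(canon)]
}

#' Preprocess a read library
#'
#' Runs the full quality-control chain: 3' quality trimming, then the
#' length, mean-quality, ambiguity and DUST-complexity filters, and
#' finally artificial-replicate removal among the surviving reads. Each
#' removed read is attributed to the first criterion it fails, in that
#' fixed order, so the per-criterion counts plus the kept count always
#' equal the input count.
#'
#' Reads shorter than 3 bases after trimming are always removed by the
#' length filter (the DUST score is undefined for them), even if
#' `min_len` is smaller.
#'
#' @param lib A [read_library].
#' @param params A [qc_params] object.
#' @return A list with elements `kept` (the trimmed, filtered
#'   [read_library]) and `report` (a `qc_report`: per-read dispositions
#'   and per-criterion removal counts).
#' @export
preprocess_reads <- function(lib, params = qc_params()) {
  stopifnot(inherits(lib, "read_library"), inherits(params, "qc_params"))
  n <- length(lib)
  trimmed <- trim_three_prime(lib, params$trim_q)
  criterion <- rep(NA_character_, n)
  alive <- rep(TRUE, n)

  len <- nchar(trimmed$seq)
  fail <- alive & (len < params$min_len | len < 3L)
  criterion[fail] <- "length"
  alive[fail] <- FALSE

  if (any(alive)) {
    mq <- mean_quality(trimmed[alive])
    fail_ids <- trimmed$id[alive][mq < params$min_mean_q]
    fail <- trimmed$id %in% fail_ids
    criterion[fail] <- "mean_quality"
    alive[fail] <- FALSE
  }

  if (any(alive)) {
    nf <- ambiguous_fraction(trimmed$seq[alive])
    fail_ids <- trimmed$id[alive][nf > params$max_n_frac]
    fail <- trimmed$id %in% fail_ids
    criterion[fail] <- "ambiguity"
    alive[fail] <- FALSE
  }

  if (any(alive)) {
    ds <- dust_score(trimmed$seq[alive])
    fail_ids <- trimmed$id[alive][ds > params$dust_max]
    fail <- trimmed$id %in% fail_ids
    criterion[fail] <- "complexity"
    alive[fail] <- FALSE
  }

  if (any(alive)) {
    rep_ids <- find_artificial_replicates(trimmed[alive])
    fail <- trimmed$id %in% rep_ids
    criterion[fail] <- "replicate"
    alive[fail] <- FALSE
  }

  criterion[alive] <- "kept"
  crits <- c("length", "mean_quality", "ambiguity", "complexity",
             "replicate", "kept")
  counts <- vapply(crits, function(cr) sum(criterion == cr), integer(1))
  report <- structure(
    list(dispositions = data.frame(read_id = lib$id,
                                   criterion = criterion,
                                   stringsAsFactors = FALSE),
         counts = counts,
         n_input = n),
    class = "qc_report")
  list(kept = trimmed[alive], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_input, "reads in,", x$counts[["kept"]], "kept\n")
  rem <- x$counts[setdiff(names(x$counts), "kept")]
  for (nm in names(rem))
    cat(sprintf("  removed (%s): %d\n", nm, rem[[nm]]))
  invisible(x)
}

#' Write a QC audit log
#'
#' Writes the per-read disposition table of a `qc_report` as TSV
#' (columns `read_id`, `criterion`).
#'
#' @param report A `qc_report` from [preprocess_reads].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  utils::write.table(report$dispositions, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
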