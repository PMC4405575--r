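#' @importFrom utils read.delim write.table count.fields head
NULL

.hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
               "mismatches", "gap_opens", "qstart", "qend",
               "sstart", "send", "evalue", "bitscore")

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

.validate_hits <- function(hits) {
  miss <- setdiff(.hit_cols, names(hits))
  if (length(miss))
    stop("hit table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(hits)) {
    if (any(hits$qstart > hits$qend)) stop("hit table: qstart > qend")
    if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
      stop("hit table: pct_identity outside [0, 100]")
    if (any(hits$evalue < 0)) stop("hit table: negative e-value")
  }
  hits
}

#' Read a 12-column tabular homology hit table
#'
#' Parses the standard tab-separated homology search output (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score; the BLAST
#' `outfmt 6` dialect, 1-based inclusive coordinates).
#'
#' @param path Path to the tabular file. An empty file yields an empty
#'   table; rows with a column count other than 12 raise an error naming
#'   the offending line(s).
#' @return A data frame with typed columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0 || all(is.na(nf))) return(.empty_hits())
  bad <- which(nf != 12)
  if (length(bad))
    stop("malformed hit table ", path, ": expected 12 columns at line",
         if (length(bad) > 1) "s " else " ",
         paste(head(bad, 5), collapse = ", "))
  hits <- read.delim(path, header = FALSE, quote = "", comment.char = "",
                     col.names = .hit_cols,
                     colClasses = c("character", "character", "numeric",
                                    "integer", "integer", "integer",
                                    "integer", "integer", "integer",
                                    "integer", "numeric", "numeric"),
                     stringsAsFactors = FALSE)
  .validate_hits(hits)
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits A hit table data frame (see [read_hit_table]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  .validate_hits(hits)
  write.table(hits[, .hit_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Best hit of a single query
#'
#' Selects the hit with the maximal bit score; ties are broken by the
#' lower e-value, then by the lexicographically smallest subject id, so
#' the choice is deterministic and independent of row order.
#'
#' @param hits Non-empty hit table rows for one query.
#' @return The single best-hit row.
#' @export
best_hit <- function(hits) {
  .validate_hits(hits)
  if (nrow(hits) == 0) stop("best_hit: no hits supplied")
  ord <- order(-hits$bitscore, hits$evalue, hits$subject_id)
  hits[ord[1], , drop = FALSE]
}

# One best-hit row per query, same tie-break rules as best_hit().
.best_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Classify one read as SSU rRNA, LSU rRNA or non-rRNA
#'
#' Hits with e-value above the cutoff are discarded first. A read with
#' passing hits in only one of the two rRNA reference tables takes that
#' label; with passing hits in both it is assigned to the database where
#' its best hit has the higher bit score (ties go to SSU, a fixed
#' documented rule); with no passing hit it is non-rRNA.
#'
#' @param ssu_hits,lsu_hits Hit table rows of one read against the SSU
#'   and LSU rRNA references (either may be empty).
#' @param evalue_cutoff Maximum e-value for a hit to count (default 1e-10).
#' @return A list with `label` (one of `"SSU"`, `"LSU"`, `"NONRRNA"`)
#'   and `best_hit` (the winning hit row, or `NULL` for non-rRNA).
#' @export
classify_rrna_read <- function(ssu_hits, lsu_hits, evalue_cutoff = 1e-10) {
  ssu_hits <- .validate_hits(ssu_hits)
  lsu_hits <- .validate_hits(lsu_hits)
  ssu_hits <- ssu_hits[ssu_hits$evalue <= evalue_cutoff, , drop = FALSE]
  lsu_hits <- lsu_hits[lsu_hits$evalue <= evalue_cutoff, , drop = FALSE]
  has_ssu <- nrow(ssu_hits) > 0
  has_lsu <- nrow(lsu_hits) > 0
  if (!has_ssu && !has_lsu)
    return(list(label = "NONRRNA", best_hit = NULL))
  if (has_ssu && !has_lsu)
    return(list(label = "SSU", best_hit = best_hit(ssu_hits)))
  if (!has_ssu && has_lsu)
    return(list(label = "LSU", best_hit = best_hit(lsu_hits)))
  bs <- best_hit(ssu_hits)
  bl <- best_hit(lsu_hits)
  if (bs$bitscore >= bl$bitscore) list(label = "SSU", best_hit = bs)
  else list(label = "LSU", best_hit = bl)
}

#' Partition a read library into SSU, LSU and non-rRNA fractions
#'
#' Applies [classify_rrna_read] to every read, using homology hit tables
#' against the SSU and LSU rRNA references. Hits whose query id is not in
#' `read_ids` are ignored with a warning. Within the non-rRNA fraction,
#' reads listed in `smallrna_ids` (e.g. flagged by an external
#' covariance-model search against a small-RNA database) are subtracted;
#' the remainder are the putative mRNA reads.
#'
#' @param read_ids Character vector of read ids (the preprocessed library).
#' @param ssu_table,lsu_table Hit tables against the SSU and LSU references.
#' @param smallrna_ids Optional character vector of non-rRNA read ids
#'   identified as small-RNA-derived.
#' @param evalue_cutoff Maximum e-value for a hit to count (default 1e-10).
#' @return A list of class `rrna_partition` with `classes` (data frame
#'   `read_id`, `label`, `best_subject`, `bitscore`, `evalue`), the id
#'   vectors `ssu_ids`, `lsu_ids`, `nonrrna_ids`, and `mrna_ids`
#'   (non-rRNA minus small RNA).
#' @export
partition_library <- function(read_ids, ssu_table, lsu_table,
                              smallrna_ids = character(0),
                              evalue_cutoff = 1e-10) {
  read_ids <- as.character(read_ids)
  ssu_table <- .validate_hits(ssu_table)
  lsu_table <- .validate_hits(lsu_table)
  for (nm in c("ssu", "lsu")) {
    tab <- if (nm == "ssu") ssu_table else lsu_table
    unknown <- setdiff(unique(tab$query_id), read_ids)
    if (length(unknown)) {
      warning(length(unknown), " ", toupper(nm),
              " hit(s) for read ids not in the library were ignored")
      tab <- tab[!tab$query_id %in% unknown, , drop = FALSE]
      if (nm == "ssu") ssu_table <- tab else lsu_table <- tab
    }
  }
  ssu_table <- ssu_table[ssu_table$evalue <= evalue_cutoff, , drop = FALSE]
  lsu_table <- lsu_table[lsu_table$evalue <= evalue_cutoff, , drop = FALSE]
  bs <- .best_per_query(ssu_table)
  bl <- .best_per_query(lsu_table)

  label <- rep("NONRRNA", length(read_ids))
  best_subject <- rep(NA_character_, length(read_ids))
  bitscore <- rep(NA_real_, length(read_ids))
  evalue <- rep(NA_real_, length(read_ids))

  is_ssu <- match(read_ids, bs$query_id)
  is_lsu <- match(read_ids, bl$query_id)
  for (i in seq_along(read_ids)) {
    si <- is_ssu[i]; li <- is_lsu[i]
    if (is.na(si) && is.na(li)) next
    if (!is.na(si) && (is.na(li) || bs$bitscore[si] >= bl$bitscore[li])) {
      label[i] <- "SSU"
      best_subject[i] <- bs$subject_id[si]
      bitscore[i] <- bs$bitscore[si]
      evalue[i] <- bs$evalue[si]
    } else {
      label[i] <- "LSU"
      best_subject[i] <- bl$subject_id[li]
      bitscore[i] <- bl$bitscore[li]
      evalue[i] <- bl$evalue[li]
    }
  }
  classes <- data.frame(read_id = read_ids, label = label,
                        best_subject = best_subject, bitscore = bitscore,
                        evalue = evalue, stringsAsFactors = FALSE)
  nonrrna <- read_ids[label == "NONRRNA"]
  structure(list(classes = classes,
                 ssu_ids = read_ids[label == "SSU"],
                 lsu_ids = read_ids[label == "LSU"],
                 nonrrna_ids = nonrrna,
                 mrna_ids = setdiff(nonrrna, smallrna_ids)),
            class = "rrna_partition")
}

#' @export
print.rrna_partition <- function(x, ...) {
  cat("rrna_partition:", nrow(x$classes), "reads\n")
  cat(sprintf("  SSU rRNA: %d\n  LSU rRNA: %d\n  non-rRNA: %d (putative mRNA: %d)\n",
              length(x$ssu_ids), length(x$lsu_ids),
              length(x$nonrrna_ids), length(x$mrna_ids)))
  invisible(x)
}
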