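.lineage_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' Parses a two-column TSV of reference id and semicolon-delimited
#' lineage (`domain;phylum;class;order;family;genus`); shorter lineages
#' are padded with `NA` at the lower ranks.
#'
#' @param path Path to the TSV file (no header).
#' @return Data frame with columns `id` plus one column per rank.
#' @export
read_taxonomy <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "lineage"), quote = "")
  parts <- strsplit(raw$lineage, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(.lineage_ranks)
    p
  }, character(length(.lineage_ranks))))
  colnames(mat) <- .lineage_ranks
  cbind(data.frame(id = raw$id, stringsAsFactors = FALSE),
        as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Bundle reference sequences with their taxonomy
#'
#' @param sequences Named character vector of reference nucleotide
#'   sequences.
#' @param taxonomy Data frame with a column `id` and one column per
#'   lineage rank (see [read_taxonomy]); every sequence id must have a
#'   taxonomy row.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(sequences, taxonomy) {
  stopifnot(!is.null(names(sequences)), is.data.frame(taxonomy),
            "id" %in% names(taxonomy))
  miss <- setdiff(names(sequences), taxonomy$id)
  if (length(miss))
    stop("no taxonomy entry for reference(s): ",
         paste(head(miss, 5), collapse = ", "))
  structure(list(sequences = sequences, taxonomy = taxonomy),
            class = "reference_set")
}

# Global pairwise identity = matches / alignment length (incl. gaps).
.global_identity <- function(a, b) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 2)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Dereplicate reference sequences by greedy identity clustering
#'
#' Greedy input-order centroid clustering: each sequence joins the first
#' existing centroid with global alignment identity (matches over
#' alignment length) at or above the cutoff, otherwise it founds a new
#' centroid. With the default 0.99 cutoff this collapses near-identical
#' references into a non-redundant set.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param identity Identity cutoff as a fraction (default 0.99).
#' @return A list with `centroids` (named character vector) and
#'   `members` (named character vector mapping every input id to its
#'   centroid id).
#' @export
dereplicate_references <- function(seqs, identity = 0.99) {
  stopifnot(!is.null(names(seqs)), identity > 0, identity <= 1)
  cent_ids <- character(0)
  members <- setNames(character(length(seqs)), names(seqs))
  for (i in seq_along(seqs)) {
    assigned <- NA_character_
    for (cid in cent_ids) {
      if (.global_identity(seqs[[i]], seqs[[cid]]) >= identity) {
        assigned <- cid
        break
      }
    }
    if (is.na(assigned)) {
      assigned <- names(seqs)[i]
      cent_ids <- c(cent_ids, assigned)
    }
    members[i] <- assigned
  }
  list(centroids = seqs[cent_ids], members = members)
}

#' Closed-reference OTU assignment of SSU rRNA reads
#'
#' Each read is assigned to the reference of its best hit (chosen as in
#' [best_hit]) if the best hit's percent identity meets the cutoff, and
#' is `UNMAPPED` otherwise. Reads mapping to the same reference sequence
#' form one OTU, represented by that reference.
#'
#' @param tag_hits Hit table of SSU rRNA reads against the reference set.
#' @param identity_cutoff Minimum percent identity of the best hit
#'   (default 95, i.e. at most 5% sequence divergence).
#' @param tag_ids Optional character vector of all read ids (the tag
#'   universe); reads without hits are reported as `UNMAPPED`. Defaults
#'   to the queries present in `tag_hits`.
#' @return Data frame `tag_id`, `otu_id` (reference id or `"UNMAPPED"`),
#'   `pct_identity`, `bitscore`.
#' @export
assign_otus <- function(tag_hits, identity_cutoff = 95,
                        tag_ids = unique(tag_hits$query_id)) {
  tag_hits <- .validate_hits(tag_hits)
  tag_ids <- as.character(tag_ids)
  best <- .best_per_query(tag_hits)
  m <- match(tag_ids, best$query_id)
  otu <- ifelse(!is.na(m) & best$pct_identity[m] >= identity_cutoff,
                best$subject_id[m], "UNMAPPED")
  data.frame(tag_id = tag_ids,
             otu_id = otu,
             pct_identity = best$pct_identity[m],
             bitscore = best$bitscore[m],
             stringsAsFactors = FALSE)
}

#' Mapping efficiency across identity cutoffs
#'
#' Fraction of reads whose best hit meets each percent-identity cutoff.
#' The curve is non-increasing in the cutoff.
#'
#' @inheritParams assign_otus
#' @param cutoffs Numeric vector of percent-identity cutoffs.
#' @return Named numeric vector of mapped fractions, one per cutoff.
#' @export
mapping_efficiency <- function(tag_hits, cutoffs = c(95, 90, 85),
                               tag_ids = unique(tag_hits$query_id)) {
  tag_hits <- .validate_hits(tag_hits)
  tag_ids <- as.character(tag_ids)
  if (length(tag_ids) == 0) stop("mapping_efficiency: empty tag set")
  best <- .best_per_query(tag_hits)
  best <- best[best$query_id %in% tag_ids, , drop = FALSE]
  eff <- vapply(cutoffs,
                function(co) sum(best$pct_identity >= co) / length(tag_ids),
                numeric(1))
  setNames(eff, as.character(cutoffs))
}

#' Taxon abundance table from an OTU assignment
#'
#' Aggregates mapped reads by the taxon of their OTU's reference at the
#' requested lineage rank. Unmapped reads stay in the denominator and
#' are reported as a `novel` bucket, so relative abundances are
#' fractions of all SSU rRNA reads and sum to 1.
#'
#' @param assignment Data frame from [assign_otus].
#' @param refset A [reference_set].
#' @param rank Lineage rank to aggregate at (one of `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`).
#' @return Data frame of class `abundance_table`: `taxon`, `count`,
#'   `fraction`, with attribute `rank`.
#' @export
abundance_table <- function(assignment, refset, rank = "phylum") {
  stopifnot(inherits(refset, "reference_set"))
  if (!rank %in% names(refset$taxonomy))
    stop("unknown taxonomic rank: ", rank)
  mapped <- assignment$otu_id != "UNMAPPED"
  bad <- setdiff(assignment$otu_id[mapped], refset$taxonomy$id)
  if (length(bad))
    stop("assignment references unknown reference id(s): ",
         paste(head(bad, 5), collapse = ", "))
  taxon <- rep("novel", nrow(assignment))
  taxon[mapped] <- refset$taxonomy[[rank]][
    match(assignment$otu_id[mapped], refset$taxonomy$id)]
  counts <- table(taxon)
  out <- data.frame(taxon = names(counts),
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / nrow(assignment),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rank") <- rank
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Identify dominant taxonomic groups across timepoints
#'
#' A taxon is dominant if its relative abundance exceeds `persist_frac`
#' at every timepoint, or if its abundance increases by at least a factor
#' of `fold` from the first to the last timepoint (a taxon absent at the
#' first timepoint but present at the last also satisfies the
#' fold-change branch). The rule is evaluated at the lowest rank at
#' which a taxon clears it: if a lineage qualifies at several nested
#' ranks, supply its lowest resolvable label. With a single timepoint
#' the fold-change branch is disabled with a warning.
#'
#' Non-dominant order-level taxa whose abundance exceeds `order_cap` at
#' any timepoint are reported in the `order_cap_violations` attribute;
#' an empty set there supports the claim that no other group exceeds the
#' cap at order level.
#'
#' @param abund Long-format data frame with columns `timepoint`,
#'   `rank`, `taxon`, `fraction` (one zone). Absent taxon-timepoint
#'   combinations count as abundance 0.
#' @param persist_frac Persistent-abundance threshold (default 0.05).
#' @param order_cap Order-level cap for non-dominant groups (default 0.03).
#' @param fold Fold-change threshold between first and last timepoint
#'   (default 2).
#' @return Data frame `taxon`, `rank`, `criterion` (`"persistent"` or
#'   `"fold_change"`), with attribute `order_cap_violations`.
#' @export
identify_dominant_groups <- function(abund, persist_frac = 0.05,
                                     order_cap = 0.03, fold = 2) {
  stopifnot(all(c("timepoint", "rank", "taxon", "fraction") %in% names(abund)))
  tps <- sort(unique(abund$timepoint))
  use_fold <- length(tps) > 1
  if (!use_fold)
    warning("single timepoint: fold-change branch disabled")
  rank_order <- rev(.lineage_ranks)  # genus first = lowest rank
  keys <- unique(abund[, c("taxon", "rank")])
  keys <- keys[order(match(keys$rank, rank_order)), , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(keys))) {
    tx <- keys$taxon[i]; rk <- keys$rank[i]
    sub <- abund[abund$taxon == tx & abund$rank == rk, , drop = FALSE]
    frac <- setNames(rep(0, length(tps)), tps)
    frac[as.character(sub$timepoint)] <- sub$fraction
    crit <- NA_character_
    if (all(frac > persist_frac)) {
      crit <- "persistent"
    } else if (use_fold) {
      f0 <- frac[[1]]; f1 <- frac[[length(frac)]]
      fc <- if (f0 == 0) ifelse(f1 > 0, Inf, 1) else f1 / f0
      if (fc >= fold) crit <- "fold_change"
    }
    if (!is.na(crit))
      res[[length(res) + 1]] <- data.frame(taxon = tx, rank = rk,
                                           criterion = crit,
                                           stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(taxon = character(0), rank = character(0),
                         criterion = character(0), stringsAsFactors = FALSE)
  ord <- abund[abund$rank == "order", , drop = FALSE]
  viol <- unique(ord$taxon[ord$fraction > order_cap])
  attr(out, "order_cap_violations") <- setdiff(viol, out$taxon)
  out
}
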