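#' Define a panel of taxon-specific protein databases
#'
#' A panel describes the K taxon-specific protein databases derived for
#' the dominant groups of one zone: a unique name and a domain flag per
#' database, with an optional protein count as metadata.
#'
#' @param name Character vector of unique taxon labels (K >= 2).
#' @param domain_flag Character vector, each one of `"bacterial"`,
#'   `"archaeal"`, `"eukaryotic"`.
#' @param n_proteins Optional integer vector of database sizes.
#' @return Data frame of class `taxon_panel`.
#' @export
taxon_panel <- function(name, domain_flag, n_proteins = NA_integer_) {
  name <- as.character(name)
  domain_flag <- as.character(domain_flag)
  if (length(name) < 2) stop("a panel needs at least two databases")
  if (anyDuplicated(name)) stop("panel database names must be unique")
  if (length(domain_flag) != length(name))
    stop("domain_flag must match name in length")
  if (!all(domain_flag %in% c("bacterial", "archaeal", "eukaryotic")))
    stop("domain_flag must be bacterial, archaeal or eukaryotic")
  out <- data.frame(name = name, domain_flag = domain_flag,
                    n_proteins = as.integer(n_proteins),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxon_panel", "data.frame")
  out
}

#' Build per-read homolog presence/absence profiles
#'
#' For every mRNA read, records in which of the K taxon-specific
#' databases it has at least one homology hit with bit score at or above
#' the cutoff (inclusive, default 50), together with a flag for whether
#' the read has a homolog anywhere in the global protein database
#' (supplied as a precomputed id list).
#'
#' @param hit_tables Named list of K hit tables, one per taxon-specific
#'   database; names must be unique and match the panel.
#' @param universe Character vector of all mRNA read ids. Reads with no
#'   hit anywhere still get an (all-`FALSE`) profile. Queries found in
#'   the tables but absent from `universe` are added to it.
#' @param bitscore_cutoff Minimum bit score for a hit to count (default 50).
#' @param nr_ids Character vector of read ids with a homolog in the
#'   global protein database; if `NULL`, all reads are treated as having
#'   none (with a warning), so profile-less reads classify as novel.
#' @return An object of class `hit_profiles`: list with `tag_id`,
#'   logical `presence` matrix (reads x databases) and logical `nr_hit`.
#' @export
build_hit_profiles <- function(hit_tables, universe = NULL,
                               bitscore_cutoff = 50, nr_ids = NULL) {
  if (is.null(names(hit_tables)) || any(!nzchar(names(hit_tables))))
    stop("hit_tables must be a named list")
  if (anyDuplicated(names(hit_tables)))
    stop("duplicate database names in hit_tables")
  hit_tables <- lapply(hit_tables, .validate_hits)
  all_queries <- unique(unlist(lapply(hit_tables, function(h) h$query_id),
                               use.names = FALSE))
  tag_id <- union(as.character(universe %||% character(0)), all_queries)
  presence <- vapply(hit_tables, function(h) {
    passing <- unique(h$query_id[h$bitscore >= bitscore_cutoff])
    tag_id %in% passing
  }, logical(length(tag_id)))
  if (length(tag_id) == 1)
    presence <- matrix(presence, nrow = 1,
                       dimnames = list(NULL, names(hit_tables)))
  rownames(presence) <- tag_id
  if (is.null(nr_ids)) {
    warning("no nr-hit id list supplied; treating all profiles as lacking ",
            "a global-database homolog")
    nr_ids <- character(0)
  }
  structure(list(tag_id = tag_id,
                 presence = presence,
                 nr_hit = setNames(tag_id %in% nr_ids, tag_id)),
            class = "hit_profiles")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one mRNA read from its homolog distribution
#'
#' Hierarchical rule over the presence/absence of homologs across the
#' panel: a read shared by all K databases, or at least by all
#' bacterial-flagged ones, is a core transcript (sequence divergence
#' across the three domains of life can hide true homologs, hence the
#' bacterial relaxation). Otherwise a read present in exactly one
#' database is taxon-specific to it, and one present in two or more is a
#' non-core shared transcript. A read absent from every database derives
#' from the minor (non-dominant) groups if it has a homolog in the
#' global protein database, and is novel if it has none.
#'
#' @param presence Logical vector of length K (homolog present per
#'   panel database, in panel order).
#' @param panel A [taxon_panel] of length K.
#' @param nr_hit Logical: homolog anywhere in the global protein database.
#' @return A list with `label` (one of `"CORE"`, `"NONCORE_SHARED"`,
#'   `"TAXON_SPECIFIC"`, `"MINOR"`, `"NOVEL"`) and `taxon` (the taxon
#'   name for taxon-specific reads, otherwise `NA`).
#' @export
classify_tag <- function(presence, panel, nr_hit = FALSE) {
  stopifnot(inherits(panel, "taxon_panel"))
  if (length(presence) != nrow(panel))
    stop("profile length does not match panel size")
  presence <- as.logical(presence)
  bact <- panel$domain_flag == "bacterial"
  if (all(presence) || (any(bact) && all(presence[bact])))
    return(list(label = "CORE", taxon = NA_character_))
  k <- sum(presence)
  if (k == 1)
    return(list(label = "TAXON_SPECIFIC", taxon = panel$name[presence]))
  if (k >= 2)
    return(list(label = "NONCORE_SHARED", taxon = NA_character_))
  list(label = if (isTRUE(nr_hit)) "MINOR" else "NOVEL",
       taxon = NA_character_)
}

#' Partition mRNA reads into core, non-core and taxon-specific sets
#'
#' Applies [classify_tag] to every profile and tallies the homolog
#' distribution: per-read labels, the count of reads in every non-empty
#' presence signature (the cells of a K-set Venn diagram), and summary
#' fractions — the share of annotated reads derived from the dominant
#' groups, and core / non-core / taxon-specific shares of those
#' dominant-group-derived reads.
#'
#' @param profiles A [build_hit_profiles] result; its presence columns
#'   must match the panel names (order is reconciled by name).
#' @param panel A [taxon_panel].
#' @return Object of class `partition_result`: `assignments` (data frame
#'   `tag_id`, `label`, `specific_taxon`, `signature`), `venn` (data
#'   frame `signature`, `count` over signatures with at least one
#'   presence), `summary` (named list of counts and fractions), `panel`.
#' @export
partition_mrna <- function(profiles, panel) {
  stopifnot(inherits(profiles, "hit_profiles"), inherits(panel, "taxon_panel"))
  if (!setequal(colnames(profiles$presence), panel$name))
    stop("profile databases do not match panel names")
  pres <- profiles$presence[, panel$name, drop = FALSE]
  k_hits <- rowSums(pres)
  K <- nrow(panel)
  bact <- panel$domain_flag == "bacterial"
  n_bact <- sum(bact)
  core <- k_hits == K
  if (n_bact > 0)
    core <- core | rowSums(pres[, bact, drop = FALSE]) == n_bact

  label <- character(length(profiles$tag_id))
  label[core] <- "CORE"
  label[!core & k_hits == 1] <- "TAXON_SPECIFIC"
  label[!core & k_hits >= 2] <- "NONCORE_SHARED"
  zero <- k_hits == 0
  label[zero & profiles$nr_hit] <- "MINOR"
  label[zero & !profiles$nr_hit] <- "NOVEL"

  specific <- rep(NA_character_, length(label))
  is_spec <- label == "TAXON_SPECIFIC"
  if (any(is_spec))
    specific[is_spec] <-
      panel$name[max.col(pres[is_spec, , drop = FALSE] * 1L)]

  signature <- apply(pres, 1, function(p) paste(as.integer(p), collapse = ""))
  assignments <- data.frame(tag_id = profiles$tag_id, label = label,
                            specific_taxon = specific,
                            signature = signature,
                            stringsAsFactors = FALSE)
  venn_tab <- table(signature[k_hits > 0])
  venn <- data.frame(signature = names(venn_tab),
                     count = as.integer(venn_tab),
                     stringsAsFactors = FALSE)

  n_total <- length(label)
  n_novel <- sum(label == "NOVEL")
  n_annotated <- n_total - n_novel
  n_dominant <- sum(k_hits > 0)
  spec_counts <- setNames(integer(K), panel$name)
  tab <- table(specific[is_spec])
  spec_counts[names(tab)] <- as.integer(tab)
  summary <- list(
    n_total = n_total,
    n_novel = n_novel,
    n_annotated = n_annotated,
    n_dominant_derived = n_dominant,
    n_minor = sum(label == "MINOR"),
    n_core = sum(label == "CORE"),
    n_noncore_shared = sum(label == "NONCORE_SHARED"),
    n_taxon_specific = sum(is_spec),
    taxon_specific_counts = spec_counts,
    dominant_derived_fraction =
      if (n_annotated > 0) n_dominant / n_annotated else NA_real_,
    core_fraction = if (n_dominant > 0) sum(core) / n_dominant else NA_real_,
    noncore_fraction =
      if (n_dominant > 0) (n_dominant - sum(core)) / n_dominant else NA_real_)
  structure(list(assignments = assignments, venn = venn,
                 summary = summary, panel = panel),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  s <- x$summary
  cat("partition_result over", s$n_total, "mRNA reads,",
      nrow(x$panel), "taxon databases\n")
  cat(sprintf("  novel: %d | minor: %d | dominant-derived: %d (%.1f%% of annotated)\n",
              s$n_novel, s$n_minor, s$n_dominant_derived,
              100 * s$dominant_derived_fraction))
  cat(sprintf("  core: %d (%.1f%%) | non-core shared: %d | taxon-specific: %d\n",
              s$n_core, 100 * s$core_fraction, s$n_noncore_shared,
              s$n_taxon_specific))
  invisible(x)
}

#' Reads shared exclusively by a subset of taxa
#'
#' Returns the read ids whose presence signature is exactly the given
#' subset of panel databases: homologs in every named taxon and in no
#' other. With a single taxon this equals that taxon's taxon-specific
#' set; with the full panel it is the all-present Venn cell.
#'
#' @param profiles A [build_hit_profiles] result.
#' @param taxa_subset Character vector of panel database names.
#' @return Character vector of read ids.
#' @export
shared_by <- function(profiles, taxa_subset) {
  stopifnot(inherits(profiles, "hit_profiles"))
  dbs <- colnames(profiles$presence)
  unknown <- setdiff(taxa_subset, dbs)
  if (length(unknown))
    stop("unknown taxon name(s): ", paste(unknown, collapse = ", "))
  want <- dbs %in% taxa_subset
  hit <- apply(profiles$presence, 1, function(p) all(p == want))
  profiles$tag_id[hit]
}
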