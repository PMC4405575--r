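#' Configuration for the synthetic metatranscriptome generator
#'
#' Bundles every knob of the generator. The defaults emulate the oxic
#' surface layer of a flooded paddy-soil microcosm sequenced on a
#' 454-style platform: read lengths around 420 bp, high base qualities
#' decaying towards the 3' end, a five-database panel (Cyanobacteria,
#' Fungi, Xanthomonadales, Myxococcales, Methylococcales, with Fungi the
#' single eukaryotic member), an SSU-heavy total-RNA mixture, and a
#' partition mixture whose expectations reproduce the oxic-zone headline
#' shares (77.2% of annotated mRNA reads derived from the dominant
#' groups, 38.5% of those core). All fractions are expectations; planted
#' QC violations are disjoint (one criterion per bad read) unless
#' `overlap = TRUE`, which additionally plants reads violating both the
#' length and mean-quality criteria to exercise first-failure
#' attribution.
#'
#' @param seed Integer seed fixing every emitted byte.
#' @param n_reads Total number of reads to simulate.
#' @param len_mean,len_sd,len_min,len_max Length model of clean reads
#'   (normal, truncated to `[len_min, len_max]`), in bases.
#' @param qual_mean,qual_sd,qual_decay Per-base Phred model of clean
#'   reads: mean, s.d., and linear 3'-decay per base; clean reads are
#'   clamped to `[21, 40]` so they always pass the default QC filters.
#' @param tail_frac Fraction of clean reads receiving a low-quality
#'   (Phred 0-9) 3' tail of `tail_len[1]`-`tail_len[2]` bases, exercising
#'   the trimmer without changing any filter outcome.
#' @param tail_len Length range of planted 3' tails.
#' @param frac_short,frac_lowq,frac_highn,frac_lowc,frac_dup,frac_rc_dup
#'   Planted violation rates: too-short reads, low-mean-quality reads,
#'   reads with >1% N, low-complexity (homopolymer/dinucleotide-repeat)
#'   reads, exact duplicates, reverse-complement duplicates.
#' @param overlap If `TRUE`, also plant reads that are both short and
#'   low-quality (attributed to the length filter, the first in order).
#' @param rrna_mix Named fractions (`SSU`, `LSU`, `NONRRNA`) of the
#'   true read classes among kept reads; must sum to 1.
#' @param smallrna_frac Fraction of true non-rRNA reads flagged as
#'   small-RNA-derived.
#' @param decoy_rate Rate of harmless decoy hits: cross-database rRNA
#'   hits at strictly lower bit score, above-cutoff e-value hits for
#'   non-rRNA reads, and sub-cutoff (bit score < 50) panel hits for
#'   absent profile cells.
#' @param composition Named fractions of the true community composition
#'   (taxon labels used at phylum rank in the synthetic taxonomy); must
#'   sum to 1.
#' @param identity_mix Fractions of SSU reads whose best-hit identity
#'   falls in `[95,100]`, `[90,95)`, `[85,90)` and below 85; must sum
#'   to 1. The default leaves 20% unmapped at the 95% cutoff and 2% at
#'   the 85% cutoff.
#' @param refs_per_taxon,ref_len Reference sequences simulated per taxon
#'   and their length in bases.
#' @param panel A [taxon_panel] describing the K databases.
#' @param partition_mix Named fractions (`core_all`, `core_bacterial`,
#'   `specific`, `shared`, `minor`, `novel`) of the planted mRNA
#'   partition mixture; must sum to 1.
#' @param qc A [qc_params] object the planted violations are calibrated
#'   against.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_reads = 10000,
                         len_mean = 420, len_sd = 80,
                         len_min = 250, len_max = 600,
                         qual_mean = 34, qual_sd = 3, qual_decay = 0.01,
                         tail_frac = 0.2, tail_len = c(5, 20),
                         frac_short = 0.03, frac_lowq = 0.03,
                         frac_highn = 0.02, frac_lowc = 0.02,
                         frac_dup = 0.03, frac_rc_dup = 0.02,
                         overlap = FALSE,
                         rrna_mix = c(SSU = 0.4, LSU = 0.1, NONRRNA = 0.5),
                         smallrna_frac = 0.05,
                         decoy_rate = 0.2,
                         composition = c(Cyanobacteria = 0.28,
                                         Fungi = 0.12,
                                         Xanthomonadales = 0.14,
                                         Myxococcales = 0.12,
                                         Methylococcales = 0.09,
                                         Acidobacteria = 0.25),
                         identity_mix = c(a95 = 0.80, a90 = 0.15,
                                          a85 = 0.03, below = 0.02),
                         refs_per_taxon = 4, ref_len = 1200,
                         panel = taxon_panel(
                           name = c("Cyanobacteria", "Fungi",
                                    "Xanthomonadales", "Myxococcales",
                                    "Methylococcales"),
                           domain_flag = c("bacterial", "eukaryotic",
                                           "bacterial", "bacterial",
                                           "bacterial")),
                         partition_mix = c(core_all = 0.15,
                                           core_bacterial = 0.1175,
                                           specific = 0.25,
                                           shared = 0.1773,
                                           minor = 0.2052,
                                           novel = 0.10),
                         qc = qc_params()) {
  stopifnot(n_reads >= 1, len_min <= len_max, len_min >= 10,
            tail_len[1] <= tail_len[2],
            all(c(frac_short, frac_lowq, frac_highn, frac_lowc,
                  frac_dup, frac_rc_dup, tail_frac, smallrna_frac,
                  decoy_rate) >= 0),
            frac_short + frac_lowq + frac_highn + frac_lowc +
              frac_dup + frac_rc_dup < 1)
  if (abs(sum(rrna_mix) - 1) > 1e-9) stop("rrna_mix must sum to 1")
  if (!setequal(names(rrna_mix), c("SSU", "LSU", "NONRRNA")))
    stop("rrna_mix needs components SSU, LSU, NONRRNA")
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  if (abs(sum(identity_mix) - 1) > 1e-9) stop("identity_mix must sum to 1")
  if (!setequal(names(identity_mix), c("a95", "a90", "a85", "below")))
    stop("identity_mix needs components a95, a90, a85, below")
  stopifnot(inherits(panel, "taxon_panel"), inherits(qc, "qc_params"))
  if (abs(sum(partition_mix) - 1) > 1e-9) stop("partition_mix must sum to 1")
  if (!setequal(names(partition_mix),
                c("core_all", "core_bacterial", "specific", "shared",
                  "minor", "novel")))
    stop(paste("partition_mix needs components core_all, core_bacterial,",
               "specific, shared, minor, novel"))
  if (partition_mix[["shared"]] > 0 && nrow(panel) < 3)
    stop("shared (non-core) signatures require a panel of size >= 3: ",
         "every size-2 subset of a 2-database panel is the full panel")
  structure(as.list(environment()), class = "synth_config")
}

.rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.clean_qual <- function(len, cfg) {
  mu <- cfg$qual_mean - cfg$qual_decay * seq_len(len)
  q <- round(stats::rnorm(len, mu, cfg$qual_sd))
  pmin(pmax(q, 21L), 40L)
}

#' Simulate a read library with planted QC violations
#'
#' Generates clean reads that pass every default filter, plus disjoint
#' blocks of reads violating exactly one criterion each: short reads,
#' low-mean-quality reads, reads with 3% N, low-complexity repeats, and
#' exact/reverse-complement duplicates of clean reads. A fraction of the
#' clean reads additionally receives a low-quality 3' tail that the
#' trimmer should remove without affecting any filter. Ground truth
#' records the expected disposition of every read.
#'
#' Draws from the active random stream; seed via [simulate_scenario] or
#' `set.seed()` for reproducibility.
#'
#' @param config A [synth_config].
#' @return List with `reads` (a [read_library]) and `truth` (data frame
#'   `id`, `planted`, `expected_criterion` — `"kept"` or the QC
#'   criterion expected to remove the read — and `tailed`).
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n <- cfg$n_reads
  n_short <- round(cfg$frac_short * n)
  n_lowq <- round(cfg$frac_lowq * n)
  n_highn <- round(cfg$frac_highn * n)
  n_lowc <- round(cfg$frac_lowc * n)
  n_dup <- round(cfg$frac_dup * n)
  n_rc <- round(cfg$frac_rc_dup * n)
  n_overlap <- if (cfg$overlap) round(0.01 * n) else 0L
  n_clean <- n - n_short - n_lowq - n_highn - n_lowc - n_dup - n_rc -
    n_overlap
  if (n_clean < max(1L, n_dup + n_rc))
    stop("infeasible config: not enough clean reads to seed duplicates")

  draw_len <- function(k) {
    pmin(pmax(round(stats::rnorm(k, cfg$len_mean, cfg$len_sd)),
              cfg$len_min), cfg$len_max)
  }

  seqs <- character(n)
  quals <- vector("list", n)
  planted <- character(n)
  expected <- character(n)
  i <- 0L

  # clean block (duplicate sources live here, in front)
  len <- draw_len(n_clean)
  for (j in seq_len(n_clean)) {
    i <- i + 1L
    seqs[i] <- .rand_seq(len[j])
    quals[[i]] <- .clean_qual(len[j], cfg)
    planted[i] <- "clean"
    expected[i] <- "kept"
  }

  # too short after trimming
  if (n_short > 0) {
    len <- sample(seq(50, cfg$qc$min_len - 1), n_short, replace = TRUE)
    for (j in seq_len(n_short)) {
      i <- i + 1L
      seqs[i] <- .rand_seq(len[j])
      quals[[i]] <- .clean_qual(len[j], cfg)
      planted[i] <- "short"
      expected[i] <- "length"
    }
  }

  # mean quality below threshold, no base below the trim threshold
  if (n_lowq > 0) {
    len <- draw_len(n_lowq)
    for (j in seq_len(n_lowq)) {
      i <- i + 1L
      seqs[i] <- .rand_seq(len[j])
      quals[[i]] <- sample(seq(cfg$qc$trim_q, cfg$qc$min_mean_q - 2),
                           len[j], replace = TRUE)
      planted[i] <- "low_mean_q"
      expected[i] <- "mean_quality"
    }
  }

  # ambiguous bases above 1%
  if (n_highn > 0) {
    len <- draw_len(n_highn)
    for (j in seq_len(n_highn)) {
      i <- i + 1L
      s <- strsplit(.rand_seq(len[j]), "", fixed = TRUE)[[1]]
      k_n <- ceiling(0.03 * len[j])
      s[sample(len[j], k_n)] <- "N"
      seqs[i] <- paste(s, collapse = "")
      quals[[i]] <- .clean_qual(len[j], cfg)
      planted[i] <- "high_n"
      expected[i] <- "ambiguity"
    }
  }

  # low-complexity repeats (homopolymers and dinucleotide repeats)
  if (n_lowc > 0) {
    len <- draw_len(n_lowc)
    for (j in seq_len(n_lowc)) {
      i <- i + 1L
      base <- sample(c("A", "C", "G", "T"), 2)
      unit <- if (stats::runif(1) < 0.5) base[1] else paste0(base, collapse = "")
      seqs[i] <- substr(strrep(unit, ceiling(len[j] / nchar(unit))),
                        1, len[j])
      quals[[i]] <- .clean_qual(len[j], cfg)
      planted[i] <- "low_complexity"
      expected[i] <- "complexity"
    }
  }

  # short AND low-quality (first-failure attribution goes to length)
  if (n_overlap > 0) {
    len <- sample(seq(50, cfg$qc$min_len - 1), n_overlap, replace = TRUE)
    for (j in seq_len(n_overlap)) {
      i <- i + 1L
      seqs[i] <- .rand_seq(len[j])
      quals[[i]] <- sample(seq(cfg$qc$trim_q, cfg$qc$min_mean_q - 2),
                           len[j], replace = TRUE)
      planted[i] <- "short_lowq"
      expected[i] <- "length"
    }
  }

  # duplicates of clean reads (sources precede copies in input order)
  dup_src <- if (n_dup + n_rc > 0)
    sample(seq_len(n_clean), n_dup + n_rc, replace = FALSE) else integer(0)
  if (n_dup > 0) {
    for (j in seq_len(n_dup)) {
      i <- i + 1L
      src <- dup_src[j]
      seqs[i] <- seqs[src]
      quals[[i]] <- quals[[src]]
      planted[i] <- "exact_duplicate"
      expected[i] <- "replicate"
    }
  }
  if (n_rc > 0) {
    for (j in seq_len(n_rc)) {
      i <- i + 1L
      src <- dup_src[n_dup + j]
      seqs[i] <- revcomp(seqs[src])
      quals[[i]] <- rev(quals[[src]])
      planted[i] <- "rc_duplicate"
      expected[i] <- "replicate"
    }
  }

  # low-quality 3' tails on clean reads not serving as duplicate sources
  tailed <- rep(FALSE, n)
  tail_candidates <- setdiff(seq_len(n_clean), dup_src)
  n_tail <- round(cfg$tail_frac * length(tail_candidates))
  if (n_tail > 0) {
    pick <- sample(tail_candidates, n_tail)
    for (ix in pick) {
      tl <- sample(seq(cfg$tail_len[1], cfg$tail_len[2]), 1)
      seqs[ix] <- paste0(seqs[ix], .rand_seq(tl))
      quals[[ix]] <- c(quals[[ix]],
                       sample(seq(0, cfg$qc$trim_q - 1), tl, replace = TRUE))
      tailed[ix] <- TRUE
    }
  }

  ids <- sprintf("read%06d", seq_len(n))
  list(reads = read_library(ids, seqs, quals),
       truth = data.frame(id = ids, planted = planted,
                          expected_criterion = expected, tailed = tailed,
                          stringsAsFactors = FALSE))
}

#' Simulate rRNA homology hit tables with known read classes
#'
#' Assigns every kept read a true class from the configured
#' SSU/LSU/non-rRNA mixture and emits hit tables such that the
#' classifier must recover the truth: true rRNA reads receive a passing
#' hit (e-value below 1e-10) in their own table, optionally accompanied
#' by a cross-database decoy at strictly lower bit score; non-rRNA reads
#' receive either no hit or only decoys with above-cutoff e-values. A
#' configured fraction of the non-rRNA reads is flagged as
#' small-RNA-derived.
#'
#' @param config A [synth_config].
#' @param kept_ids Character vector of read ids surviving QC.
#' @return List with `ssu_table`, `lsu_table` (hit tables),
#'   `smallrna_ids`, and `truth` (data frame `id`, `class`, `is_mrna`).
#' @export
simulate_rrna_hits <- function(config, kept_ids) {
  stopifnot(inherits(config, "synth_config"))
  kept_ids <- as.character(kept_ids)
  n <- length(kept_ids)
  cls <- sample(names(config$rrna_mix), n, replace = TRUE,
                prob = config$rrna_mix)
  mk_hit <- function(q, subj, bitscore, evalue) {
    alen <- as.integer(round(stats::runif(length(q), 150, 400)))
    data.frame(query_id = q, subject_id = subj,
               pct_identity = round(stats::runif(length(q), 85, 100), 2),
               aln_len = alen,
               mismatches = as.integer(round(stats::runif(length(q), 0, 20))),
               gap_opens = 0L,
               qstart = 1L, qend = alen,
               sstart = 1L, send = alen,
               evalue = evalue, bitscore = round(bitscore, 1),
               stringsAsFactors = FALSE)
  }
  ssu <- .empty_hits()
  lsu <- .empty_hits()
  for (lab in c("SSU", "LSU")) {
    q <- kept_ids[cls == lab]
    if (!length(q)) next
    bit <- stats::runif(length(q), 200, 500)
    ev <- 10^-stats::runif(length(q), 20, 60)
    own <- mk_hit(q, paste0(lab, "_ref_",
                            sample(200, length(q), replace = TRUE)),
                  bit, ev)
    has_decoy <- stats::runif(length(q)) < config$decoy_rate
    decoy <- mk_hit(q[has_decoy],
                    paste0(ifelse(lab == "SSU", "LSU", "SSU"), "_ref_",
                           sample(200, sum(has_decoy), replace = TRUE)),
                    bit[has_decoy] - stats::runif(sum(has_decoy), 20, 100),
                    10^-stats::runif(sum(has_decoy), 11, 30))
    if (lab == "SSU") {
      ssu <- rbind(ssu, own)
      lsu <- rbind(lsu, decoy)
    } else {
      lsu <- rbind(lsu, own)
      ssu <- rbind(ssu, decoy)
    }
  }
  q <- kept_ids[cls == "NONRRNA"]
  if (length(q)) {
    has_decoy <- stats::runif(length(q)) < config$decoy_rate
    qd <- q[has_decoy]
    if (length(qd)) {
      to_ssu <- stats::runif(length(qd)) < 0.5
      weak <- mk_hit(qd, paste0(ifelse(to_ssu, "SSU", "LSU"), "_ref_",
                                sample(200, length(qd), replace = TRUE)),
                     stats::runif(length(qd), 40, 80),
                     10^-stats::runif(length(qd), 2, 8))
      ssu <- rbind(ssu, weak[to_ssu, , drop = FALSE])
      lsu <- rbind(lsu, weak[!to_ssu, , drop = FALSE])
    }
  }
  nonr <- kept_ids[cls == "NONRRNA"]
  smallrna <- nonr[stats::runif(length(nonr)) < config$smallrna_frac]
  list(ssu_table = ssu, lsu_table = lsu, smallrna_ids = smallrna,
       truth = data.frame(id = kept_ids, class = cls,
                          is_mrna = cls == "NONRRNA" &
                            !kept_ids %in% smallrna,
                          stringsAsFactors = FALSE))
}

# Draw one non-core shared signature: >=2 databases, not the full panel,
# never covering every bacterial member.
.draw_shared_signature <- function(K, bact) {
  repeat {
    size <- sample(2:(K - 1), 1)
    pick <- sort(sample(K, size))
    sig <- seq_len(K) %in% pick
    if (!(sum(bact) > 0 && all(sig[bact]))) return(sig)
  }
}

#' Simulate panel hit tables with a planted partition mixture
#'
#' Draws a partition class for every mRNA read from the configured
#' mixture, converts it to a presence signature over the K
#' taxon-specific databases (core: all present; bacterial-core: exactly
#' the bacterial members; taxon-specific: a single database; shared: a
#' proper subset of size >= 2 never covering all bacterial members;
#' minor/novel: all absent, with and without a global-database homolog),
#' and emits hit tables with bit scores >= 50 for present cells.
#' Absent cells may receive sub-cutoff decoy hits (bit score < 50) at
#' the configured decoy rate.
#'
#' @param config A [synth_config].
#' @param mrna_ids Character vector of putative mRNA read ids.
#' @return List with `hit_tables` (named list of K hit tables),
#'   `nr_ids`, `universe`, and `truth` (data frame `tag_id`, `planted`,
#'   `expected_label`, `specific_taxon`, `signature`).
#' @export
simulate_panel_hits <- function(config, mrna_ids) {
  stopifnot(inherits(config, "synth_config"))
  mrna_ids <- as.character(mrna_ids)
  panel <- config$panel
  K <- nrow(panel)
  bact <- panel$domain_flag == "bacterial"
  if (sum(bact) == 0 && config$partition_mix[["core_bacterial"]] > 0)
    stop("core_bacterial mixture mass requires a bacterial panel member")
  n <- length(mrna_ids)
  planted <- sample(names(config$partition_mix), n, replace = TRUE,
                    prob = config$partition_mix)
  sig <- matrix(FALSE, n, K, dimnames = list(mrna_ids, panel$name))
  spec_taxon <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sig[i, ] <- switch(
      planted[i],
      core_all = rep(TRUE, K),
      core_bacterial = bact,
      specific = {
        t <- sample(K, 1)
        spec_taxon[i] <- panel$name[t]
        seq_len(K) == t
      },
      shared = .draw_shared_signature(K, bact),
      minor = rep(FALSE, K),
      novel = rep(FALSE, K))
  }
  expected <- c(core_all = "CORE", core_bacterial = "CORE",
                specific = "TAXON_SPECIFIC", shared = "NONCORE_SHARED",
                minor = "MINOR", novel = "NOVEL")[planted]

  mk_panel_hit <- function(q, db, bitscore) {
    alen <- as.integer(round(stats::runif(length(q), 30, 130)))
    data.frame(query_id = q,
               subject_id = paste0(db, "_prot_",
                                   sample(5000, length(q), replace = TRUE)),
               pct_identity = round(stats::runif(length(q), 40, 100), 2),
               aln_len = alen,
               mismatches = as.integer(round(stats::runif(length(q), 0, 40))),
               gap_opens = as.integer(round(stats::runif(length(q), 0, 3))),
               qstart = 1L, qend = alen * 3L,
               sstart = 1L, send = alen,
               evalue = 10^-stats::runif(length(q), 5, 40),
               bitscore = round(bitscore, 1),
               stringsAsFactors = FALSE)
  }
  hit_tables <- setNames(vector("list", K), panel$name)
  for (k in seq_len(K)) {
    present <- mrna_ids[sig[, k]]
    tab <- if (length(present))
      mk_panel_hit(present, panel$name[k],
                   stats::runif(length(present), 50, 300))
    else .empty_hits()
    absent <- mrna_ids[!sig[, k]]
    weak <- absent[stats::runif(length(absent)) < config$decoy_rate]
    if (length(weak))
      tab <- rbind(tab, mk_panel_hit(weak, panel$name[k],
                                     stats::runif(length(weak), 20, 49.5)))
    hit_tables[[k]] <- tab
  }
  nr_ids <- mrna_ids[rowSums(sig) > 0 | planted == "minor"]
  sig_str <- apply(sig, 1, function(p) paste(as.integer(p), collapse = ""))
  list(hit_tables = hit_tables, nr_ids = nr_ids, universe = mrna_ids,
       truth = data.frame(tag_id = mrna_ids, planted = planted,
                          expected_label = unname(expected),
                          specific_taxon = spec_taxon,
                          signature = unname(sig_str),
                          stringsAsFactors = FALSE))
}

#' Simulate a reference set, taxonomy and SSU mapping hits
#'
#' Builds reference sequences with planted lineages (the community taxa
#' placed at phylum rank), draws a true taxon for every SSU read from
#' the configured composition, and emits one best hit per read whose
#' percent identity falls in the configured identity stratum, so the
#' fraction of reads mappable at the 95/90/85% cutoffs is controlled.
#'
#' @param config A [synth_config].
#' @param ssu_ids Character vector of SSU rRNA read ids.
#' @return List with `refs` (named character vector), `taxonomy` (data
#'   frame as from [read_taxonomy]), `tag_hits` (hit table), and `truth`
#'   (data frame `tag_id`, `taxon`, `stratum`, `pct_identity`,
#'   `ref_id`).
#' @export
simulate_references_and_taxonomy <- function(config, ssu_ids) {
  stopifnot(inherits(config, "synth_config"))
  ssu_ids <- as.character(ssu_ids)
  taxa <- names(config$composition)
  domain_of <- function(tx) {
    if (tx %in% c("Fungi")) "Eukaryota"
    else if (tx %in% c("Euryarchaeota")) "Archaea"
    else "Bacteria"
  }
  ref_ids <- character(0)
  ref_seqs <- character(0)
  tax_rows <- list()
  for (tx in taxa) {
    ids <- sprintf("%s_ref_%02d", tx, seq_len(config$refs_per_taxon))
    ref_ids <- c(ref_ids, ids)
    ref_seqs <- c(ref_seqs,
                  vapply(ids, function(x) .rand_seq(config$ref_len),
                         character(1)))
    tax_rows[[tx]] <- data.frame(
      id = ids, domain = domain_of(tx), phylum = tx,
      class = paste0(tx, "_class"), order = paste0(tx, "_order"),
      family = paste0(tx, "_family"),
      genus = paste0(tx, "_genus_", seq_along(ids)),
      stringsAsFactors = FALSE)
  }
  refs <- setNames(ref_seqs, ref_ids)
  taxonomy <- do.call(rbind, c(tax_rows, list(make.row.names = FALSE)))

  n <- length(ssu_ids)
  taxon <- sample(taxa, n, replace = TRUE, prob = config$composition)
  stratum <- sample(names(config$identity_mix), n, replace = TRUE,
                    prob = config$identity_mix)
  pct <- numeric(n)
  pct[stratum == "a95"] <- stats::runif(sum(stratum == "a95"), 95, 100)
  pct[stratum == "a90"] <- stats::runif(sum(stratum == "a90"), 90, 94.99)
  pct[stratum == "a85"] <- stats::runif(sum(stratum == "a85"), 85, 89.99)
  pct[stratum == "below"] <- stats::runif(sum(stratum == "below"), 60, 84.9)
  ref_id <- vapply(taxon, function(tx) {
    sprintf("%s_ref_%02d", tx, sample(config$refs_per_taxon, 1))
  }, character(1), USE.NAMES = FALSE)
  alen <- as.integer(round(stats::runif(n, 200, 450)))
  tag_hits <- data.frame(
    query_id = ssu_ids, subject_id = ref_id,
    pct_identity = round(pct, 2), aln_len = alen,
    mismatches = as.integer(round(alen * (100 - pct) / 100)),
    gap_opens = 0L, qstart = 1L, qend = alen,
    sstart = 1L, send = alen,
    evalue = 10^-stats::runif(n, 30, 80),
    bitscore = round(stats::runif(n, 200, 600), 1),
    stringsAsFactors = FALSE)
  list(refs = refs, taxonomy = taxonomy, tag_hits = tag_hits,
       truth = data.frame(tag_id = ssu_ids, taxon = taxon,
                          stratum = stratum,
                          pct_identity = round(pct, 2), ref_id = ref_id,
                          stringsAsFactors = FALSE))
}

#' Simulate a complete metatranscriptome scenario
#'
#' Seeds a single random stream from `config$seed` and runs the whole
#' generator chain in a fixed module order: reads with planted QC
#' violations, rRNA hit tables for the reads expected to survive QC,
#' panel hit tables for the putative mRNA reads, and references plus
#' SSU mapping hits for the SSU reads. Every emitted object is a
#' deterministic function of the seed.
#'
#' @param config A [synth_config].
#' @return An object of class `coretax_scenario`: a list with
#'   `config`, `reads`, `truth_reads`, `ssu_table`, `lsu_table`,
#'   `smallrna_ids`, `truth_rrna`, `panel_hits`, `nr_ids`,
#'   `mrna_universe`, `truth_partition`, `refs`, `taxonomy`,
#'   `tag_hits`, `truth_otu`.
#' @export
simulate_scenario <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  rd <- simulate_reads(config)
  kept_ids <- rd$truth$id[rd$truth$expected_criterion == "kept"]
  rr <- simulate_rrna_hits(config, kept_ids)
  mrna_ids <- rr$truth$id[rr$truth$is_mrna]
  pn <- simulate_panel_hits(config, mrna_ids)
  ssu_ids <- rr$truth$id[rr$truth$class == "SSU"]
  ot <- simulate_references_and_taxonomy(config, ssu_ids)
  structure(list(config = config,
                 reads = rd$reads, truth_reads = rd$truth,
                 ssu_table = rr$ssu_table, lsu_table = rr$lsu_table,
                 smallrna_ids = rr$smallrna_ids, truth_rrna = rr$truth,
                 panel_hits = pn$hit_tables, nr_ids = pn$nr_ids,
                 mrna_universe = pn$universe, truth_partition = pn$truth,
                 refs = ot$refs, taxonomy = ot$taxonomy,
                 tag_hits = ot$tag_hits, truth_otu = ot$truth),
            class = "coretax_scenario")
}

#' Write a simulated scenario to a directory of plain-text files
#'
#' Emits `reads.fastq`, `ssu_hits.tsv`, `lsu_hits.tsv`,
#' `smallrna_ids.txt`, `panel/<db>.tsv` with a `panel.tsv` manifest
#' (`db_name`, `domain_flag`, `hits_path`), `nr_ids.txt`,
#' `mrna_universe.txt`, `refs.fasta`, `taxonomy.tsv`, `tag_hits.tsv`
#' and the ground-truth tables (`truth_*.tsv`). All files round-trip
#' through the package readers.
#'
#' @param scenario A `coretax_scenario` from [simulate_scenario].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "coretax_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "panel"), showWarnings = FALSE)
  write_fastq(scenario$reads, file.path(dir, "reads.fastq"))
  write_hit_table(scenario$ssu_table, file.path(dir, "ssu_hits.tsv"))
  write_hit_table(scenario$lsu_table, file.path(dir, "lsu_hits.tsv"))
  writeLines(scenario$smallrna_ids, file.path(dir, "smallrna_ids.txt"))
  writeLines(scenario$nr_ids, file.path(dir, "nr_ids.txt"))
  writeLines(scenario$mrna_universe, file.path(dir, "mrna_universe.txt"))
  panel <- scenario$config$panel
  manifest <- data.frame(db_name = panel$name,
                         domain_flag = panel$domain_flag,
                         hits_path = file.path("panel",
                                               paste0(panel$name, ".tsv")),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "panel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (db in panel$name)
    write_hit_table(scenario$panel_hits[[db]],
                    file.path(dir, "panel", paste0(db, ".tsv")))
  fa <- Biostrings::DNAStringSet(scenario$refs)
  Biostrings::writeXStringSet(fa, file.path(dir, "refs.fasta"))
  tax <- scenario$taxonomy
  lineage <- apply(tax[, .lineage_ranks], 1, paste, collapse = ";")
  write.table(data.frame(tax$id, lineage),
              file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_hit_table(scenario$tag_hits, file.path(dir, "tag_hits.tsv"))
  for (nm in c("truth_reads", "truth_rrna", "truth_partition", "truth_otu"))
    write.table(scenario[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
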