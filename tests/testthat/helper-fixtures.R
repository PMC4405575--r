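# Small builders shared across the test files.

make_lib <- function(seqs, quals = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("r", seq_len(n))
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(L) rep(30L, L))
  read_library(ids, seqs, quals)
}

make_hit <- function(query = "q1", subject = "s1", pct = 98, alen = 100L,
                     mm = 2L, gaps = 0L, qs = 1L, qe = 100L, ss = 1L,
                     se = 100L, evalue = 1e-30, bitscore = 200) {
  data.frame(query_id = query, subject_id = subject, pct_identity = pct,
             aln_len = as.integer(alen), mismatches = as.integer(mm),
             gap_opens = as.integer(gaps), qstart = as.integer(qs),
             qend = as.integer(qe), sstart = as.integer(ss),
             send = as.integer(se), evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

no_hits <- function() make_hit()[0, ]

# Sequence of length L whose overlapping triplets are all distinct:
# concatenation of distinct 4-mers over disjoint alphabets would still
# share triplets, so build from a de-Bruijn-style enumeration instead.
all_distinct_triplet_seq <- function() {
  # enumerate 4^3 = 64 distinct triplets and chain them via overlaps is
  # overkill; a short sequence suffices for the boundary check.
  "ACGTAGCTTGCA"  # verified distinct triplets in the test that uses it
}

# Independent brute-force classifier, written directly from the
# classification rules: shared by all dominant groups or at least all
# bacterial members = core; unique to one group = taxon-specific; in two
# or more = non-core shared; in none = minor with a global-database
# homolog, novel without.
naive_classify <- function(sig, flags, nr) {
  bact_all <- sum(flags == "bacterial") > 0 &&
    all(sig[flags == "bacterial"])
  if (all(sig) || bact_all) return("CORE")
  n_in <- sum(sig)
  if (n_in == 1) return("TAXON_SPECIFIC")
  if (n_in >= 2) return("NONCORE_SHARED")
  if (nr) "MINOR" else "NOVEL"
}

oxic_panel <- function() {
  taxon_panel(
    name = c("Cyanobacteria", "Fungi", "Xanthomonadales",
             "Myxococcales", "Methylococcales"),
    domain_flag = c("bacterial", "eukaryotic", "bacterial",
                    "bacterial", "bacterial"))
}
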