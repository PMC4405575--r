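test_that("dereplication collapses identical and near-identical sequences", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  res <- dereplicate_references(c(a = s, b = s))
  expect_length(res$centroids, 1)
  expect_equal(unname(res$members), c("a", "a"))

  # two sequences at ~90% identity stay separate at the 0.99 cutoff
  mut <- strsplit(s, "")[[1]]
  pos <- sample(400, 40)
  mut[pos] <- vapply(mut[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  s90 <- paste(mut, collapse = "")
  res <- dereplicate_references(c(a = s, b = s90))
  expect_length(res$centroids, 2)
})

test_that("dereplication recovers planted cluster structure", {
  set.seed(37)
  bases <- c("A", "C", "G", "T")
  centroids <- vapply(1:4, function(i)
    paste(sample(bases, 500, TRUE), collapse = ""), character(1))
  seqs <- character(0)
  for (i in seq_along(centroids)) {
    seqs[paste0("c", i)] <- centroids[i]
    for (j in 1:2) {  # copies with 2 substitutions (0.4% divergence)
      m <- strsplit(centroids[i], "")[[1]]
      pos <- sample(500, 2)
      m[pos] <- vapply(m[pos], function(b) sample(setdiff(bases, b), 1),
                       character(1))
      seqs[paste0("c", i, "m", j)] <- paste(m, collapse = "")
    }
  }
  res <- dereplicate_references(seqs, identity = 0.99)
  expect_length(res$centroids, 4)
  expect_equal(names(res$centroids), paste0("c", 1:4))
  # no pair of centroids at or above the cutoff
  cids <- names(res$centroids)
  for (i in seq_along(cids)[-1]) {
    for (j in seq_len(i - 1)) {
      aln <- Biostrings::pairwiseAlignment(
        res$centroids[[cids[i]]], res$centroids[[cids[j]]], type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
        gapOpening = 5, gapExtension = 2)
      expect_lt(Biostrings::pid(aln, type = "PID1") / 100, 0.99)
    }
  }
})

test_that("OTU assignment respects the identity cutoff and best-hit rule", {
  hits <- rbind(make_hit("t1", "refA", pct = 96),
                make_hit("t2", "refB", pct = 92),
                make_hit("t3", "refC", pct = 80))
  a95 <- assign_otus(hits, 95)
  expect_equal(a95$otu_id[a95$tag_id == "t1"], "refA")
  expect_equal(a95$otu_id[a95$tag_id == "t2"], "UNMAPPED")
  a90 <- assign_otus(hits, 90)
  expect_equal(a90$otu_id[a90$tag_id == "t2"], "refB")

  # a tag with no hits is UNMAPPED when the universe says it exists
  a <- assign_otus(hits, 95, tag_ids = c("t1", "t2", "t3", "t4"))
  expect_equal(a$otu_id[a$tag_id == "t4"], "UNMAPPED")

  # the identity used is that of the best-bit-score hit, not the best identity
  hits2 <- rbind(make_hit("t1", "refHi", pct = 99, bitscore = 100),
                 make_hit("t1", "refLo", pct = 91, bitscore = 400))
  a2 <- assign_otus(hits2, 95)
  expect_equal(a2$otu_id, "UNMAPPED")
})

test_that("mapping efficiency matches hand counts and is non-increasing", {
  hits <- rbind(make_hit("t1", "r1", pct = 96),
                make_hit("t2", "r2", pct = 92),
                make_hit("t3", "r3", pct = 80))
  eff <- mapping_efficiency(hits, c(95, 90, 85))
  expect_equal(unname(eff), c(1 / 3, 2 / 3, 2 / 3))

  all100 <- rbind(make_hit("t1", "r1", pct = 100),
                  make_hit("t2", "r2", pct = 100))
  expect_equal(unname(mapping_efficiency(all100, c(95, 90, 85))),
               c(1, 1, 1))

  expect_error(mapping_efficiency(no_hits()), "empty")

  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(k)
      make_hit(paste0("t", k), "r", pct = runif(1, 60, 100))))
    eff <- mapping_efficiency(h, c(95, 90, 85))
    expect_true(all(diff(unname(eff)) >= 0))  # decreasing cutoff, rising eff
  }
})

test_that("abundance tables keep unmapped tags in the denominator", {
  refs <- c(rA = "ACGT", rB = "ACGG")
  tax <- data.frame(id = c("rA", "rB"),
                    domain = "Bacteria",
                    phylum = c("PhyA", "PhyB"),
                    class = NA, order = NA, family = NA, genus = NA,
                    stringsAsFactors = FALSE)
  refset <- reference_set(refs, tax)
  asn <- data.frame(tag_id = paste0("t", 1:5),
                    otu_id = c("rA", "rA", "rA", "rB", "UNMAPPED"),
                    stringsAsFactors = FALSE)
  ab <- abundance_table(asn, refset, "phylum")
  expect_equal(sum(ab$fraction), 1)
  expect_equal(ab$fraction[ab$taxon == "PhyA"], 0.6)
  expect_equal(ab$fraction[ab$taxon == "novel"], 0.2)
  expect_error(abundance_table(asn, refset, "species"), "rank")

  # everything in one phylum
  asn1 <- data.frame(tag_id = "t1", otu_id = "rA", stringsAsFactors = FALSE)
  ab1 <- abundance_table(asn1, refset, "phylum")
  expect_equal(ab1$fraction, 1)
})

test_that("dominant groups: persistence, order cap, and fold-change branches", {
  abund <- data.frame(
    timepoint = rep(c(25, 45, 90), times = 3),
    rank = c(rep("phylum", 3), rep("order", 3), rep("order", 3)),
    taxon = c(rep("Cyanobacteria", 3), rep("Quietales", 3),
              rep("Risingales", 3)),
    fraction = c(0.06, 0.07, 0.08,   # persistent > 5%
                 0.02, 0.02, 0.02,   # never above caps
                 0.01, 0.02, 0.05),  # 5-fold increase
    stringsAsFactors = FALSE)
  dom <- identify_dominant_groups(abund)
  expect_setequal(dom$taxon, c("Cyanobacteria", "Risingales"))
  expect_equal(dom$criterion[dom$taxon == "Cyanobacteria"], "persistent")
  expect_equal(dom$criterion[dom$taxon == "Risingales"], "fold_change")
  expect_length(attr(dom, "order_cap_violations"), 0)

  # non-dominant order-level taxa above the cap are reported (with the
  # fold threshold raised, Risingales loses dominance and peaks at 5%)
  abund$fraction[abund$taxon == "Quietales"] <- c(0.04, 0.04, 0.04)
  dom2 <- identify_dominant_groups(abund, fold = 10)
  expect_setequal(attr(dom2, "order_cap_violations"),
                  c("Quietales", "Risingales"))

  # single timepoint disables the fold-change branch
  one <- abund[abund$timepoint == 25, ]
  expect_warning(dom3 <- identify_dominant_groups(one), "single timepoint")
  expect_equal(dom3$taxon, "Cyanobacteria")
})
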