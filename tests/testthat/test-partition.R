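test_that("hit profiles honour the inclusive bit-score cutoff", {
  tabs <- list(dbA = make_hit("t1", "pA", bitscore = 49),
               dbB = make_hit("t1", "pB", bitscore = 51))
  prof <- build_hit_profiles(tabs, universe = "t1", nr_ids = "t1")
  expect_equal(unname(prof$presence["t1", ]), c(FALSE, TRUE))

  # exactly at the cutoff counts as present
  tabs <- list(dbA = make_hit("t1", "pA", bitscore = 50),
               dbB = no_hits())
  prof <- build_hit_profiles(tabs, universe = "t1", nr_ids = "t1")
  expect_equal(unname(prof$presence["t1", ]), c(TRUE, FALSE))

  # a tag absent from all tables still gets an all-false profile
  prof <- build_hit_profiles(tabs, universe = c("t1", "t2"),
                             nr_ids = character(0))
  expect_equal(unname(prof$presence["t2", ]), c(FALSE, FALSE))

  expect_error(
    build_hit_profiles(setNames(list(no_hits(), no_hits()),
                                c("dbA", "dbA"))),
    "duplicate")
  expect_warning(build_hit_profiles(list(dbA = no_hits()), universe = "t1"),
                 "nr-hit")
})

test_that("classification follows the hierarchical homolog-distribution rules", {
  panel <- oxic_panel()  # Fungi is the single eukaryotic member

  all5 <- rep(TRUE, 5)
  expect_equal(classify_tag(all5, panel)$label, "CORE")

  # all four bacterial members, Fungi absent: still core
  bact_only <- panel$domain_flag == "bacterial"
  expect_equal(classify_tag(bact_only, panel)$label, "CORE")

  only_methylo <- panel$name == "Methylococcales"
  got <- classify_tag(only_methylo, panel)
  expect_equal(got$label, "TAXON_SPECIFIC")
  expect_equal(got$taxon, "Methylococcales")

  # the methanol-dehydrogenase pattern: exactly two bacterial members
  mdh <- panel$name %in% c("Methylococcales", "Xanthomonadales")
  expect_equal(classify_tag(mdh, panel)$label, "NONCORE_SHARED")

  none <- rep(FALSE, 5)
  expect_equal(classify_tag(none, panel, nr_hit = TRUE)$label, "MINOR")
  expect_equal(classify_tag(none, panel, nr_hit = FALSE)$label, "NOVEL")

  # Fungi-only presence is taxon-specific, not core, under the literal rule
  only_fungi <- panel$name == "Fungi"
  expect_equal(classify_tag(only_fungi, panel)$label, "TAXON_SPECIFIC")

  expect_error(classify_tag(c(TRUE, FALSE), panel), "length")
})

test_that("every presence signature classifies identically to the brute-force rule", {
  panels <- list(
    taxon_panel(c("A", "B"), c("bacterial", "bacterial")),
    taxon_panel(c("A", "B"), c("bacterial", "eukaryotic")),
    taxon_panel(c("A", "B", "C"),
                c("bacterial", "archaeal", "eukaryotic")),
    taxon_panel(c("A", "B", "C", "D"),
                c("bacterial", "bacterial", "eukaryotic", "archaeal")),
    oxic_panel())
  for (panel in panels) {
    K <- nrow(panel)
    sigs <- expand.grid(rep(list(c(FALSE, TRUE)), K))
    for (i in seq_len(nrow(sigs))) {
      sig <- unlist(sigs[i, ])
      for (nr in c(TRUE, FALSE)) {
        got <- classify_tag(sig, panel, nr)
        want <- naive_classify(sig, panel$domain_flag, nr)
        expect_equal(got$label, want,
                     info = paste(panel$name, collapse = ","))
        # exactly one branch fires: label is a single known value
        expect_true(got$label %in% c("CORE", "NONCORE_SHARED",
                                     "TAXON_SPECIFIC", "MINOR", "NOVEL"))
      }
    }
  }
})

test_that("classification is invariant to panel order and to dropping
           a non-bacterial database from core tags", {
  panel <- oxic_panel()
  set.seed(43)
  for (i in 1:20) {
    sig <- runif(5) < 0.5
    perm <- sample(5)
    permuted <- taxon_panel(panel$name[perm], panel$domain_flag[perm])
    a <- classify_tag(sig, panel)
    b <- classify_tag(sig[perm], permuted)
    expect_equal(a$label, b$label)
  }
  # removing the eukaryotic database never demotes a core tag
  drop_fungi <- panel$name != "Fungi"
  reduced <- taxon_panel(panel$name[drop_fungi],
                         panel$domain_flag[drop_fungi])
  sigs <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  for (i in seq_len(nrow(sigs))) {
    sig <- unlist(sigs[i, ])
    if (classify_tag(sig, panel)$label == "CORE")
      expect_equal(classify_tag(sig[drop_fungi], reduced)$label, "CORE")
  }
})

test_that("partitioning tallies Venn cells and summary fractions coherently", {
  panel <- taxon_panel(c("A", "B", "C"),
                       c("bacterial", "bacterial", "eukaryotic"))
  tabs <- list(
    A = rbind(make_hit("core1", "a1", bitscore = 90),
              make_hit("bcore1", "a2", bitscore = 70),
              make_hit("specA1", "a3", bitscore = 55)),
    B = rbind(make_hit("core1", "b1", bitscore = 120),
              make_hit("bcore1", "b2", bitscore = 60),
              make_hit("shareBC", "b3", bitscore = 80)),
    C = rbind(make_hit("core1", "c1", bitscore = 65),
              make_hit("shareBC", "c2", bitscore = 90)))
  universe <- c("core1", "bcore1", "specA1", "shareBC", "minor1", "novel1")
  prof <- build_hit_profiles(tabs, universe, nr_ids = c(
    "core1", "bcore1", "specA1", "shareBC", "minor1"))
  res <- partition_mrna(prof, panel)
  lab <- setNames(res$assignments$label, res$assignments$tag_id)
  expect_equal(unname(lab[c("core1", "bcore1", "specA1", "shareBC",
                            "minor1", "novel1")]),
               c("CORE", "CORE", "TAXON_SPECIFIC", "NONCORE_SHARED",
                 "MINOR", "NOVEL"))
  expect_equal(sum(res$venn$count), res$summary$n_dominant_derived)
  expect_equal(res$summary$n_annotated, 5)
  expect_equal(res$summary$dominant_derived_fraction, 4 / 5)
  expect_equal(res$summary$core_fraction, 2 / 4)
  expect_equal(res$summary$taxon_specific_counts[["A"]], 1L)

  # all-present input: single Venn cell, 100% core
  tabs1 <- list(A = make_hit("t", "a", bitscore = 60),
                B = make_hit("t", "b", bitscore = 60),
                C = make_hit("t", "c", bitscore = 60))
  res1 <- partition_mrna(build_hit_profiles(tabs1, "t", nr_ids = "t"),
                         panel)
  expect_equal(res1$venn$signature, "111")
  expect_equal(res1$summary$core_fraction, 1)
})

test_that("shared_by returns exclusive signature cells", {
  scn <- simulate_scenario(synth_config(seed = 13, n_reads = 1500))
  prof <- build_hit_profiles(scn$panel_hits, scn$mrna_universe,
                             nr_ids = scn$nr_ids)
  res <- partition_mrna(prof, scn$config$panel)
  panel <- scn$config$panel

  # a single taxon equals its taxon-specific set
  for (tx in panel$name) {
    spec_ids <- res$assignments$tag_id[
      res$assignments$label == "TAXON_SPECIFIC" &
        res$assignments$specific_taxon == tx]
    expect_setequal(shared_by(prof, tx), spec_ids)
  }
  # the full panel equals the all-present cell
  full_sig <- strrep("1", nrow(panel))
  expect_setequal(shared_by(prof, panel$name),
                  res$assignments$tag_id[res$assignments$signature ==
                                           full_sig])
  # taxon-specific sets are pairwise disjoint by construction
  spec <- res$assignments[res$assignments$label == "TAXON_SPECIFIC", ]
  expect_equal(anyDuplicated(spec$tag_id), 0L)

  expect_error(shared_by(prof, "Atlantis"), "unknown")
})
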