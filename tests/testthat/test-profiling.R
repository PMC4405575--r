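test_that("Bray-Curtis hits its analytic bounds and formula values", {
  x <- c(PhyA = 0.5, PhyB = 0.3, PhyC = 0.2)
  expect_equal(bray_curtis(x, x), 0)

  y <- c(PhyD = 0.7, PhyE = 0.3)
  expect_equal(bray_curtis(x, y), 1)

  expect_equal(bray_curtis(c(a = 0.75, b = 0.25), c(a = 0.25, b = 0.75)),
               0.5)
  expect_error(bray_curtis(c(a = 0), c(a = 0)), "all-zero")
})

test_that("Bray-Curtis agrees with vegan on union-aligned vectors", {
  skip_if_not_installed("vegan")
  set.seed(47)
  for (i in 1:20) {
    taxa <- paste0("tx", 1:8)
    x <- setNames(runif(8), taxa)
    y <- setNames(runif(8), taxa)
    x[sample(8, 2)] <- 0
    y[sample(8, 2)] <- 0
    x <- x / sum(x); y <- y / sum(y)
    ref <- as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
    expect_equal(bray_curtis(x, y), ref, tolerance = 1e-12)
  }
})

test_that("Bray-Curtis is symmetric, bounded, and zero only for equal vectors", {
  set.seed(53)
  for (i in 1:20) {
    x <- setNames(runif(6), paste0("t", 1:6))
    y <- setNames(runif(6), paste0("t", 1:6))
    bc <- bray_curtis(x, y)
    expect_equal(bc, bray_curtis(y, x))
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    if (bc == 0) expect_equal(x, y)
  }
})

test_that("dissimilarity matrices are symmetric with zero diagonal", {
  v <- list(s1 = c(a = 0.6, b = 0.4),
            s2 = c(a = 0.6, b = 0.4),
            s3 = c(a = 0.1, b = 0.2, c = 0.7))
  m <- dissimilarity_matrix(v)
  expect_equal(diag(m), setNames(rep(0, 3), names(v)))
  expect_equal(m, t(m))
  expect_equal(m["s1", "s2"], 0)
  expect_equal(m["s1", "s3"], bray_curtis(v$s1, v$s3))

  # quartile binning of the entries (the annotation scheme used when
  # displaying ranges of indices by quarter)
  set.seed(59)
  vs <- lapply(1:6, function(i) {
    x <- setNames(runif(5), paste0("t", 1:5)); x / sum(x)
  })
  names(vs) <- paste0("s", 1:6)
  m2 <- dissimilarity_matrix(vs)
  vals <- m2[upper.tri(m2)]
  bins <- cut(vals, breaks = c(0, 0.25, 0.5, 0.75, 1),
              include.lowest = TRUE)
  expect_equal(length(bins), length(vals))
  expect_false(anyNA(bins))
})

test_that("normalized taxon-specific abundance rescales to the dominant fraction", {
  scn <- simulate_scenario(synth_config(seed = 19, n_reads = 1500))
  prof <- build_hit_profiles(scn$panel_hits, scn$mrna_universe,
                             nr_ids = scn$nr_ids)
  res <- partition_mrna(prof, scn$config$panel)
  vals <- vapply(scn$config$panel$name,
                 function(g) normalized_specific_abundance(res, g),
                 numeric(1))
  expect_equal(sum(vals), res$summary$dominant_derived_fraction)
  expect_true(all(vals >= 0))

  # a group with zero specific tags scores 0
  zero_groups <- names(which(res$summary$taxon_specific_counts == 0))
  for (g in zero_groups) expect_equal(normalized_specific_abundance(res, g), 0)
  expect_error(normalized_specific_abundance(res, "Atlantis"), "unknown")
})

test_that("key-function expression divides by the group's specific total", {
  expect_equal(key_function_expression(c(photosynthesis = 30, other = 70)),
               c(photosynthesis = 0.3, other = 0.7))
  expect_equal(unname(key_function_expression(c(mcr = 12), 12)), 1)
  # an explicit total larger than the listed counts leaves headroom
  kf <- key_function_expression(c(pmoA = 5, mxaF = 3), total_specific = 20)
  expect_equal(unname(kf), c(0.25, 0.15))
  expect_length(key_function_expression(setNames(numeric(0), character(0))),
                0)
  expect_error(key_function_expression(c(x = 1), total_specific = 0),
               "positive")
})

test_that("Yates chi-square matches hand-derived values and base R", {
  # table (30,70,10,90): margins 100/100, 40/160; E = (20,80,20,80);
  # statistic = 9.5^2 * (1/20 + 1/80) * 2 = 11.28125
  res <- yates_chi_square(30, 70, 10, 90)
  expect_equal(res$statistic, 11.28125)
  expect_equal(res$p_value, pchisq(11.28125, 1, lower.tail = FALSE))

  # proportionally identical rows: clamped correction gives exactly 0
  res0 <- yates_chi_square(10, 90, 20, 180)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(yates_chi_square(0, 0, 5, 5), "margin")

  set.seed(61)
  for (i in 1:25) {
    t <- rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1))[, 1]
    if (any(t[1] + t[2] == 0, t[3] + t[4] == 0,
            t[1] + t[3] == 0, t[2] + t[4] == 0)) next
    ours <- yates_chi_square(t[1], t[2], t[3], t[4])$statistic
    ref <- suppressWarnings(
      chisq.test(matrix(t, 2, byrow = TRUE), correct = TRUE))$statistic
    expect_equal(ours, unname(ref), tolerance = 1e-12)
    # the correction can only shrink the uncorrected statistic
    raw <- suppressWarnings(
      chisq.test(matrix(t, 2, byrow = TRUE), correct = FALSE))$statistic
    expect_lte(ours, unname(raw) + 1e-12)
  }
})

test_that("differential subsystems flag planted enrichment with direction", {
  # identical profiles: nothing flagged
  cts <- c(ribosome = 300, glycolysis = 200, transport = 100)
  res <- differential_subsystems(cts, cts)
  expect_false(any(res$flagged))

  # a 10x enriched subsystem in A is flagged towards A
  a <- c(photosynthesis = 200, ribosome = 900, transport = 900)
  b <- c(photosynthesis = 20, ribosome = 990, transport = 990)
  res <- differential_subsystems(a, b, alpha = 0.01,
                                 sample_names = c("oxic", "anoxic"))
  row <- res[res$subsystem == "photosynthesis", ]
  expect_true(row$flagged)
  expect_equal(row$direction, "oxic")

  # alpha = 0 flags nothing
  res0 <- differential_subsystems(a, b, alpha = 0)
  expect_false(any(res0$flagged))

  # a subsystem absent from both samples is untestable, not flagged
  a2 <- c(a, ghost = 0); b2 <- c(b, ghost = 0)
  res2 <- differential_subsystems(a2, b2)
  expect_true(is.na(res2$p_value[res2$subsystem == "ghost"]))
  expect_false(res2$flagged[res2$subsystem == "ghost"])

  # Bonferroni correction is at least as conservative as raw p-values
  res_bf <- differential_subsystems(a, b, p_adjust = "bonferroni")
  m <- merge(res, res_bf, by = "subsystem")
  expect_true(all(m$p_adjusted.y >= m$p_adjusted.x - 1e-15, na.rm = TRUE))
})
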