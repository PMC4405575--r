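#' Bray-Curtis dissimilarity between two composition vectors
#'
#' `BC = sum |x_i - y_i| / sum (x_i + y_i)` over the union of taxa
#' (taxa absent from one vector count as 0). For non-negative inputs
#' the value lies in `[0, 1]`: 0 for identical compositions, 1 when the
#' two compositions share no taxon.
#'
#' @param x,y Named numeric vectors of non-negative relative abundances.
#' @return The Bray-Curtis dissimilarity (a single number).
#' @export
bray_curtis <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("composition vectors must be named by taxon")
  if (any(x < 0) || any(y < 0))
    stop("composition vectors must be non-negative")
  taxa <- union(names(x), names(y))
  xi <- setNames(rep(0, length(taxa)), taxa)
  yi <- xi
  xi[names(x)] <- x
  yi[names(y)] <- y
  denom <- sum(xi + yi)
  if (denom == 0) stop("both composition vectors are all-zero")
  sum(abs(xi - yi)) / denom
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param vectors Named list of composition vectors (see [bray_curtis]).
#' @return Symmetric numeric matrix with zero diagonal, labelled by the
#'   list names.
#' @export
dissimilarity_matrix <- function(vectors) {
  n <- length(vectors)
  if (n < 2) stop("need at least two composition vectors")
  labs <- names(vectors) %||% paste0("sample", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- bray_curtis(vectors[[i]], vectors[[j]])
    }
  }
  m
}

#' Normalized taxon-specific transcript abundance
#'
#' Rescales a dominant group's share of the taxon-specific transcripts
#' to the whole microbiome by the proportion of dominant-group-derived
#' reads among all annotated mRNA reads:
#' `(specific(group) / sum_g specific(g)) * dominant_derived_fraction`.
#' Summed over groups the values recover the dominant-derived fraction.
#'
#' @param partition A `partition_result` from [partition_mrna].
#' @param group Name of a panel taxon.
#' @return A single normalized abundance value.
#' @export
normalized_specific_abundance <- function(partition, group) {
  stopifnot(inherits(partition, "partition_result"))
  sc <- partition$summary$taxon_specific_counts
  if (!group %in% names(sc)) stop("unknown panel taxon: ", group)
  total <- sum(sc)
  if (total == 0) stop("no taxon-specific reads in the partition")
  (sc[[group]] / total) * partition$summary$dominant_derived_fraction
}

#' Relative expression of key functions within one dominant group
#'
#' Divides the number of taxon-specific mRNA reads annotated to each
#' function by the total number of taxon-specific reads of the group.
#'
#' @param specific_counts Named numeric vector of per-function read
#'   counts for one group (not necessarily covering every read).
#' @param total_specific Total taxon-specific read count of the group;
#'   defaults to `sum(specific_counts)`.
#' @return Named numeric vector of per-function fractions.
#' @export
key_function_expression <- function(specific_counts,
                                    total_specific = sum(specific_counts)) {
  if (length(specific_counts) == 0) return(setNames(numeric(0), character(0)))
  if (any(specific_counts < 0)) stop("counts must be non-negative")
  if (total_specific <= 0)
    stop("total taxon-specific count must be positive")
  specific_counts / total_specific
}

#' Yates-corrected chi-square test on 2x2 tables
#'
#' Two-sided chi-square test of independence with continuity correction
#' for the table `[a b; c d]`. The statistic is
#' `sum (max(0, |O - E| - 0.5))^2 / E` over the four cells, with
#' expected values from the margins; the correction is clamped at zero
#' so proportionally identical rows give a statistic of exactly 0. The
#' p-value comes from the chi-square distribution with 1 degree of
#' freedom. All arguments are vectorized over tables.
#'
#' @param a,b,c,d Non-negative cell counts (row 1: `a`, `b`; row 2:
#'   `c`, `d`). All four margins must be positive.
#' @return List with numeric vectors `statistic` and `p_value`.
#' @export
yates_chi_square <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0))
    stop("degenerate 2x2 table: zero margin")
  n <- r1 + r2
  stat <- numeric(length(n))
  for (cell in list(c("r1", "c1"), c("r1", "c2"),
                    c("r2", "c1"), c("r2", "c2"))) {
    rr <- if (cell[1] == "r1") r1 else r2
    cc <- if (cell[2] == "c1") c1 else c2
    o <- switch(paste(cell, collapse = ""),
                "r1c1" = a, "r1c2" = b, "r2c1" = c, "r2c2" = d)
    e <- rr * cc / n
    stat <- stat + pmax(0, abs(o - e) - 0.5)^2 / e
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Differentially represented functional subsystems between two samples
#'
#' For every subsystem, tests the 2x2 table (reads in the subsystem vs
#' all other reads, sample A vs sample B) with [yates_chi_square] and
#' flags subsystems with p below `alpha`; the direction names the sample
#' with the larger proportion. Subsystems absent from both samples are
#' untestable and reported with `NA` p-values. Raw p-values are used by
#' default; set `p_adjust` to a [stats::p.adjust] method (e.g.
#' `"bonferroni"`) to correct across subsystems.
#'
#' @param counts_a,counts_b Named numeric vectors of per-subsystem read
#'   counts for the two samples (aligned on the union of names).
#' @param alpha Significance threshold on the (adjusted) p-value
#'   (default 0.01).
#' @param p_adjust Multiple-testing correction method (default
#'   `"none"`).
#' @param sample_names Labels for the two samples, used in the
#'   `direction` column.
#' @return Data frame `subsystem`, `count_a`, `count_b`, `prop_a`,
#'   `prop_b`, `statistic`, `p_value`, `p_adjusted`, `direction`,
#'   `flagged`, ordered by p-value.
#' @export
differential_subsystems <- function(counts_a, counts_b, alpha = 0.01,
                                    p_adjust = "none",
                                    sample_names = c("A", "B")) {
  if (is.null(names(counts_a)) || is.null(names(counts_b)))
    stop("subsystem count vectors must be named")
  subsystems <- union(names(counts_a), names(counts_b))
  ca <- setNames(rep(0, length(subsystems)), subsystems)
  cb <- ca
  ca[names(counts_a)] <- counts_a
  cb[names(counts_b)] <- counts_b
  tot_a <- sum(ca); tot_b <- sum(cb)
  if (tot_a == 0 || tot_b == 0)
    stop("each sample needs a positive total count")
  testable <- (ca + cb) > 0 & (ca < tot_a | cb < tot_b)
  stat <- p <- rep(NA_real_, length(subsystems))
  if (any(testable)) {
    res <- yates_chi_square(ca[testable], tot_a - ca[testable],
                            cb[testable], tot_b - cb[testable])
    stat[testable] <- res$statistic
    p[testable] <- res$p_value
  }
  padj <- stats::p.adjust(p, method = p_adjust)
  prop_a <- ca / tot_a
  prop_b <- cb / tot_b
  out <- data.frame(
    subsystem = subsystems,
    count_a = as.numeric(ca), count_b = as.numeric(cb),
    prop_a = prop_a, prop_b = prop_b,
    statistic = stat, p_value = p, p_adjusted = padj,
    direction = ifelse(prop_a >= prop_b, sample_names[1], sample_names[2]),
    flagged = !is.na(padj) & padj < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value), , drop = FALSE]
}
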