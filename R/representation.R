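arm_membership <- function(catalog, arm) {
  if (identical(arm, "autosomes")) catalog$arm %in% AUTOSOME_LEVELS
  else if (arm %in% ARM_LEVELS) catalog$arm == arm
  else stop("unknown arm: ", arm, call. = FALSE)
}

#' Representation ratio of a gene set on a chromosome arm
#'
#' The fraction of the set located on the arm divided by the arm's fraction
#' of the whole catalog; 1.0 means genome-average representation.
#'
#' @param gene_set Character vector of gene ids, a subset of the catalog.
#' @param catalog A \code{\link{gene_catalog}} (the universe).
#' @param arm An arm label, or \code{"autosomes"} for the union of the
#'   autosomal arms.
#' @return Nonnegative scalar.
#' @export
representation_ratio <- function(gene_set, catalog, arm = "X") {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop("gene_set must be non-empty", call. = FALSE)
  if (!all(gene_set %in% catalog$gene_id))
    stop("gene_set contains ids absent from the catalog", call. = FALSE)
  on_arm <- arm_membership(catalog, arm)
  n_arm <- sum(on_arm)
  if (n_arm == 0) stop("no catalog genes on arm ", arm, call. = FALSE)
  in_set <- catalog$gene_id %in% gene_set
  (sum(in_set & on_arm) / length(gene_set)) / (n_arm / nrow(catalog))
}

check_hyper_counts <- function(k, n_set, n_arm, n_genome) {
  v <- c(k, n_set, n_arm, n_genome)
  if (any(v != floor(v)) || any(v < 0))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (n_set > n_genome || n_arm > n_genome || k > min(n_set, n_arm) ||
      k < max(0, n_set + n_arm - n_genome))
    stop("inconsistent hypergeometric counts", call. = FALSE)
}

#' Hypergeometric under- and over-representation tails
#'
#' For \code{K ~ Hypergeometric(n_genome, n_arm, n_set)} (the arm count of
#' a set of \code{n_set} genes drawn without replacement from a genome with
#' \code{n_arm} genes on the arm), returns \code{p_under = P(K <= k)} and
#' \code{p_over = P(K >= k)}. Both tails share the point mass at \code{k},
#' so they sum to at least 1.
#'
#' @param n_set_on_arm Observed count \code{k}.
#' @param n_set Set size.
#' @param n_arm Genes on the arm, genome-wide.
#' @param n_genome Genome (universe) size.
#' @return Named numeric vector \code{c(p_under, p_over)}.
#' @export
hypergeom_test <- function(n_set_on_arm, n_set, n_arm, n_genome) {
  check_hyper_counts(n_set_on_arm, n_set, n_arm, n_genome)
  c(p_under = stats::phyper(n_set_on_arm, n_arm, n_genome - n_arm, n_set),
    p_over = stats::phyper(n_set_on_arm - 1, n_arm, n_genome - n_arm, n_set,
                           lower.tail = FALSE))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum, over tables
#' with the observed margins, of probabilities no larger than the observed
#' table's.
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise:
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v != floor(v)) || any(v < 0))
    stop("cells must be nonnegative integers", call. = FALSE)
  if (sum(v) == 0) stop("all-zero table", call. = FALSE)
  stats::fisher.test(matrix(v, 2, byrow = TRUE))$p.value
}

#' Chi-square comparison of bias-category counts between gene groups
#'
#' Pearson chi-square (no continuity correction) on the 2-by-C table of
#' category counts for two gene groups (e.g. X-linked versus autosomal
#' genes across bias categories). Categories with a zero margin are dropped
#' with a warning; a warning is also logged when any expected count is
#' below 5.
#'
#' @param counts_x,counts_autosome Nonnegative integer vectors over the
#'   same ordered categories.
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @export
chisq_category_table <- function(counts_x, counts_autosome) {
  if (length(counts_x) != length(counts_autosome))
    stop("count vectors must share the category order", call. = FALSE)
  tab <- rbind(counts_x, counts_autosome)
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning("dropping zero-margin categories: ",
            paste(which(zero), collapse = ", "), call. = FALSE)
    tab <- tab[, !zero, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("need at least two non-empty categories",
                          call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5))
    xb_log("WARN", "chisq_category_table: expected counts below 5")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Bonferroni adjustment within a family of tests
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param m Family size; defaults to \code{length(p_values)}.
#' @return Adjusted p-values \code{pmin(1, m * p)}, order preserved.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p_values)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values (monotone-enforced), order preserved.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Arm-wise enrichment of a gene set with exact tests
#'
#' For each arm (or for X versus the pooled autosomes) computes the counts,
#' representation ratio and hypergeometric under/over tails, with
#' multiple-testing adjustment across the arms as one family.
#'
#' @param gene_set Character vector of gene ids.
#' @param catalog A \code{\link{gene_catalog}}.
#' @param by \code{"arm"} for all six arms, \code{"x_vs_autosomes"} for the
#'   dichotomy.
#' @param adjust Adjustment applied to the smaller tail per arm:
#'   \code{"bonferroni"}, \code{"BH"} or \code{"none"}.
#' @return Data frame with one row per compartment: counts, ratio,
#'   \code{p_under}, \code{p_over}, \code{p_adjusted}, \code{method}.
#' @export
arm_enrichment <- function(gene_set, catalog, by = c("arm", "x_vs_autosomes"),
                           adjust = c("bonferroni", "BH", "none")) {
  by <- match.arg(by); adjust <- match.arg(adjust)
  arms <- if (by == "arm") ARM_LEVELS else c("X", "autosomes")
  gene_set <- unique(gene_set)
  in_set <- catalog$gene_id %in% gene_set
  rows <- lapply(arms, function(a) {
    on_arm <- arm_membership(catalog, a)
    k <- sum(in_set & on_arm)
    ht <- hypergeom_test(k, sum(in_set), sum(on_arm), nrow(catalog))
    data.frame(arm = a, n_set_on_arm = k, n_set = sum(in_set),
               n_arm = sum(on_arm), n_genome = nrow(catalog),
               representation_ratio = (k / sum(in_set)) /
                 (sum(on_arm) / nrow(catalog)),
               p_under = ht[["p_under"]], p_over = ht[["p_over"]],
               method = "hypergeometric", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  p_min <- pmin(res$p_under, res$p_over)
  res$p_adjusted <- switch(adjust,
                           bonferroni = bonferroni(p_min),
                           BH = bh_fdr(p_min),
                           none = p_min)
  res
}
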