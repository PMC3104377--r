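#' Bound-gene set for one protein at its threshold
#'
#' Genes whose score is at or above the protein's threshold; genes with a
#' missing score are not assessed for this protein and are excluded from
#' both the bound set and the universe.
#'
#' @param bp A \code{\link{binding_profile}}.
#' @param protein Protein name.
#' @return Character vector of bound gene ids.
#' @export
binarize_binding <- function(bp, protein) {
  stopifnot(inherits(bp, "binding_profile"))
  if (!protein %in% colnames(bp$scores))
    stop("unknown protein: ", protein, call. = FALSE)
  s <- bp$scores[, protein]
  names(s)[!is.na(s) & s >= bp$thresholds[[protein]]]
}

#' Bound-gene frequency of a gene set relative to the genome, by compartment
#'
#' For the X-linked and the autosomal members of a gene set, the fraction
#' of bound genes is normalized to the genome-wide bound fraction on the
#' same assessed-gene universe (genes with a score for this protein); a
#' relative frequency of 1.0 means genome-average binding. An empty
#' compartment yields an \code{NA} row flagged not assessable rather than
#' an error.
#'
#' @param bp A \code{\link{binding_profile}}.
#' @param protein Protein name.
#' @param gene_set Character vector of gene ids.
#' @param catalog A \code{\link{gene_catalog}}.
#' @return Data frame with one row per compartment (X, autosomes).
#' @export
binding_enrichment <- function(bp, protein, gene_set, catalog) {
  bound <- binarize_binding(bp, protein)
  assessed <- rownames(bp$scores)[!is.na(bp$scores[, protein])]
  assessed <- intersect(assessed, catalog$gene_id)
  f_genome <- if (length(assessed)) mean(assessed %in% bound) else NA_real_
  arm <- catalog$arm[match(assessed, catalog$gene_id)]
  set_assessed <- assessed[assessed %in% gene_set]
  set_arm <- arm[assessed %in% gene_set]
  rows <- lapply(c("X", "autosomes"), function(comp) {
    members <- if (comp == "X") set_assessed[set_arm == "X"]
               else set_assessed[set_arm %in% AUTOSOME_LEVELS]
    f_set <- if (length(members)) mean(members %in% bound) else NA_real_
    data.frame(protein = protein, role = bp$roles[[protein]],
               compartment = comp, n_set = length(members),
               f_set = f_set, f_genome = f_genome,
               relative_frequency = if (!is.na(f_set) && f_genome > 0)
                 f_set / f_genome else NA_real_,
               assessable = length(members) > 0 && isTRUE(f_genome > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between developmental up-regulation and binding score
#'
#' For every protein and later timepoint, the Pearson correlation between
#' the log2 fold change (versus the earliest timepoint) and the protein's
#' continuous binding score over the genes shared by both tables
#' (pairwise-complete per protein), with a two-sided p-value and Bonferroni
#' adjustment across the whole protein-by-timepoint series. Cells with
#' fewer than 3 shared genes are omitted with a log entry.
#'
#' @param fc A \code{\link{fold_change_vs_earliest}} result.
#' @param bp A \code{\link{binding_profile}}.
#' @return Data frame with columns \code{protein}, \code{role},
#'   \code{timepoint}, \code{r}, \code{n}, \code{p}, \code{p_adjusted}.
#' @export
expression_binding_correlation <- function(fc, bp) {
  stopifnot(inherits(fc, "fold_change_matrix"),
            inherits(bp, "binding_profile"))
  shared <- intersect(rownames(fc$lfc), rownames(bp$scores))
  rows <- list()
  for (pr in colnames(bp$scores)) {
    s <- bp$scores[shared, pr]
    for (tp in colnames(fc$lfc)) {
      y <- fc$lfc[shared, tp]
      ok <- !is.na(s) & !is.na(y)
      if (sum(ok) < 3) {
        xb_log("WARN",
               "expression_binding_correlation: %s x %s has %d shared genes; omitted",
               pr, tp, sum(ok))
        next
      }
      ct <- stats::cor.test(s[ok], y[ok], method = "pearson",
                            alternative = "two.sided")
      rows[[paste(pr, tp)]] <- data.frame(
        protein = pr, role = bp$roles[[pr]], timepoint = tp,
        r = unname(ct$estimate), n = sum(ok), p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adjusted <- bonferroni(res$p)
  res
}

#' Summarize the inverse correlation pattern across protein roles
#'
#' Counts significant (adjusted p below \code{alpha}) positive and
#' negative correlations per role. The "inverse" pattern flag is TRUE when
#' significant correlations of silencing-role proteins are predominantly
#' positive (up-regulated genes bind repressors in non-target cells) and
#' those of activation-role proteins predominantly negative; each role
#' must contribute at least one significant cell.
#'
#' @param results Output of \code{\link{expression_binding_correlation}}.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return List with per-role counts and the logical
#'   \code{inverse_pattern} flag.
#' @export
inverse_correlation_report <- function(results, alpha = 0.05) {
  sig <- results[!is.na(results$p_adjusted) & results$p_adjusted < alpha, ]
  count <- function(role, dir) {
    r <- sig$r[sig$role == role]
    if (dir == "pos") sum(r > 0) else sum(r < 0)
  }
  tab <- data.frame(
    role = c("silencing", "activation"),
    n_significant = c(sum(sig$role == "silencing"),
                      sum(sig$role == "activation")),
    n_positive = c(count("silencing", "pos"), count("activation", "pos")),
    n_negative = c(count("silencing", "neg"), count("activation", "neg")),
    stringsAsFactors = FALSE)
  tab$fraction_positive <- ifelse(tab$n_significant > 0,
                                  tab$n_positive / tab$n_significant,
                                  NA_real_)
  sil <- tab[tab$role == "silencing", ]
  act <- tab[tab$role == "activation", ]
  flag <- sil$n_significant > 0 && act$n_significant > 0 &&
    sil$n_positive > sil$n_negative && act$n_negative > act$n_positive
  list(by_role = tab, inverse_pattern = flag, alpha = alpha)
}
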