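condition_labels <- function(samples) {
  paste0("d", samples$day, substr(samples$stage, 1, 1))
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

#' Log2 transform and quantile-normalize a time course
#'
#' The in-repo surrogate for external array normalization: intensities are
#' log2 transformed and quantile normalization equalizes the distribution
#' across samples, so columns that differ only by a scale factor become
#' identical.
#'
#' @param tc A \code{\link{time_course}} with positive raw intensities.
#' @return A \code{\link{time_course}} on the log2 scale.
#' @export
normalize_arrays <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  if (tc$log2) stop("time course is already on the log2 scale", call. = FALSE)
  if (any(tc$values <= 0))
    stop("nonpositive intensities cannot be log2 transformed", call. = FALSE)
  norm <- limma::normalizeQuantiles(log2(tc$values))
  dimnames(norm) <- dimnames(tc$values)
  suppressWarnings(time_course(norm, tc$samples, log2 = TRUE))
}

#' Shrink gene-wise variances toward a pooled prior
#'
#' Empirical-Bayes variance moderation: the prior degrees of freedom
#' \code{d0} and prior variance \code{s02} are estimated from the marginal
#' distribution of the gene-wise sample variances by moment matching
#' (under the scaled-F marginal, \code{var/mean^2 = 2(d + d0 - 2) /
#' (d (d0 - 4))}), and each gene's posterior variance is
#' \code{(d0 s02 + d s2) / (d0 + d)}. With \code{d0 = 0} this is the
#' ordinary gene-wise variance; as \code{d0} grows it approaches the
#' pooled prior.
#'
#' @param s2 Gene-wise sample variances.
#' @param df Residual degrees of freedom of each \code{s2} (scalar).
#' @param d0,s02 Optional fixed prior; estimated when \code{NULL}.
#' @return List with \code{s2_post}, \code{d0}, \code{s02}.
#' @export
moderate_variances <- function(s2, df, d0 = NULL, s02 = NULL) {
  if (is.null(d0) || is.null(s02)) {
    m1 <- mean(s2)
    cv2 <- if (m1 > 0) stats::var(s2) / m1^2 else 0
    if (!is.finite(cv2) || cv2 * df <= 2) {
      d0 <- Inf
      s02 <- m1
    } else {
      d0 <- (2 * df - 4 + 4 * cv2 * df) / (cv2 * df - 2)
      if (d0 <= 0) d0 <- Inf
      s02 <- if (is.finite(d0)) m1 * (d0 - 2) / d0 else m1
      if (!is.finite(s02) || s02 < 0) s02 <- m1
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  list(s2_post = s2_post, d0 = d0, s02 = s02)
}

#' Fold changes and moderated-t calls versus the earliest timepoint
#'
#' For every later condition, computes the mean log2 difference versus the
#' earliest condition, a moderated t statistic (gene-wise pooled two-sample
#' variances shrunk toward a moment-matched prior,
#' \code{\link{moderate_variances}}), a p-value from the t distribution
#' with \code{d0 + d} degrees of freedom, and Benjamini-Hochberg q-values
#' within each contrast.
#'
#' @param tc_norm A normalized (log2-scale) \code{\link{time_course}}.
#' @param shrink Use variance moderation (default); \code{FALSE} gives the
#'   ordinary two-sample t.
#' @return List of class \code{fold_change_matrix} with gene-by-contrast
#'   matrices \code{lfc}, \code{t}, \code{p}, \code{q}, plus
#'   \code{reference}, per-contrast \code{d0}, \code{s02} and total
#'   degrees of freedom.
#' @export
fold_change_vs_earliest <- function(tc_norm, shrink = TRUE) {
  stopifnot(inherits(tc_norm, "time_course"))
  if (!tc_norm$log2)
    stop("fold_change_vs_earliest expects a log2-scale time course; ",
         "run normalize_arrays() first", call. = FALSE)
  cond <- condition_labels(tc_norm$samples)
  ord <- order(tc_norm$samples$day, match(cond, cond))
  levels_ord <- unique(cond[ord])
  ref <- levels_ord[1]
  later <- levels_ord[-1]
  ref_cols <- which(cond == ref)
  if (length(ref_cols) < 2)
    stop("reference condition needs at least 2 replicates", call. = FALSE)
  X <- tc_norm$values
  ref_mean <- rowMeans(X[, ref_cols, drop = FALSE])
  ref_var <- row_vars(X[, ref_cols, drop = FALSE])
  n1 <- length(ref_cols)

  out <- list(lfc = NULL, t = NULL, p = NULL, q = NULL)
  d0s <- s02s <- dfs <- stats::setNames(numeric(length(later)), later)
  mats <- lapply(c("lfc", "t", "p", "q"), function(.)
    matrix(NA_real_, nrow(X), length(later), dimnames = list(rownames(X), later)))
  names(mats) <- c("lfc", "t", "p", "q")
  for (ct in later) {
    cols <- which(cond == ct)
    if (length(cols) < 2)
      stop("condition ", ct, " needs at least 2 replicates", call. = FALSE)
    n2 <- length(cols)
    lfc <- rowMeans(X[, cols, drop = FALSE]) - ref_mean
    s2 <- ((n1 - 1) * ref_var + (n2 - 1) * row_vars(X[, cols, drop = FALSE])) /
      (n1 + n2 - 2)
    d <- n1 + n2 - 2
    if (shrink) {
      mod <- moderate_variances(s2, d)
      s2_use <- mod$s2_post; df_t <- d + mod$d0
      d0s[ct] <- mod$d0; s02s[ct] <- mod$s02
    } else {
      s2_use <- s2; df_t <- d
      d0s[ct] <- 0; s02s[ct] <- NA_real_
    }
    se <- sqrt(s2_use * (1 / n1 + 1 / n2))
    tt <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
    p <- if (is.finite(df_t)) 2 * stats::pt(abs(tt), df_t, lower.tail = FALSE)
         else 2 * stats::pnorm(abs(tt), lower.tail = FALSE)
    mats$lfc[, ct] <- lfc; mats$t[, ct] <- tt; mats$p[, ct] <- p
    mats$q[, ct] <- bh_fdr(p)
    dfs[ct] <- df_t
  }
  structure(list(lfc = mats$lfc, t = mats$t, p = mats$p, q = mats$q,
                 reference = ref, contrasts = later, d0 = d0s, s02 = s02s,
                 df_total = dfs),
            class = "fold_change_matrix")
}

#' Genes up-regulated during testis development
#'
#' Differential expression is called at \code{q < q_threshold}; a gene is
#' up-regulated when it is significant with a positive log2 fold change at
#' one or more later timepoints. Genes significant only with negative fold
#' changes are excluded.
#'
#' @param fc A \code{\link{fold_change_vs_earliest}} result.
#' @param q_threshold FDR threshold (default 0.1).
#' @return Character vector of gene ids.
#' @export
upregulated_set <- function(fc, q_threshold = 0.1) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  hit <- fc$q < q_threshold & fc$lfc > 0
  rownames(fc$lfc)[rowSums(hit, na.rm = TRUE) > 0]
}

#' Per-timepoint comparison of global X-linked versus autosomal expression
#'
#' For every condition, summarizes the per-gene mean normalized signal of
#' the X-linked and autosomal gene groups (median and quartiles), their
#' median difference, and a two-sided Wilcoxon rank-sum p-value, with
#' Bonferroni adjustment across the condition series.
#'
#' @param tc_norm A normalized \code{\link{time_course}}.
#' @param catalog A \code{\link{gene_catalog}} covering the time-course
#'   genes.
#' @return Data frame, one row per condition.
#' @export
x_vs_autosome_profile <- function(tc_norm, catalog) {
  stopifnot(inherits(tc_norm, "time_course"))
  ids <- rownames(tc_norm$values)
  arm <- catalog$arm[match(ids, catalog$gene_id)]
  if (anyNA(arm))
    stop("time-course genes missing from the catalog", call. = FALSE)
  is_x <- arm == "X"
  if (!any(is_x) || !any(!is_x))
    stop("both X and autosomal gene groups must be non-empty", call. = FALSE)
  cond <- condition_labels(tc_norm$samples)
  ord <- order(tc_norm$samples$day, match(cond, cond))
  levels_ord <- unique(cond[ord])
  rows <- lapply(levels_ord, function(ct) {
    m <- rowMeans(tc_norm$values[, cond == ct, drop = FALSE])
    x <- m[is_x]; a <- m[!is_x]
    qs_x <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    qs_a <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = ct,
               day = tc_norm$samples$day[match(ct, cond)],
               n_x = length(x), n_autosome = length(a),
               x_q1 = qs_x[1], x_median = qs_x[2], x_q3 = qs_x[3],
               autosome_q1 = qs_a[1], autosome_median = qs_a[2],
               autosome_q3 = qs_a[3],
               median_diff = qs_x[2] - qs_a[2],
               p = suppressWarnings(stats::wilcox.test(x, a)$p.value),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bonferroni(res$p)
  res
}

#' Relative expression from qPCR Ct values (2^-ddCt)
#'
#' Per gene and sample, \code{dCt = Ct_target - Ct_reference} (the loading
#' control); \code{ddCt} is taken versus a designated reference sample, so
#' that sample's relative expression is exactly 1.
#'
#' @param qt A \code{\link{qpcr_table}}.
#' @param reference_sample Sample id present for every gene.
#' @return Data frame with columns \code{gene_id}, \code{sample_id},
#'   \code{rel_expression}.
#' @export
qpcr_relative <- function(qt, reference_sample) {
  stopifnot(inherits(qt, "qpcr_table"))
  dct <- qt$ct_target - qt$ct_reference
  ref <- qt$sample_id == reference_sample
  by_gene <- split(seq_len(nrow(qt)), qt$gene_id)
  rows <- lapply(by_gene, function(i) {
    r <- i[ref[i]]
    if (length(r) != 1)
      stop("reference sample '", reference_sample,
           "' missing (or duplicated) for gene ", qt$gene_id[i[1]],
           call. = FALSE)
    data.frame(gene_id = qt$gene_id[i], sample_id = qt$sample_id[i],
               rel_expression = 2^(-(dct[i] - dct[r])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
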