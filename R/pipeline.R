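#' Percentage of assayed genes that are induced, as printed in reports
#'
#' \code{floor(100 * n_induced / n_assayed)}: the percentage is truncated
#' to a whole number (474 of 501 is 94.61 and reports as 94), the
#' convention under which published induced-gene percentages of this kind
#' reproduce exactly.
#'
#' @param n_induced Number of induced genes, \code{0 <= n_induced <=
#'   n_assayed}.
#' @param n_assayed Number of genes assayed, positive.
#' @return Integer percentage.
#' @export
induced_fraction <- function(n_induced, n_assayed) {
  if (n_assayed <= 0) stop("n_assayed must be positive", call. = FALSE)
  if (n_induced < 0 || n_induced > n_assayed)
    stop("need 0 <= n_induced <= n_assayed", call. = FALSE)
  as.integer(floor(100 * n_induced / n_assayed))
}

#' Run the full analysis on a synthetic or user-supplied study
#'
#' Executes the stages in dependency order: tissue-bias scoring per target
#' tissue, chromosomal representation of the biased sets, time-course
#' normalization and moderated-t differential calls, the per-timepoint
#' X-versus-autosome comparison, and the chromatin-binding enrichment and
#' correlation analyses. Deterministic for a fixed configuration seed.
#'
#' @param config A \code{\link{sim_config}} used to generate the study
#'   when \code{data} is NULL.
#' @param data Optional pre-built study list with elements \code{catalog},
#'   \code{atlas}, \code{timecourse}, \code{binding} (as produced by
#'   \code{\link{simulate_study}} or assembled from user tables).
#' @param target_tissues Tissues to score bias toward; defaults to every
#'   atlas tissue.
#' @param bias_thresholds Category edges for bias classification.
#' @param q_threshold FDR threshold for differential calls.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV plus a JSON report.
#' @return List of class \code{run_report} with per-stage results and
#'   headline numbers.
#' @export
run_study <- function(config = sim_config(), data = NULL,
                      target_tissues = NULL,
                      bias_thresholds = c(2, 5, 10), q_threshold = 0.1,
                      out_dir = NULL) {
  if (is.null(data)) {
    xb_log("INFO", "run_study: generating synthetic study (seed %d)",
           config$seed)
    data <- simulate_study(config)
  }
  catalog <- data$catalog
  atlas <- data$atlas
  target_tissues <- target_tissues %||% colnames(atlas)

  # stage 1: bias scoring per target tissue
  bias <- lapply(target_tissues, function(t)
    bias_table(atlas, t, thresholds = bias_thresholds))
  names(bias) <- target_tissues

  # stage 2: chromosomal representation of biased sets per tissue x category
  top <- bias_thresholds[length(bias_thresholds)]
  rep_rows <- list()
  high_sets <- list()
  for (t in target_tissues) {
    for (thr in bias_thresholds) {
      set <- bias[[t]]$gene_id[bias[[t]]$min_ratio >= thr]
      if (length(set) == 0) next
      er <- arm_enrichment(set, catalog, by = "x_vs_autosomes",
                           adjust = "none")
      er <- er[er$arm == "X", ]
      er$tissue <- t; er$bias_threshold <- thr
      rep_rows[[paste(t, thr)]] <- er
      if (thr == top) high_sets[[t]] <- set
    }
  }
  representation <- do.call(rbind, rep_rows)
  rownames(representation) <- NULL
  # one Bonferroni family per analysis table
  representation$p_adjusted <-
    bonferroni(pmin(representation$p_under, representation$p_over))
  high_union <- unique(unlist(high_sets))

  # stage 3: time course
  tc_norm <- normalize_arrays(data$timecourse)
  fc <- fold_change_vs_earliest(tc_norm)
  upreg <- upregulated_set(fc, q_threshold)
  profile <- x_vs_autosome_profile(tc_norm, catalog)

  # X vs autosome bias-category contrast among testis-up-regulated genes
  chisq <- NULL
  if ("testis" %in% target_tissues && length(upreg) >= 2) {
    bt <- bias[["testis"]]
    bt <- bt[bt$gene_id %in% upreg, ]
    arm <- catalog$arm[match(bt$gene_id, catalog$gene_id)]
    cx <- table(bt$category[arm == "X"])
    ca <- table(bt$category[arm != "X"])
    chisq <- tryCatch(chisq_category_table(as.integer(cx), as.integer(ca)),
                      error = function(e) NULL)
  }

  # stage 4: chromatin association
  correlations <- expression_binding_correlation(fc, data$binding)
  inverse <- inverse_correlation_report(correlations)
  enrichment <- do.call(rbind, lapply(colnames(data$binding$scores),
    function(pr) {
      sets <- lapply(target_tissues, function(t)
        bias[[t]]$gene_id[bias[[t]]$min_ratio >= bias_thresholds[1]])
      do.call(rbind, Map(function(set, t) {
        be <- binding_enrichment(data$binding, pr, set, catalog)
        be$tissue <- t
        be
      }, sets, target_tissues))
    }))
  rownames(enrichment) <- NULL

  x_row <- representation[representation$tissue == "testis" &
                            representation$bias_threshold == top, ]
  headline <- list(
    n_genes = nrow(catalog),
    n_upregulated = length(upreg),
    x_ratio_high_bias_union = if (length(high_union))
      representation_ratio(high_union, catalog, "X") else NA_real_,
    x_p_under_high_bias_union = if (length(high_union))
      unname(hypergeom_test(
        sum(catalog$gene_id[catalog$arm == "X"] %in% high_union),
        length(high_union), sum(catalog$arm == "X"),
        nrow(catalog))["p_under"]) else NA_real_,
    x_ratio_testis_high = if (nrow(x_row)) x_row$representation_ratio
                          else NA_real_,
    chisq_p = if (!is.null(chisq)) chisq$p else NA_real_,
    inverse_pattern = inverse$inverse_pattern,
    x_autosome_min_p_adjusted = min(profile$p_adjusted),
    seed = config$seed)

  report <- structure(list(bias = bias, representation = representation,
                           fold_change = fc, upregulated = upreg,
                           x_vs_autosome = profile, chisq = chisq,
                           correlations = correlations, inverse = inverse,
                           binding_enrichment = enrichment,
                           headline = headline, config = config),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write the stage outputs of a run to a directory
#'
#' @param report A \code{\link{run_study}} result.
#' @param out_dir Directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_result_table(do.call(rbind, report$bias), p("bias.tsv"))
  write_result_table(report$representation, p("representation.tsv"))
  write_result_table(
    data.frame(gene_id = rownames(report$fold_change$lfc),
               report$fold_change$lfc, check.names = FALSE),
    p("foldchange.tsv"))
  writeLines(report$upregulated, p("upregulated.txt"))
  write_result_table(report$x_vs_autosome, p("x_vs_autosome.tsv"))
  write_result_table(report$correlations, p("correlations.tsv"))
  write_result_table(report$binding_enrichment, p("binding_enrichment.tsv"))
  write_result_json(report$headline, p("report.json"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  h <- x$headline
  cat("xbias run report\n")
  cat(sprintf("  genes: %d; up-regulated (q<0.1, FC>0): %d\n",
              h$n_genes, h$n_upregulated))
  cat(sprintf("  X ratio of >=10x biased union: %.3f (p_under %.3g)\n",
              h$x_ratio_high_bias_union, h$x_p_under_high_bias_union))
  cat(sprintf("  inverse correlation pattern: %s\n", h$inverse_pattern))
  invisible(x)
}
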