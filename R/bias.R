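#' Minimal target-to-panel signal ratio
#'
#' The tissue-bias statistic: the minimum, over a panel of non-target
#' tissues, of the target::tissue signal ratio. Taking the minimum rather
#' than a mean or median is deliberately conservative — a gene only scores
#' as biased if its target signal exceeds every panel tissue. A pseudocount
#' \code{epsilon} is added to numerator and denominator to guard against
#' zero signals.
#'
#' @param target_signal Nonnegative scalar, the target-tissue signal.
#' @param panel_signals Nonnegative vector of panel-tissue signals.
#' @param epsilon Nonnegative pseudocount.
#' @return The minimal ratio, a nonnegative scalar.
#' @export
minimal_ratio <- function(target_signal, panel_signals, epsilon = 0) {
  if (length(panel_signals) == 0)
    stop("panel must be non-empty", call. = FALSE)
  if (target_signal < 0 || any(panel_signals < 0) || epsilon < 0)
    stop("signals and epsilon must be nonnegative", call. = FALSE)
  if (epsilon == 0 && any(panel_signals == 0))
    stop("zero panel signal with epsilon = 0; supply a positive epsilon",
         call. = FALSE)
  min((target_signal + epsilon) / (panel_signals + epsilon))
}

#' Classify a bias ratio into the standard categories
#'
#' Bins are half-open with inclusive lower edges, so a ratio of exactly 10
#' belongs to the \code{">=10"} category.
#'
#' @param min_ratio Numeric vector of minimal ratios.
#' @param thresholds Strictly increasing bin edges (default
#'   \code{c(2, 5, 10)}).
#' @return Factor with levels \code{"<2"}, \code{">=2"}, \code{">=5"},
#'   \code{">=10"} (for the default thresholds).
#' @export
classify_bias <- function(min_ratio, thresholds = c(2, 5, 10)) {
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  labs <- c(paste0("<", thresholds[1]), paste0(">=", thresholds))
  idx <- findInterval(min_ratio, thresholds) + 1L
  factor(labs[idx], levels = labs)
}

default_epsilon <- function(atlas) {
  pos <- atlas[atlas > 0]
  if (length(pos) == 0) 1 else min(pos) / 2
}

min_ratio_for_target <- function(atlas, target_tissue, epsilon) {
  if (!target_tissue %in% colnames(atlas))
    stop("unknown target tissue: ", target_tissue, call. = FALSE)
  panel <- setdiff(colnames(atlas), target_tissue)
  if (length(panel) == 0)
    stop("atlas has no panel tissues besides the target", call. = FALSE)
  tgt <- atlas[, target_tissue] + epsilon
  ratios <- lapply(panel, function(t) tgt / (atlas[, t] + epsilon))
  stats::setNames(do.call(pmin, ratios), rownames(atlas))
}

#' Per-gene bias score table against a target tissue
#'
#' Computes the minimal target-to-panel ratio for every gene in the atlas;
#' the panel is every atlas tissue except the target (the somatic panel
#' includes ovary — no germline exclusion is applied).
#'
#' @param atlas An \code{\link{expression_atlas}}.
#' @param target_tissue Tissue to score bias toward.
#' @param epsilon Pseudocount; \code{"auto"} (default) uses half the
#'   smallest positive intensity in the atlas.
#' @param thresholds Category edges passed to \code{\link{classify_bias}}.
#' @return Data frame with columns \code{gene_id}, \code{target_tissue},
#'   \code{min_ratio}, \code{category}, in atlas row order.
#' @export
bias_table <- function(atlas, target_tissue, epsilon = "auto",
                       thresholds = c(2, 5, 10)) {
  if (identical(epsilon, "auto")) epsilon <- default_epsilon(atlas)
  mr <- min_ratio_for_target(atlas, target_tissue, epsilon)
  data.frame(gene_id = rownames(atlas), target_tissue = target_tissue,
             min_ratio = as.numeric(mr),
             category = classify_bias(as.numeric(mr), thresholds),
             stringsAsFactors = FALSE)
}

#' Genes biased toward a target tissue at a ratio threshold
#'
#' @inheritParams bias_table
#' @param threshold Minimal-ratio cut-off (inclusive).
#' @return Character vector of gene ids with \code{min_ratio >= threshold}.
#' @export
biased_gene_set <- function(atlas, target_tissue, threshold = 10,
                            epsilon = "auto") {
  if (identical(epsilon, "auto")) epsilon <- default_epsilon(atlas)
  mr <- min_ratio_for_target(atlas, target_tissue, epsilon)
  rownames(atlas)[mr >= threshold]
}

#' Fraction of one gene set contained in another
#'
#' \code{|a intersect b| / |a|}, e.g. the share of a tissue-biased set that
#' is gonad-dependent.
#'
#' @param set_a Non-empty character vector (the denominator set).
#' @param set_b Character vector.
#' @return Fraction in [0, 1].
#' @export
overlap_fraction <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0) stop("set_a must be non-empty", call. = FALSE)
  length(intersect(set_a, set_b)) / length(set_a)
}
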