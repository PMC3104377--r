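#' Chromosome arm vocabulary
#'
#' The five major Drosophila melanogaster chromosome arms plus the dot
#' chromosome. Genes on the Y or on unmapped scaffolds are outside the
#' vocabulary and are dropped at load time.
#'
#' @format Character vector of arm labels.
#' @export
ARM_LEVELS <- c("X", "2L", "2R", "3L", "3R", "4")

#' Autosomal arms
#'
#' All arms in \code{\link{ARM_LEVELS}} except the X; chromosome 4 is
#' retained as an autosome.
#'
#' @format Character vector of arm labels.
#' @export
AUTOSOME_LEVELS <- c("2L", "2R", "3L", "3R", "4")

#' Construct a validated gene catalog
#'
#' A gene catalog maps gene identifiers to chromosome arms and serves as the
#' universe for every enrichment test in the package.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param arm Character vector of arm labels, drawn from
#'   \code{\link{ARM_LEVELS}}.
#' @return A data frame of class \code{gene_catalog} with columns
#'   \code{gene_id} and \code{arm}, in input order.
#' @export
gene_catalog <- function(gene_id, arm) {
  gene_id <- as.character(gene_id)
  arm <- as.character(arm)
  if (length(gene_id) != length(arm))
    stop("gene_id and arm must have the same length", call. = FALSE)
  if (length(gene_id) == 0)
    stop("gene catalog must be non-empty", call. = FALSE)
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop("duplicate gene_id in catalog: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(arm), ARM_LEVELS)
  if (length(bad))
    stop("arm labels outside vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(data.frame(gene_id = gene_id, arm = arm,
                       stringsAsFactors = FALSE),
            class = c("gene_catalog", "data.frame"))
}

#' Construct a validated expression atlas
#'
#' A genes-by-tissues matrix of nonnegative intensities in arbitrary units,
#' e.g. a FlyAtlas-style panel of adult tissue signals.
#'
#' @param values Numeric matrix; rownames are gene ids, colnames tissue
#'   labels.
#' @return Matrix of class \code{expression_atlas}.
#' @export
expression_atlas <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("atlas rows must carry unique gene ids", call. = FALSE)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("atlas columns must carry unique tissue labels", call. = FALSE)
  if (!is.numeric(values) || anyNA(values))
    stop("atlas intensities must be numeric and complete", call. = FALSE)
  if (any(values < 0))
    stop("atlas intensities must be nonnegative", call. = FALSE)
  class(values) <- c("expression_atlas", class(values))
  values
}

#' Construct a validated expression time course
#'
#' A genes-by-samples intensity matrix with per-sample metadata (day,
#' developmental stage, replicate). Conditions are (day, stage) pairs; the
#' earliest condition is the reference for fold-change analysis.
#'
#' @param values Numeric matrix, rownames gene ids, colnames sample ids.
#' @param samples Data frame with columns \code{sample}, \code{day}
#'   (integer), \code{stage} (free text, e.g. feeding/wandering) and
#'   \code{replicate}; one row per column of \code{values}.
#' @param log2 Logical; \code{TRUE} once intensities have been log2
#'   transformed (negative values are then permitted).
#' @return List of class \code{time_course} with elements \code{values},
#'   \code{samples} and \code{log2}.
#' @export
time_course <- function(values, samples, log2 = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop("time-course intensities must be numeric and complete", call. = FALSE)
  if (!log2 && any(values < 0))
    stop("time-course intensities must be nonnegative", call. = FALSE)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("time-course rows must carry unique gene ids", call. = FALSE)
  req <- c("sample", "day", "stage", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample metadata needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!identical(as.character(samples$sample), colnames(values)))
    stop("sample metadata must match matrix columns in order", call. = FALSE)
  cond <- interaction(samples$day, samples$stage, drop = TRUE)
  if (length(unique(samples$day)) < 2)
    stop("time course needs at least two timepoints", call. = FALSE)
  nrep <- table(cond)
  if (any(nrep < 3))
    warning("conditions with fewer than 3 replicates: ",
            paste(names(nrep)[nrep < 3], collapse = ", "), call. = FALSE)
  structure(list(values = values, samples = samples, log2 = isTRUE(log2)),
            class = "time_course")
}

#' Construct a validated chromatin-binding profile
#'
#' Genes-by-proteins continuous binding scores (ChIP or DamID style
#' enrichments; log-ratios, so negative values are allowed), with a
#' per-protein bound/non-bound threshold and a per-protein role tag.
#' Missing scores mark genes not assessed for that protein; they are
#' excluded pairwise downstream.
#'
#' @param scores Numeric matrix, rownames gene ids, colnames protein names;
#'   \code{NA} allowed.
#' @param thresholds Named numeric vector, one finite threshold per protein.
#' @param roles Named character vector, one of \code{"silencing"} or
#'   \code{"activation"} per protein.
#' @return List of class \code{binding_profile}.
#' @export
binding_profile <- function(scores, thresholds, roles) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)) || anyDuplicated(colnames(scores)))
    stop("binding columns must carry unique protein names", call. = FALSE)
  if (is.null(rownames(scores)) || anyDuplicated(rownames(scores)))
    stop("binding rows must carry unique gene ids", call. = FALSE)
  prot <- colnames(scores)
  if (!all(prot %in% names(thresholds)) || !all(is.finite(thresholds[prot])))
    stop("every protein needs a finite threshold", call. = FALSE)
  if (!all(prot %in% names(roles)) ||
      !all(roles[prot] %in% c("silencing", "activation")))
    stop("every protein needs a role: silencing or activation", call. = FALSE)
  structure(list(scores = scores, thresholds = thresholds[prot],
                 roles = roles[prot]),
            class = "binding_profile")
}

#' Construct a validated qPCR Ct table
#'
#' Paired target/loading-control threshold-cycle values per gene and sample,
#' as produced by SYBR-green qRT-PCR with a reference transcript (rp49-style)
#' as template loading control.
#'
#' @param df Data frame with columns \code{gene_id}, \code{sample_id},
#'   \code{ct_target}, \code{ct_reference}.
#' @return Data frame of class \code{qpcr_table}.
#' @export
qpcr_table <- function(df) {
  req <- c("gene_id", "sample_id", "ct_target", "ct_reference")
  if (!all(req %in% names(df)))
    stop("qPCR table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(is.finite(df$ct_target)) || !all(is.finite(df$ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  if (anyDuplicated(df[c("gene_id", "sample_id")]))
    stop("one paired Ct record per (gene, sample) expected", call. = FALSE)
  structure(df, class = c("qpcr_table", "data.frame"))
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time_course: %d genes x %d samples (%d conditions)%s\n",
              nrow(x$values), ncol(x$values),
              length(unique(interaction(x$samples$day, x$samples$stage,
                                        drop = TRUE))),
              if (x$log2) ", log2 scale" else ""))
  invisible(x)
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("binding_profile: %d genes x %d proteins (%d silencing, %d activation)\n",
              nrow(x$scores), ncol(x$scores),
              sum(x$roles == "silencing"), sum(x$roles == "activation")))
  invisible(x)
}
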