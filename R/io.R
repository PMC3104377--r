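# Tabular interchange: TSV with a header row; gzip input accepted
# transparently via the file extension.

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_tsv_raw <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  utils::read.delim(con, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
}

#' Read a gene catalog from TSV
#'
#' Expects header columns \code{gene_id} and \code{arm}. Rows whose arm is
#' outside the major-arm vocabulary (e.g. Y-linked genes or unmapped
#' scaffolds) are dropped with a logged count; duplicated gene ids are an
#' error.
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return A \code{\link{gene_catalog}}.
#' @export
read_catalog <- function(path) {
  df <- read_tsv_raw(path)
  if (!all(c("gene_id", "arm") %in% names(df)))
    stop("catalog file must have columns gene_id and arm", call. = FALSE)
  keep <- df$arm %in% ARM_LEVELS
  if (any(!keep))
    xb_log("INFO", "read_catalog: dropped %d gene(s) outside arm vocabulary (%s)",
           sum(!keep), paste(unique(df$arm[!keep]), collapse = ", "))
  df <- df[keep, , drop = FALSE]
  gene_catalog(df$gene_id, df$arm)
}

parse_numeric_cells <- function(df, path, allow_na) {
  ids <- df[[1]]
  mat <- as.matrix(df[-1])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat),
                                dimnames = list(ids, colnames(mat))))
  bad <- is.na(num) & !(allow_na & mat %in% c("NA", ""))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-numeric cell '%s' at row %d (gene %s), column '%s'",
                 path, mat[idx[1], idx[2]], idx[1], ids[idx[1]],
                 colnames(mat)[idx[2]]), call. = FALSE)
  }
  num
}

read_sidecar <- function(meta) {
  if (is.character(meta) && length(meta) == 1) {
    if (grepl("\\.json$", meta)) jsonlite::read_json(meta, simplifyVector = TRUE)
    else yaml::read_yaml(meta)
  } else meta
}

#' Read an expression or binding matrix from TSV
#'
#' First column is \code{gene_id}; remaining columns are samples. Time-course
#' and binding matrices take a sidecar configuration (a list, or a path to a
#' JSON/YAML file): sample metadata for a time course, per-protein
#' \code{thresholds} and \code{roles} for a binding profile.
#'
#' Missing values are disallowed in atlas and time-course matrices and
#' allowed in binding matrices, where an \code{NA} cell means the gene was
#' not assessed for that protein. Negative values are an error for
#' intensities and accepted for binding scores (log-ratios).
#'
#' @param path TSV file (optionally gzip-compressed).
#' @param kind One of \code{"atlas"}, \code{"timecourse"}, \code{"binding"}.
#' @param meta Sidecar configuration; see Details.
#' @return An \code{\link{expression_atlas}}, \code{\link{time_course}} or
#'   \code{\link{binding_profile}}.
#' @export
read_matrix <- function(path, kind = c("atlas", "timecourse", "binding"),
                        meta = NULL) {
  kind <- match.arg(kind)
  df <- read_tsv_raw(path)
  if (ncol(df) < 2)
    stop(path, ": expected gene_id plus at least one sample column",
         call. = FALSE)
  num <- parse_numeric_cells(df, path, allow_na = kind == "binding")
  if (kind != "binding" && any(num < 0))
    stop(path, ": negative intensities are not allowed for kind=", kind,
         call. = FALSE)
  switch(kind,
    atlas = expression_atlas(num),
    timecourse = {
      meta <- read_sidecar(meta)
      if (is.null(meta$samples))
        stop("timecourse sidecar must provide $samples metadata", call. = FALSE)
      time_course(num, as.data.frame(meta$samples, stringsAsFactors = FALSE))
    },
    binding = {
      meta <- read_sidecar(meta)
      if (is.null(meta$thresholds) || is.null(meta$roles))
        stop("binding sidecar must provide $thresholds and $roles",
             call. = FALSE)
      binding_profile(num, unlist(meta$thresholds), unlist(meta$roles))
    })
}

#' Write a result table as TSV
#'
#' Header plus one row per record; numeric columns are serialized with six
#' significant digits; column order is taken from the input, so re-running on
#' the same records is byte-identical.
#'
#' @param records Data frame sharing one schema.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_result_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- records
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a JSON summary of headline statistics
#'
#' @param x Named list of scalars or simple structures.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Collapse a multi-probe table to gene level by per-gene median
#'
#' Probe-level tables (several rows per gene) are collapsed to one row per
#' gene by taking the column-wise median of that gene's rows; the number of
#' collapsed genes is logged. Input row order of first appearance is kept.
#'
#' @param df Data frame whose first column is \code{gene_id} and whose
#'   remaining columns are numeric.
#' @return Data frame with unique \code{gene_id}.
#' @export
collapse_by_gene <- function(df) {
  ids <- as.character(df[[1]])
  if (!anyDuplicated(ids)) return(df)
  first <- !duplicated(ids)
  ord <- ids[first]
  num <- as.matrix(df[-1])
  storage.mode(num) <- "double"
  med <- do.call(rbind, lapply(split(seq_along(ids), factor(ids, levels = ord)),
                               function(i) apply(num[i, , drop = FALSE], 2,
                                                 stats::median, na.rm = TRUE)))
  xb_log("INFO", "collapse_by_gene: %d probe rows collapsed to %d genes",
         length(ids), length(ord))
  out <- data.frame(gene_id = ord, med, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- names(df)
  rownames(out) <- NULL
  out
}

#' Write a gene catalog, matrix object or truth table as TSV
#'
#' Companion to the readers; produces files \code{\link{read_catalog}} and
#' \code{\link{read_matrix}} round-trip to serialized precision.
#'
#' @param x A \code{gene_catalog}, \code{expression_atlas},
#'   \code{time_course}, \code{binding_profile} or plain data frame.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_table_tsv <- function(x, path) {
  df <- if (inherits(x, "expression_atlas")) {
    data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "time_course") || inherits(x, "binding_profile")) {
    m <- if (inherits(x, "time_course")) x$values else x$scores
    data.frame(gene_id = rownames(m), m, check.names = FALSE,
               stringsAsFactors = FALSE)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
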