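# Small in-code fixtures shared across test files.

tiny_catalog <- function() {
  gene_catalog(paste0("g", 1:6), c("X", "2L", "2R", "3L", "3R", "4"))
}

# Atlas with known planted factors and no noise: gene gi has factor f[i]
# toward `target`, all other tissues at `base`.
planted_atlas <- function(factors, target = "testis",
                          panel = c("midgut", "head", "ovary"), base = 100) {
  n <- length(factors)
  tis <- c(target, panel)
  m <- matrix(base, n, length(tis), dimnames = list(paste0("g", seq_len(n)), tis))
  m[, target] <- base * factors
  expression_atlas(m)
}

# Two-condition time course built from explicit per-condition replicate
# values (log2 scale), for direct checks of the moderated t machinery.
two_point_tc <- function(ref, later, days = c(4L, 7L)) {
  stopifnot(ncol(ref) == ncol(later), nrow(ref) == nrow(later))
  vals <- cbind(ref, later)
  colnames(vals) <- c(paste0("d", days[1], "f_r", seq_len(ncol(ref))),
                     paste0("d", days[2], "f_r", seq_len(ncol(later))))
  rownames(vals) <- paste0("g", seq_len(nrow(ref)))
  meta <- data.frame(
    sample = colnames(vals),
    day = rep(days, times = c(ncol(ref), ncol(later))),
    stage = "feeding",
    replicate = c(seq_len(ncol(ref)), seq_len(ncol(later))),
    stringsAsFactors = FALSE)
  suppressWarnings(time_course(vals, meta, log2 = TRUE))
}

# Exact distribution of the on-arm count of a drawn set, by exhaustive
# enumeration of all C(n_genome, n_set) subsets; genes 1..n_arm are on the
# arm. Independent combinatorial oracle for the hypergeometric and Fisher
# tails.
enum_arm_count_dist <- function(n_genome, n_arm, n_set) {
  subsets <- utils::combn(n_genome, n_set)
  k <- colSums(subsets <= n_arm)
  counts <- tabulate(k + 1L, nbins = n_set + 1L)  # index k+1 holds count of k
  list(k = 0:n_set, counts = counts, total = ncol(subsets))
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
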