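#!/usr/bin/env Rscript
# Chromatin association: correlate developmental up-regulation with the
# binding of silencing- and activation-role proteins, summarize the
# inverse pattern, and compare bound-gene frequencies of the biased sets
# between the X and the autosomes.

suppressPackageStartupMessages(library(xbias))

src <- "results/synthetic"
catalog <- read_catalog(file.path(src, "catalog.tsv"))
atlas <- read_matrix(file.path(src, "atlas.tsv"), "atlas")
tc <- read_matrix(file.path(src, "timecourse.tsv"), "timecourse",
                  meta = file.path(src, "timecourse_meta.yaml"))
bp <- read_matrix(file.path(src, "binding.tsv"), "binding",
                  meta = file.path(src, "binding_meta.yaml"))

fc <- fold_change_vs_earliest(normalize_arrays(tc))
co <- expression_binding_correlation(fc, bp)
inv <- inverse_correlation_report(co)

dir.create("results", showWarnings = FALSE)
write_result_table(co, "results/binding_correlations.tsv")
write_result_json(list(by_role = inv$by_role,
                       inverse_pattern = inv$inverse_pattern),
                  "results/inverse_pattern.json")

# bound-gene frequencies of the testis-up-regulated set (the set carrying
# the planted binding structure), X versus autosomes
up <- upregulated_set(fc, 0.1)
enr <- do.call(rbind, lapply(colnames(bp$scores), function(pr) {
  be <- binding_enrichment(bp, pr, up, catalog)
  be$set <- "testis_upregulated"
  be
}))
write_result_table(enr, "results/binding_enrichment.tsv")

fin <- co[co$timepoint == "d10w", ]
cat(sprintf("final-timepoint correlations: silencing mean r %.3f, activation mean r %.3f\n",
            mean(fin$r[fin$role == "silencing"]),
            mean(fin$r[fin$role == "activation"])))
cat(sprintf("inverse correlation pattern: %s\n", inv$inverse_pattern))
x_dev <- mean(abs(enr$relative_frequency[enr$compartment == "X"] - 1),
              na.rm = TRUE)
a_dev <- mean(abs(enr$relative_frequency[enr$compartment == "autosomes"] - 1),
              na.rm = TRUE)
cat(sprintf("mean |relative frequency - 1| for up-regulated genes: X %.3f vs autosomes %.3f\n",
            x_dev, a_dev))
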