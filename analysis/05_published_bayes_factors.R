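#!/usr/bin/env Rscript
# Bayes factors from the published per-family root-restriction table.
#
# The package ships the reported log marginal likelihoods of root-restricted
# models for ten language families (inst/extdata/family_root_lml.tsv). This
# driver recomputes, for each family, the log Bayes factor of the
# best-supported root state against the runner-up — 2 x (best LML - second
# LML) — together with its evidence label.

suppressPackageStartupMessages(library(anchorphylo))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

path <- system.file("extdata", "family_root_lml.tsv",
                    package = "anchorphylo")
lml <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

rows <- lapply(split(lml, lml$family), function(d) {
  d <- d[order(d$lml, decreasing = TRUE), ]
  bf <- log_bayes_factor(d$lml[1], d$lml[2])
  data.frame(family = d$family[1], best_state = d$state[1],
             best_lml = d$lml[1], second_state = d$state[2],
             second_lml = d$lml[2], log_bf = round(bf$log_bf, 1),
             evidence = bf$label, stringsAsFactors = FALSE)
})
res <- do.call(rbind, rows)
res <- res[order(-res$log_bf), ]
print(res, row.names = FALSE)
write.table(res, file.path(out_dir, "published_root_bf.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nNote: only families whose table rows are printed at consistent",
    "precision yield the bracketed value exactly; see the methods",
    "vignette.\n")
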