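#!/usr/bin/env Rscript
# Maximum-likelihood ancestral-state reconstruction on a synthetic family.
#
# Fits the rates of the unconstrained model by maximum likelihood on a
# single tree and reconstructs the marginal state posterior at every
# internal node, then scores the reconstruction against the simulation's
# known internal-node states. Writes an annotated Newick whose node
# comments carry the per-state probabilities.

suppressPackageStartupMessages(library(anchorphylo))

seed <- 1L
out_dir <- "results/asr"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- make_family_preset("arawakan", seed = seed)  # 56 tips, 4 states
d <- sim_dataset(spec)

out <- asr_with_ml_rates(d$tree, d$matrix, rate_config(d$matrix$space))
cat("Fitted rates (", paste(out$config$pairs$name[out$config$mask],
                            collapse = " "), "):\n  ",
    paste(round(out$rates, 3), collapse = " "), "\n", sep = "")
cat("Log-likelihood at the optimum:", round(out$loglik, 3), "\n")

truth <- d$node_states[as.character(out$table$node)]
hits <- mean(out$table$map_state == truth)
cat(sprintf("Most-probable state matches the simulated truth at %.0f%% of %d internal nodes\n",
            100 * hits, nrow(out$table)))
root_row <- out$table[1, d$matrix$space$codes]
cat("Root reconstruction:",
    paste(sprintf("%s=%.3f", d$matrix$space$codes, as.numeric(root_row)),
          collapse = " "),
    "| true root", d$root_state, "\n")

write.table(out$table, file.path(out_dir, "node_states.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(write_asr_newick(d$tree, out$table),
           file.path(out_dir, "annotated_tree.nwk"))
export_state_tsv(d$matrix, file.path(out_dir, "tip_states.tsv"))
cat("Outputs written to", out_dir, "\n")
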