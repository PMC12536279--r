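#' Write a posterior chain as a tab-separated log
#'
#' One row per retained iteration: iteration number, log-likelihood, number
#' of rate bins, tree index, and one column per transition-rate parameter
#' (0 where the parameter is off). A self-describing header records the
#' settings and seed so a run is reproducible from its log.
#'
#' @param sample a \code{posterior_sample}.
#' @param path output path.
#' @export
write_chain_tsv <- function(sample, path) {
  stopifnot(inherits(sample, "posterior_sample"))
  con <- file(path, "w")
  on.exit(close(con))
  s <- sample$settings
  writeLines(c(
    sprintf("# anchorphylo chain log"),
    sprintf("# iterations=%d burnin=%d thinning=%d seed=%d rj=%s power=%g",
            s$iterations, s$burnin, s$thinning, s$seed, sample$rj,
            sample$power),
    sprintf("# rate_prior=exponential(mean %g) model_prior=uniform over configurations",
            sample$prior$rate_mean)), con)
  df <- data.frame(iteration = sample$iteration, loglik = sample$loglik,
                   n_bins = sample$n_bins, tree = sample$tree_index,
                   sample$rates, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export tip states for external mapping tools
#'
#' Writes a plain (taxon, state) TSV — the hand-off point for geographic
#' visualization, which this package deliberately does not do itself.
#'
#' @param matrix a [trait_matrix].
#' @param path output path.
#' @export
export_state_tsv <- function(matrix, path) {
  df <- data.frame(taxon = matrix$taxa, state = trait_state_strings(matrix),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
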