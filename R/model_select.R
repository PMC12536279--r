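#' Log Bayes factor from two log marginal likelihoods
#'
#' Twice the difference of log marginal likelihoods, the scale on which the
#' conventional evidence thresholds are stated: > 2 positive, 5--10 strong,
#' > 10 very strong evidence.
#'
#' @param lml_a,lml_b finite log marginal likelihoods (numbers or
#'   \code{lml_estimate} objects).
#' @return a \code{bayes_factor}: list with \code{lml_a}, \code{lml_b},
#'   \code{log_bf} \eqn{= 2(a - b)} and \code{label} (evidence label of the
#'   magnitude).
#' @examples
#' log_bayes_factor(-39.45, -40.46)$log_bf  # 2.02
#' @export
log_bayes_factor <- function(lml_a, lml_b) {
  if (inherits(lml_a, "lml_estimate")) lml_a <- lml_a$lml
  if (inherits(lml_b, "lml_estimate")) lml_b <- lml_b$lml
  if (!is.finite(lml_a) || !is.finite(lml_b))
    stop("log marginal likelihoods must be finite")
  log_bf <- 2 * (lml_a - lml_b)
  structure(list(lml_a = lml_a, lml_b = lml_b, log_bf = log_bf,
                 label = interpret_bf(abs(log_bf))),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("log BF = %.1f (%s evidence)\n", x$log_bf,
              if (x$label == "none") "no" else x$label))
  invisible(x)
}

#' Evidence label for a log Bayes factor
#'
#' Step function with breakpoints at 2, 5 and 10: \code{"none"} for values
#' up to and including 2, \code{"positive"} on (2, 5], \code{"strong"} on
#' (5, 10], \code{"very strong"} above 10.
#'
#' @param log_bf non-negative log Bayes factor (orient the comparison so the
#'   better model is first).
#' @return one of \code{"none"}, \code{"positive"}, \code{"strong"},
#'   \code{"very strong"}.
#' @export
interpret_bf <- function(log_bf) {
  if (is.na(log_bf)) stop("log_bf must be a number")
  if (log_bf < 0)
    stop("negative log Bayes factor: reorder the models so the better one is first")
  if (log_bf <= 2) "none"
  else if (log_bf <= 5) "positive"
  else if (log_bf <= 10) "strong"
  else "very strong"
}

#' Root-state restriction test
#'
#' Fossilizes the root to each candidate state in turn, estimates the
#' stepping-stone log marginal likelihood of each restricted model, and
#' reports which root state the data support, with the Bayes factor of the
#' best against the second-best restriction. This is the formal test of the
#' proto-language's numeral-system type.
#'
#' @param matrix a [trait_matrix].
#' @param trees a [tree_set] or \code{phylo}.
#' @param config a [rate_config] (or \code{NULL} for reversible jump).
#' @param prior a [prior_spec].
#' @param states state codes to test (default: all states of the space; a
#'   state with no tips is legal — the root may be unobserved at the tips).
#' @param ... stepping-stone settings passed to [stepping_stone()]
#'   (\code{K}, \code{iterations}, \code{burnin}, \code{seed}, ...).
#' @return a \code{root_test_table}: data frame \code{table} (state, code,
#'   lml), \code{best}, \code{second}, \code{bf} (a \code{bayes_factor}),
#'   \code{estimates} (per-state \code{lml_estimate}s).
#' @export
test_root_states <- function(matrix, trees, config = NULL,
                             prior = prior_spec(), states = NULL, ...) {
  space <- matrix$space
  if (is.null(states)) states <- space$codes
  estimates <- lapply(states, function(s) {
    stepping_stone(matrix, trees, prior, config = config,
                   root = root_prior("fixed", space, state = s), ...)
  })
  names(estimates) <- states
  lml <- vapply(estimates, `[[`, 0, "lml")
  ord <- order(lml, decreasing = TRUE)
  tab <- data.frame(state = space$labels[match(states, space$codes)],
                    code = states, lml = lml, row.names = NULL,
                    stringsAsFactors = FALSE)
  bf <- if (length(states) > 1)
    log_bayes_factor(lml[ord[1]], lml[ord[2]]) else NULL
  structure(list(table = tab, best = states[ord[1]],
                 second = if (length(states) > 1) states[ord[2]] else NA,
                 bf = bf, estimates = estimates),
            class = "root_test_table")
}

#' @export
print.root_test_table <- function(x, ...) {
  cat("Root-state restriction test (log marginal likelihoods):\n")
  for (i in seq_len(nrow(x$table))) {
    star <- x$table$code[i] == x$best
    cat(sprintf("  %-24s %s%.2f%s\n", x$table$state[i],
                if (star) "**" else "  ", x$table$lml[i],
                if (star && !is.null(x$bf))
                  sprintf("** (%.1f)", x$bf$log_bf) else ""))
  }
  invisible(x)
}

#' Iterative model reduction
#'
#' Starting from a (by default fully unconstrained) configuration, run a
#' reversible-jump analysis, drop the transition-rate parameters that are
#' regularly turned off in the posterior (inclusion below \code{threshold}),
#' and repeat on the reduced configuration, recording a stepping-stone log
#' marginal likelihood per round. Stops when no parameter drops, when
#' \code{max_rounds} is reached, or when the marginal likelihood worsens by
#' a Bayes factor above 2 (in which case the previous round's configuration
#' is the winner).
#'
#' @param matrix a [trait_matrix].
#' @param trees a [tree_set] or \code{phylo}.
#' @param prior a [prior_spec].
#' @param threshold drop parameters with posterior inclusion strictly below
#'   this (in (0, 1); \code{threshold = 0} never drops anything).
#' @param max_rounds maximum reduction rounds.
#' @param settings an [mcmc_settings] for the per-round RJ runs.
#' @param root root prior vector (default uniform).
#' @param ss_K,ss_iterations,ss_burnin stepping-stone settings per round.
#' @return a \code{reduction_trace}: list with \code{rounds} (each:
#'   \code{config}, \code{lml}, \code{inclusion}, \code{dropped}),
#'   \code{best_config}, \code{best_round}, \code{threshold}.
#' @export
iterative_reduction <- function(matrix, trees, prior = prior_spec(),
                                threshold = 0.5, max_rounds = 5,
                                settings = mcmc_settings(), root = NULL,
                                ss_K = 10, ss_iterations = 500,
                                ss_burnin = 200) {
  stopifnot(threshold >= 0, threshold < 1)
  cfg <- rate_config(matrix$space)
  rounds <- list()
  best_round <- 1L
  for (r in seq_len(max_rounds)) {
    sample <- run_mcmc(matrix, trees, prior, settings, rj = TRUE,
                       fixed_config = cfg, root = root)
    incl <- posterior_inclusion(sample)
    lml <- stepping_stone(matrix, trees, prior, config = cfg,
                          K = ss_K, iterations = ss_iterations,
                          burnin = ss_burnin,
                          seed = settings$seed + 1000L * r, root = root)
    drop <- cfg$mask & (incl < threshold)
    rounds[[r]] <- list(config = cfg, lml = lml$lml, inclusion = incl,
                        dropped = cfg$pairs$name[drop])
    if (r > 1) {
      worse <- log_bayes_factor(rounds[[r - 1]]$lml, rounds[[r]]$lml)
      if (worse$log_bf > 2) { best_round <- r - 1L; break }
      best_round <- if (rounds[[r]]$lml >= rounds[[best_round]]$lml) r
                    else best_round
    }
    if (!any(drop)) break
    new_mask <- cfg$mask & !drop
    if (!any(new_mask)) {
      # an empty model only makes sense for constant data
      Q0 <- base::matrix(0, matrix$space$k, matrix$space$k)
      tr1 <- as_tree_set(trees)$trees[[1]]
      ll0 <- prune_loglik(tr1, matrix, Q0,
                          if (is.null(root)) NULL else root)
      if (!is.finite(ll0)) {
        cond <- errorCondition(
          "all transition-rate parameters were dropped but the data are not constant",
          trace = rounds, class = "anchorphylo_reduction_error")
        stop(cond)
      }
    }
    cfg <- rate_config(matrix$space, mask = new_mask)
  }
  structure(list(rounds = rounds, best_config = rounds[[best_round]]$config,
                 best_round = best_round, threshold = threshold),
            class = "reduction_trace")
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat("Iterative model reduction (inclusion threshold", x$threshold, "):\n")
  for (r in seq_along(x$rounds)) {
    rd <- x$rounds[[r]]
    cat(sprintf("  round %d: %d parameters on, LML %.2f, dropped: %s\n",
                r, sum(rd$config$mask), rd$lml,
                if (length(rd$dropped)) paste(rd$dropped, collapse = " ")
                else "(none)"))
  }
  cat("  best: round", x$best_round, "with",
      sum(x$best_config$mask), "parameters\n")
  invisible(x)
}

#' Compare candidate models by stepping-stone marginal likelihood
#'
#' Estimates a log marginal likelihood per named configuration (e.g. the two
#' orientations of a cyclical model against a reduced model), ranks them, and
#' reports all pairwise log Bayes factors with evidence labels.
#'
#' @param models named list of [rate_config]s (>= 2).
#' @param matrix a [trait_matrix].
#' @param trees a [tree_set] or \code{phylo}.
#' @param prior a [prior_spec].
#' @param ... stepping-stone settings passed to [stepping_stone()].
#' @return a \code{model_comparison}: \code{table} (name, n_parameters, lml,
#'   rank), \code{pairwise} (matrix of log BFs, row minus column),
#'   \code{estimates}.
#' @export
compare_models <- function(models, matrix, trees, prior = prior_spec(), ...) {
  stopifnot(length(models) >= 2, !is.null(names(models)))
  estimates <- lapply(models, function(cfg)
    stepping_stone(matrix, trees, prior, config = cfg, ...))
  lml <- vapply(estimates, `[[`, 0, "lml")
  tab <- data.frame(model = names(models),
                    n_parameters = vapply(models, count_free_parameters, 0L),
                    lml = lml, rank = rank(-lml, ties.method = "min"),
                    row.names = NULL, stringsAsFactors = FALSE)
  pw <- outer(lml, lml, function(a, b) 2 * (a - b))
  dimnames(pw) <- list(names(models), names(models))
  structure(list(table = tab[order(tab$rank), ], pairwise = pw,
                 estimates = estimates), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (stepping-stone log marginal likelihoods):\n")
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %d. %-20s %2d par  LML %.2f\n", x$table$rank[i],
                x$table$model[i], x$table$n_parameters[i], x$table$lml[i]))
  }
  invisible(x)
}

#' Render a model report as a directed edge list
#'
#' Describes a rate configuration the way best-model diagrams are drawn:
#' on-parameters as directed edges between states (with rate summaries when
#' a posterior sample or rate vector is supplied), off-parameters listed
#' separately.
#'
#' @param config a [rate_config].
#' @param rates optional per-bin rate vector (point estimates).
#' @param sample optional \code{posterior_sample} for posterior mean rates
#'   and inclusion probabilities.
#' @return a \code{model_report}: list with \code{edges} (data frame: from,
#'   to, name, bin, and rate/inclusion columns when available) and
#'   \code{off} (character vector of off-parameter names).
#' @export
render_model_report <- function(config, rates = NULL, sample = NULL) {
  stopifnot(inherits(config, "rate_config"))
  on <- which(config$mask)
  sp <- config$space
  edges <- data.frame(from = sp$labels[config$pairs$from[on]],
                      to = sp$labels[config$pairs$to[on]],
                      name = config$pairs$name[on],
                      bin = config$bins[on],
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(rates)) edges$rate <- rates[config$bins[on]]
  if (!is.null(sample)) {
    edges$mean_rate <- colMeans(sample$rates)[on]
    if (sample$rj) edges$inclusion <- posterior_inclusion(sample)[on]
  }
  structure(list(edges = edges, off = config$pairs$name[!config$mask],
                 space = sp), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Model report:", nrow(x$edges), "transition(s) on\n")
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      extra <- if (!is.null(x$edges$mean_rate))
        sprintf("  mean rate %.3f", x$edges$mean_rate[i])
      else if (!is.null(x$edges$rate))
        sprintf("  rate %.3f", x$edges$rate[i]) else ""
      cat(sprintf("  %s: %s -> %s%s\n", x$edges$name[i], x$edges$from[i],
                  x$edges$to[i], extra))
    }
  }
  if (length(x$off)) cat("  off:", paste(x$off, collapse = " "), "\n")
  invisible(x)
}
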