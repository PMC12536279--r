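#' Prior specification for the Bayesian machinery
#'
#' Transition rates carry independent exponential priors with a stated mean
#' (default 10); the model prior over (mask, bin-partition) configurations is
#' uniform, so it cancels from all acceptance ratios.
#'
#' @param rate_mean mean of the exponential rate prior (> 0).
#' @return a \code{prior_spec} list.
#' @export
prior_spec <- function(rate_mean = 10) {
  stopifnot(rate_mean > 0)
  structure(list(rate_mean = rate_mean), class = "prior_spec")
}

#' MCMC settings
#'
#' @param iterations total iterations.
#' @param burnin iterations discarded (proposal scales adapt only here).
#' @param thinning keep every \code{thinning}-th post-burn-in iteration.
#' @param seed integer seed driving proposals, tree draws and rate
#'   initialization.
#' @return an \code{mcmc_settings} list.
#' @export
mcmc_settings <- function(iterations = 20000, burnin = 5000, thinning = 10,
                          seed = 1) {
  stopifnot(iterations > burnin, burnin >= 0, thinning >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed)), class = "mcmc_settings")
}

# precomputed pruning inputs for one tree (postorder edges, tip partials)
ctm_context <- function(tree, matrix) {
  tp <- tip_partial_matrix(tree, matrix)
  post <- ape::reorder.phylo(tree, "postorder")
  list(edge = post$edge, lengths = post$edge.length, tp = tp,
       n_internal = tree$Nnode, root = post$edge[nrow(post$edge), 1])
}

ctx_loglik <- function(ctx, Q, prior) {
  prune_loglik_cpp(ctx$edge, ctx$lengths, ctx$tp, Q, prior,
                   ctx$n_internal, ctx$root)
}

# ---- reversible-jump bookkeeping ---------------------------------------
# chain configuration: integer vector `bins` over the m ordered state pairs
# (0 = off, b = bin id) and numeric `rates`, one per live bin id.

# remove parameter i from its bin; delete the bin if it empties, compacting
# higher bin ids (rates stay aligned). Returns the possibly shifted id map.
rj_drop_param <- function(bins, rates, i) {
  b <- bins[i]
  bins[i] <- 0L
  dropped <- FALSE
  if (b > 0L && !any(bins == b)) {
    rates <- rates[-b]
    bins[bins > b] <- bins[bins > b] - 1L
    dropped <- TRUE
  }
  list(bins = bins, rates = rates, emptied = dropped, old_bin = b)
}

# ---- the sampler --------------------------------------------------------

#' Run (reversible-jump) MCMC over transition rates
#'
#' Metropolis--Hastings sampling of the posterior over per-bin transition
#' rates and — when \code{rj = TRUE} — over the rate configuration itself
#' (which parameters are off, and how the on-parameters share bins). Moves:
#' multiplicative log-normal random-walk updates of a single bin's rate
#' (scale auto-tuned during burn-in towards 20--40\% acceptance), a
#' reassign move (a parameter jumps to off, to another bin, or to a fresh
#' singleton bin whose rate is drawn from the prior), and explicit bin
#' split/merge moves; dimension-changing proposals draw new rates from the
#' prior so the Hastings ratios stay simple and exact. With a tree sample, a
#' uniformly proposed tree index is accepted by its likelihood ratio each
#' iteration (\code{tree_mode = "mh"}), or the index advances
#' deterministically through the sample (\code{tree_mode = "rotate"}, which
#' forces every tree to contribute).
#'
#' @param matrix a [trait_matrix].
#' @param trees a [tree_set] or single \code{phylo}.
#' @param prior a [prior_spec].
#' @param settings an [mcmc_settings].
#' @param rj reversible jump over configurations (\code{TRUE}) or fixed
#'   configuration (\code{FALSE}, requires \code{fixed_config}).
#' @param fixed_config a [rate_config] used when \code{rj = FALSE}, and as
#'   the start/ceiling configuration when \code{rj = TRUE} (default: fully
#'   unconstrained with singleton bins).
#' @param root root prior vector (default uniform over the matrix's states).
#' @param power power \eqn{\beta} on the likelihood (used internally by the
#'   stepping-stone sampler; \code{power = 0} samples the prior).
#' @param tree_mode \code{"mh"} or \code{"rotate"} (see above).
#' @return a \code{posterior_sample}: list with \code{rates} (kept
#'   iterations x parameters, 0 where off), \code{bins} (same shape, bin
#'   ids), \code{loglik}, \code{tree_index}, \code{n_bins},
#'   \code{iteration}, plus \code{config} (template), \code{space},
#'   \code{rj}, \code{settings}, \code{prior}, \code{accept} rates.
#' @export
run_mcmc <- function(matrix, trees, prior = prior_spec(),
                     settings = mcmc_settings(), rj = TRUE,
                     fixed_config = NULL, root = NULL, power = 1,
                     tree_mode = c("mh", "rotate")) {
  tree_mode <- match.arg(tree_mode)
  trees <- as_tree_set(trees)
  stopifnot(inherits(prior, "prior_spec"), inherits(settings, "mcmc_settings"))
  space <- matrix$space
  if (is.null(root)) root <- root_prior("uniform", space)
  template <- if (is.null(fixed_config)) rate_config(space) else fixed_config
  if (!rj && is.null(fixed_config))
    stop("rj = FALSE requires fixed_config")
  m <- nrow(template$pairs)
  ctxs <- lapply(trees$trees, ctm_context, matrix = matrix)
  rate_mean <- prior$rate_mean

  # likelihood of the all-off model: finite iff the data admit a constant state
  if (!rj && template$n_bins == 0L) {
    ll0 <- ctx_loglik(ctxs[[1]], base::matrix(0, space$k, space$k), root)
    if (!is.finite(ll0))
      stop("configuration has zero on-parameters but the data are not constant")
  }

  n_keep <- (settings$iterations - settings$burnin) %/% settings$thinning
  rec_rates <- base::matrix(0, n_keep, m,
                            dimnames = list(NULL, template$pairs$name))
  rec_bins <- base::matrix(0L, n_keep, m,
                           dimnames = list(NULL, template$pairs$name))
  rec_ll <- numeric(n_keep)
  rec_tree <- integer(n_keep)
  rec_nbins <- integer(n_keep)
  rec_iter <- integer(n_keep)

  acc <- c(rate = 0, rate_n = 0, rj = 0, rj_n = 0, tree = 0, tree_n = 0)

  with_local_seed(settings$seed, {
    bins <- template$bins
    rates <- if (template$n_bins > 0)
      stats::rexp(template$n_bins, 1 / rate_mean) else numeric()
    tree_i <- 1L
    sigma <- 1.0
    loglik_of <- function(bins, rates, ti) {
      if (power == 0) return(0)
      cfg_rates <- numeric(m)
      on <- bins > 0L
      cfg_rates[on] <- rates[bins[on]]
      Q <- base::matrix(0, space$k, space$k)
      pr <- template$pairs
      Q[cbind(pr$from, pr$to)] <- cfg_rates
      diag(Q) <- -rowSums(Q)
      ll <- ctx_loglik(ctxs[[ti]], Q, root)
      # a log-likelihood above 0 is numerically impossible for discrete
      # data: treat overflow garbage as an invalid (always rejected) state
      if (is.nan(ll) || ll > 1e-8) ll <- -Inf
      ll
    }
    ll <- loglik_of(bins, rates, tree_i)
    log_rate_prior <- function(r) sum(stats::dexp(r, 1 / rate_mean, log = TRUE))
    keep_i <- 0L

    for (iter in seq_len(settings$iterations)) {
      # tree handling
      if (trees$n_trees > 1L) {
        if (tree_mode == "rotate") {
          tree_i <- (iter %% trees$n_trees) + 1L
          ll <- loglik_of(bins, rates, tree_i)
        } else {
          tj <- sample.int(trees$n_trees, 1L)
          if (tj != tree_i) {
            llj <- loglik_of(bins, rates, tj)
            acc["tree_n"] <- acc["tree_n"] + 1
            if (log(stats::runif(1)) < power * (llj - ll)) {
              tree_i <- tj; ll <- llj; acc["tree"] <- acc["tree"] + 1
            }
          }
        }
      }

      # move-type choice must not depend on the current state, or the
      # empty-configuration state gets double outflow and is undersampled
      do_rj <- rj && stats::runif(1) < 0.5
      if (!do_rj && length(rates) > 0L) {
        # within-model multiplicative log-normal update of one bin's rate
        j <- sample.int(length(rates), 1L)
        prop <- rates
        # mix a prior-independence proposal (prior and proposal densities
        # cancel; decorrelates the chain, especially near the prior) with
        # the multiplicative log-normal walk
        indep <- stats::runif(1) < 0.25
        llp <- -Inf
        la <- if (indep) {
          prop[j] <- stats::rexp(1, 1 / rate_mean)
          llp <- loglik_of(bins, prop, tree_i)
          power * (llp - ll)
        } else {
          prop[j] <- rates[j] * exp(sigma * stats::rnorm(1))
          if (!is.finite(prop[j]) || prop[j] <= 0) -Inf else {
            llp <- loglik_of(bins, prop, tree_i)
            power * (llp - ll) +
              stats::dexp(prop[j], 1 / rate_mean, log = TRUE) -
              stats::dexp(rates[j], 1 / rate_mean, log = TRUE) +
              log(prop[j] / rates[j])  # Hastings term of the log-scale walk
          }
        }
        if (is.nan(la)) la <- -Inf
        acc["rate_n"] <- acc["rate_n"] + 1
        if (log(stats::runif(1)) < la) {
          rates <- prop; ll <- llp; acc["rate"] <- acc["rate"] + 1
        }
        if (iter <= settings$burnin && acc["rate_n"] %% 50 == 0) {
          rate_acc <- acc["rate"] / acc["rate_n"]
          if (rate_acc > 0.4) sigma <- min(sigma * 1.3, 25)
          if (rate_acc < 0.2) sigma <- max(sigma / 1.3, 1e-3)
        }
      } else if (do_rj) {
        move <- sample(c("reassign", "split", "merge"), 1L)
        res <- switch(move,
          reassign = rj_propose_reassign(bins, rates, rate_mean,
                                         allowed = template$mask),
          split = rj_propose_split(bins, rates, rate_mean),
          merge = rj_propose_merge(bins, rates, rate_mean))
        if (!is.null(res)) {
          llp <- loglik_of(res$bins, res$rates, tree_i)
          la <- power * (llp - ll) + res$log_hastings
          acc["rj_n"] <- acc["rj_n"] + 1
          if (is.finite(llp) && log(stats::runif(1)) < la) {
            bins <- res$bins; rates <- res$rates; ll <- llp
            acc["rj"] <- acc["rj"] + 1
          }
        }
      }

      if (iter > settings$burnin &&
          (iter - settings$burnin) %% settings$thinning == 0L) {
        keep_i <- keep_i + 1L
        on <- bins > 0L
        rr <- numeric(m); rr[on] <- rates[bins[on]]
        rec_rates[keep_i, ] <- rr
        rec_bins[keep_i, ] <- bins
        rec_ll[keep_i] <- if (power == 0) loglik_of_full(ctxs[[tree_i]],
          rr, template, space, root) else ll
        rec_tree[keep_i] <- tree_i
        rec_nbins[keep_i] <- length(rates)
        rec_iter[keep_i] <- iter
      }
    }
  })

  structure(list(rates = rec_rates, bins = rec_bins, loglik = rec_ll,
                 tree_index = rec_tree, n_bins = rec_nbins,
                 iteration = rec_iter, config = template, space = space,
                 rj = rj, settings = settings, prior = prior,
                 power = power, tree_mode = tree_mode,
                 accept = acc), class = "posterior_sample")
}

# full-likelihood evaluation from a per-parameter rate vector (records the
# data likelihood even when the chain targets the prior, power = 0)
loglik_of_full <- function(ctx, rr, template, space, root) {
  Q <- base::matrix(0, space$k, space$k)
  Q[cbind(template$pairs$from, template$pairs$to)] <- rr
  diag(Q) <- -rowSums(Q)
  ctx_loglik(ctx, Q, root)
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample:", nrow(x$rates), "kept iterations,",
      ncol(x$rates), "rate parameters,",
      if (x$rj) "reversible jump on" else "fixed configuration", "\n")
  cat("  mean log-likelihood:", round(mean(x$loglik), 3),
      " mean bins:", round(mean(x$n_bins), 2), "\n")
  invisible(x)
}

# -- RJ proposal kernels; each returns NULL (impossible) or
#    list(bins, rates, log_hastings) --------------------------------------

# parameter i jumps to off / another existing bin / a fresh singleton bin.
# The set of other parameters' bins is unchanged, so the uniform-destination
# proposal is symmetric and the Hastings term is 0 (prior draws for new
# rates cancel against the rate prior).
rj_propose_reassign <- function(bins, rates, rate_mean,
                                allowed = rep(TRUE, length(bins))) {
  cand <- which(allowed)
  i <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  others <- bins[-i]
  other_ids <- unique(others[others > 0L])
  a <- bins[i]
  cur <- if (a == 0L) 0L else if (a %in% other_ids) a else -1L
  dests <- setdiff(c(0L, other_ids, -1L), cur)
  d <- if (length(dests) == 1L) dests else dests[sample.int(length(dests), 1L)]
  dr <- rj_drop_param(bins, rates, i)
  bins <- dr$bins; rates <- dr$rates
  if (dr$emptied && d > dr$old_bin) d <- d - 1L  # id shifted by compaction
  if (d == -1L) {
    rates <- c(rates, stats::rexp(1, 1 / rate_mean))
    bins[i] <- length(rates)
  } else if (d > 0L) {
    bins[i] <- d
  }
  list(bins = bins, rates = rates, log_hastings = 0)
}

# split a multi-member bin into two non-empty parts, both rates redrawn from
# the prior; pairs with the merge move below
rj_propose_split <- function(bins, rates, rate_mean) {
  sizes <- tabulate(bins[bins > 0L], nbins = length(rates))
  multi <- which(sizes >= 2L)
  if (!length(multi)) return(NULL)
  b <- if (length(multi) == 1L) multi else multi[sample.int(length(multi), 1L)]
  members <- which(bins == b)
  nb <- length(members)
  repeat {  # uniform over the 2^(nb-1) - 1 unordered non-trivial splits
    flip <- stats::runif(nb) < 0.5
    if (any(flip) && !all(flip)) break
  }
  new_rates <- rates
  new_rates[b] <- stats::rexp(1, 1 / rate_mean)
  new_rates <- c(new_rates, stats::rexp(1, 1 / rate_mean))
  new_bins <- bins
  new_bins[members[flip]] <- length(new_rates)
  B <- length(rates)
  # forward: choose bin (1/|multi|) then split (1/(2^(nb-1)-1));
  # reverse: merge chooses this pair among C(B+1, 2)
  log_h <- log(length(multi)) + log(2^(nb - 1) - 1) - log(choose(B + 1, 2))
  list(bins = new_bins, rates = new_rates, log_hastings = log_h)
}

# merge two bins into one, rate redrawn from the prior; pairs with split
rj_propose_merge <- function(bins, rates, rate_mean) {
  B <- length(rates)
  if (B < 2L) return(NULL)
  pair <- sample.int(B, 2L)
  b1 <- min(pair); b2 <- max(pair)
  n_merged <- sum(bins == b1) + sum(bins == b2)
  new_bins <- bins
  new_bins[new_bins == b2] <- b1
  new_rates <- rates
  new_rates[b1] <- stats::rexp(1, 1 / rate_mean)
  new_rates <- new_rates[-b2]
  new_bins[new_bins > b2] <- new_bins[new_bins > b2] - 1L
  sizes <- tabulate(new_bins[new_bins > 0L], nbins = length(new_rates))
  n_multi <- sum(sizes >= 2L)
  log_h <- log(choose(B, 2)) - log(n_multi) - log(2^(n_merged - 1) - 1)
  list(bins = new_bins, rates = new_rates, log_hastings = log_h)
}

#' Posterior inclusion probabilities of rate parameters
#'
#' The fraction of retained iterations in which each of the k^2 - k ordered
#' transition-rate parameters carries a nonzero rate. Parameters that are
#' regularly turned off in the posterior (low inclusion) are the candidates
#' for removal during iterative model reduction.
#'
#' @param sample a reversible-jump \code{posterior_sample}.
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
posterior_inclusion <- function(sample) {
  stopifnot(inherits(sample, "posterior_sample"))
  if (!sample$rj) stop("posterior_inclusion needs a reversible-jump sample")
  colMeans(sample$bins > 0L)
}

#' Convergence diagnostics for a posterior sample
#'
#' Reports the Pearson correlation between the retained log-likelihood trace
#' and the iteration number (a drifting chain has not converged), the
#' effective sample size of the log-likelihood and of each rate parameter
#' (initial-positive-sequence autocorrelation estimator), and pass/warn
#' flags at the configured thresholds.
#'
#' @param sample a \code{posterior_sample} of length >= 10.
#' @param cor_warn warn when |correlation| exceeds this (default 0.2).
#' @param ess_warn warn when the log-likelihood ESS is below this (default
#'   100).
#' @return list with \code{lik_iter_cor}, \code{ess} (named vector),
#'   \code{pass}, \code{warnings} (character).
#' @export
convergence_report <- function(sample, cor_warn = 0.2, ess_warn = 100) {
  stopifnot(inherits(sample, "posterior_sample"))
  ll <- sample$loglik
  if (length(ll) < 10) stop("need at least 10 retained iterations")
  r <- if (stats::sd(ll) == 0) 0 else stats::cor(ll, seq_along(ll))
  ess <- c(loglik = ess_ips(ll),
           vapply(seq_len(ncol(sample$rates)), function(j)
             ess_ips(sample$rates[, j]), 0))
  names(ess)[-1] <- colnames(sample$rates)
  warnings <- character()
  if (abs(r) > cor_warn)
    warnings <- c(warnings, sprintf(
      "log-likelihood correlates with iteration (r = %.3f): chain may be drifting", r))
  if (ess[["loglik"]] < ess_warn)
    warnings <- c(warnings, sprintf(
      "log-likelihood ESS %.0f below %g", ess[["loglik"]], ess_warn))
  list(lik_iter_cor = r, ess = ess, pass = length(warnings) == 0L,
       warnings = warnings)
}

# effective sample size by the initial positive sequence estimator
ess_ips <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (t in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[t] + ac[t + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}
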