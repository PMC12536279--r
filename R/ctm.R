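#' Transition probabilities over a branch
#'
#' The probability of change between every pair of states along a branch of
#' length \code{t} under generator \code{Q}: the matrix exponential
#' \eqn{P(t) = e^{Qt}}, computed by scaling-and-squaring. Rows sum to one.
#'
#' @param Q k x k generator matrix (rows sum to zero).
#' @param t non-negative branch length.
#' @return k x k row-stochastic matrix.
#' @examples
#' sp <- state_space(c("a", "b"))
#' Q <- build_q(0.5, rate_config(sp, bins = c(1, 1)))
#' transition_probs(Q, 1)[1, 1]  # (1 + exp(-1)) / 2
#' @export
transition_probs <- function(Q, t) {
  if (t < 0) stop("branch length t must be >= 0")
  P <- expm_ctm(Q, t)
  P[P < 0] <- 0  # clip tiny negative round-off
  dimnames(P) <- dimnames(Q)
  P
}

# n x k matrix of 0/1 tip partial likelihoods in the tree's tip order;
# ambiguity sets put 1 on each allowed state, missing data on all states
tip_partial_matrix <- function(tree, matrix) {
  stopifnot(inherits(matrix, "trait_matrix"))
  idx <- match(tree$tip.label, matrix$taxa)
  if (anyNA(idx)) {
    stop("tree tips without trait data: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "),
         " (see match_taxa())")
  }
  k <- matrix$space$k
  out <- base::matrix(0, length(idx), k)
  for (i in seq_along(idx)) out[i, matrix$states[[idx[i]]]] <- 1
  rownames(out) <- tree$tip.label
  out
}

#' Pruning log-likelihood of tip states on a tree
#'
#' Exact log-likelihood of the observed tip states under a continuous-time
#' Markov model, computed by the post-order pruning recursion that
#' marginalizes over all internal-node states. Polytomies are handled
#' natively (the recursion multiplies over all children of a node, any
#' arity); ambiguous or missing tips contribute partial likelihood 1 on each
#' allowed state; per-node rescaling guards against underflow on large
#' trees.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param matrix a [trait_matrix] covering every tip.
#' @param Q generator matrix over the matrix's state space.
#' @param prior root prior probability vector (see [root_prior()]); defaults
#'   to uniform.
#' @return the log-likelihood (scalar; \code{-Inf} if the data are
#'   impossible under \code{Q}).
#' @export
prune_loglik <- function(tree, matrix, Q, prior = NULL) {
  if (is.null(prior)) prior <- root_prior("uniform", matrix$space)
  tp <- tip_partial_matrix(tree, matrix)
  n <- length(tree$tip.label)
  if (n == 1L) {
    # single tip: likelihood is the prior mass transported down one branch
    P <- transition_probs(Q, tree$edge.length[1])
    return(log(sum((prior %*% P) * tp[1, ])))
  }
  post <- ape::reorder.phylo(tree, "postorder")
  root <- post$edge[nrow(post$edge), 1]
  prune_loglik_cpp(post$edge, post$edge.length, tp, Q, prior,
                   tree$Nnode, root)
}

#' Pruning log-likelihood averaged over a tree set
#'
#' Mean of per-tree likelihoods (not log-likelihoods): trees in a posterior
#' sample carry equal weight, so the model likelihood is the average of the
#' per-tree likelihoods. Computed by log-sum-exp.
#'
#' @param trees a [tree_set] (or single \code{phylo}).
#' @inheritParams prune_loglik
#' @return log of the mean likelihood across trees.
#' @export
prune_loglik_treeset <- function(trees, matrix, Q, prior = NULL) {
  trees <- as_tree_set(trees)
  ll <- vapply(trees$trees, prune_loglik, 0, matrix = matrix, Q = Q,
               prior = prior)
  log_mean_exp(ll)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Maximum-likelihood rate estimation
#'
#' Maximizes the pruning log-likelihood over the free rates of a
#' configuration by bounded quasi-Newton search (L-BFGS-B, lower bound 0);
#' boundary estimates of exactly zero are legal (e.g. constant data). Used
#' for the point estimates that feed ancestral-state visualization; Bayesian
#' machinery lives in [run_mcmc()].
#'
#' @param tree a rooted \code{phylo}.
#' @param matrix a [trait_matrix].
#' @param config a [rate_config] with at least one on-parameter.
#' @param prior root prior vector (default uniform).
#' @param init initial rate value(s) (recycled over bins).
#' @param upper upper bound for rates during search.
#' @param control list passed to [stats::optim()].
#' @return list with \code{rates} (per bin), \code{loglik}, \code{converged},
#'   \code{config}.
#' @export
ml_fit <- function(tree, matrix, config, prior = NULL, init = 1,
                   upper = 1e3, control = list()) {
  stopifnot(inherits(config, "rate_config"))
  if (config$n_bins == 0L) stop("ml_fit needs at least one on-parameter")
  if (is.null(prior)) prior <- root_prior("uniform", matrix$space)
  nb <- config$n_bins
  fn <- function(r) {
    ll <- prune_loglik(tree, matrix, build_q(r, config), prior)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ctl <- utils::modifyList(list(maxit = 500), control)
  fit <- stats::optim(rep(init, length.out = nb), fn, method = "L-BFGS-B",
                      lower = 0, upper = upper, control = ctl)
  list(rates = fit$par, loglik = -fit$value,
       converged = fit$convergence == 0, config = config)
}
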