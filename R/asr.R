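#' Marginal ancestral-state reconstruction
#'
#' Exact marginal posterior probability of each state at every internal node
#' under fixed rates, via the inside--outside (up--down) algorithm: the up
#' pass computes each node's conditional likelihood of the data below it
#' (the pruning partials), the down pass the joint probability of the data
#' outside it, and the per-node marginal is their normalized product. The
#' root row equals the normalized mixture of fixed-root likelihoods.
#'
#' @param tree a rooted \code{phylo} (>= 2 tips).
#' @param matrix a [trait_matrix].
#' @param Q generator matrix.
#' @param prior root prior vector (default uniform).
#' @return a \code{node_state_table}: data frame with one row per internal
#'   node (\code{node} id as in the \code{phylo}), a probability column per
#'   state code, and \code{map_state} (most probable state code). Rows sum
#'   to 1.
#' @export
marginal_asr <- function(tree, matrix, Q, prior = NULL) {
  validate_tree(tree, "marginal_asr")
  space <- matrix$space
  k <- space$k
  if (is.null(prior)) prior <- root_prior("uniform", space)
  tp <- tip_partial_matrix(tree, matrix)
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  n_edge <- nrow(post$edge)
  root <- post$edge[n_edge, 1]
  ntot <- n + tree$Nnode

  # up pass: rescaled partials and per-edge child messages
  partial <- base::matrix(1, ntot, k)
  partial[seq_len(n), ] <- tp
  P_edge <- vector("list", n_edge)
  M_edge <- base::matrix(0, n_edge, k)  # M[e, s_parent]
  for (e in seq_len(n_edge)) {
    parent <- post$edge[e, 1]; child <- post$edge[e, 2]
    cp <- partial[child, ]
    m <- max(cp)
    if (m <= 0) stop("data impossible under Q: zero partial likelihood")
    cp <- cp / m
    partial[child, ] <- cp
    P <- transition_probs(Q, post$edge.length[e])
    P_edge[[e]] <- P
    M_edge[e, ] <- as.numeric(P %*% cp)
    partial[parent, ] <- partial[parent, ] * M_edge[e, ]
  }
  partial[root, ] <- partial[root, ] / max(partial[root, ])

  # down pass: outside probabilities, preorder (reverse postorder)
  child_edges <- split(seq_len(n_edge), post$edge[, 1])
  D <- base::matrix(0, ntot, k)
  D[root, ] <- prior
  for (e in rev(seq_len(n_edge))) {
    parent <- post$edge[e, 1]; child <- post$edge[e, 2]
    sibs <- setdiff(child_edges[[as.character(parent)]], e)
    S <- D[parent, ]
    for (e2 in sibs) S <- S * M_edge[e2, ]
    Dc <- as.numeric(S %*% P_edge[[e]])
    mx <- max(Dc)
    D[child, ] <- if (mx > 0) Dc / mx else Dc
  }

  nodes <- sort(unique(post$edge[, 1]))  # internal node ids
  probs <- base::matrix(0, length(nodes), k,
                        dimnames = list(NULL, space$codes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    p <- D[v, ] * partial[v, ]
    probs[i, ] <- p / sum(p)
  }
  out <- data.frame(node = nodes, probs,
                    map_state = space$codes[max.col(probs, "first")],
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("node_state_table", "data.frame")
  attr(out, "space") <- space
  attr(out, "root") <- root
  out
}

#' Ancestral states under maximum-likelihood rates
#'
#' Convenience composition: fit the configuration's rates by maximum
#' likelihood ([ml_fit()]), then reconstruct marginal ancestral states under
#' the fitted generator. These point reconstructions serve visualization and
#' exploratory reading of within-family patterns; formal root-state tests
#' use [test_root_states()].
#'
#' @inheritParams ml_fit
#' @return list with \code{table} (a \code{node_state_table}), \code{rates},
#'   \code{loglik}, \code{config}.
#' @export
asr_with_ml_rates <- function(tree, matrix, config, prior = NULL, ...) {
  fit <- ml_fit(tree, matrix, config, prior = prior, ...)
  Q <- build_q(fit$rates, config)
  list(table = marginal_asr(tree, matrix, Q, prior = prior),
       rates = fit$rates, loglik = fit$loglik, config = config)
}

#' Average ancestral reconstructions over a tree set
#'
#' Extension beyond single-tree reconstruction: computes [marginal_asr()] on
#' every tree of a set and averages node posteriors across trees for nodes
#' identified by their tip-set bipartition (a node "matches" across trees
#' when the same set of tips descends from it). Nodes absent from a tree
#' simply do not contribute to that bipartition's average.
#'
#' @param trees a [tree_set].
#' @param matrix a [trait_matrix].
#' @param Q generator matrix.
#' @param prior root prior vector.
#' @return data frame: \code{clade} (sorted, comma-joined tip labels), one
#'   probability column per state, \code{n_trees} supporting the clade.
#' @export
asr_average_treeset <- function(trees, matrix, Q, prior = NULL) {
  trees <- as_tree_set(trees)
  space <- matrix$space
  acc <- new.env(parent = emptyenv())
  for (tr in trees$trees) {
    tab <- marginal_asr(tr, matrix, Q, prior)
    post <- ape::reorder.phylo(tr, "postorder")
    n <- length(tr$tip.label)
    below <- vector("list", n + tr$Nnode)
    for (i in seq_len(n)) below[[i]] <- tr$tip.label[i]
    for (e in seq_len(nrow(post$edge))) {
      p <- post$edge[e, 1]; ch <- post$edge[e, 2]
      below[[p]] <- c(below[[p]], below[[ch]])
    }
    for (i in seq_len(nrow(tab))) {
      key <- paste(sort(below[[tab$node[i]]]), collapse = ",")
      prev <- if (!is.null(acc[[key]])) acc[[key]] else
        list(p = numeric(space$k), n = 0L)
      acc[[key]] <- list(p = prev$p + as.numeric(tab[i, space$codes]),
                         n = prev$n + 1L)
    }
  }
  keys <- ls(acc)
  probs <- t(vapply(keys, function(kk) acc[[kk]]$p / acc[[kk]]$n,
                    numeric(space$k)))
  colnames(probs) <- space$codes
  data.frame(clade = keys, probs,
             n_trees = vapply(keys, function(kk) acc[[kk]]$n, 0L),
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a tree with ancestral-state annotations
#'
#' Exports Newick with per-internal-node comment blocks carrying the
#' reconstruction probabilities, e.g. \code{[&A=0.82,B=0.18]}.
#'
#' @param tree the \code{phylo} used for the reconstruction.
#' @param table a \code{node_state_table} from [marginal_asr()].
#' @param path optional output path; the annotated Newick string is returned
#'   invisibly.
#' @export
write_asr_newick <- function(tree, table, path = NULL) {
  space <- attr(table, "space")
  lab <- vapply(seq_len(nrow(table)), function(i)
    paste0("[&", paste0(space$codes, "=",
                        sprintf("%.4f", as.numeric(table[i, space$codes])),
                        collapse = ","), "]"), "")
  n <- length(tree$tip.label)
  tree$node.label <- lab[order(table$node)][seq_len(tree$Nnode)]
  txt <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
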