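# Independent oracles used across the suite. These deliberately avoid the
# package's pruning code path: likelihoods are computed by brute-force
# enumeration over all internal-node state assignments, with transition
# probabilities from the package's (separately tested) matrix exponential.

# brute-force likelihood: sum over every assignment of states to internal
# nodes of root-prior mass x product of per-edge transition probabilities,
# summing tip ambiguity sets explicitly
enum_loglik <- function(tree, matrix, Q, prior = NULL) {
  sp <- matrix$space
  k <- sp$k
  if (is.null(prior)) prior <- rep(1 / k, k)
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  n_edge <- nrow(post$edge)
  root <- post$edge[n_edge, 1]
  internal <- sort(unique(post$edge[, 1]))
  P <- lapply(seq_len(n_edge), function(e)
    transition_probs(Q, post$edge.length[e]))
  tip_states <- lapply(tree$tip.label, function(t)
    matrix$states[[match(t, matrix$taxa)]])
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    names(st) <- internal
    w <- prior[st[[as.character(root)]]]
    for (e in seq_len(n_edge)) {
      par_state <- st[[as.character(post$edge[e, 1])]]
      ch <- post$edge[e, 2]
      w <- w * if (ch <= n) sum(P[[e]][par_state, tip_states[[ch]]])
               else P[[e]][par_state, st[[as.character(ch)]]]
      if (w == 0) break
    }
    total <- total + w
  }
  log(total)
}

# brute-force marginal ancestral distribution at each internal node
enum_asr <- function(tree, matrix, Q, prior = NULL) {
  sp <- matrix$space
  k <- sp$k
  if (is.null(prior)) prior <- rep(1 / k, k)
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  n_edge <- nrow(post$edge)
  root <- post$edge[n_edge, 1]
  internal <- sort(unique(post$edge[, 1]))
  P <- lapply(seq_len(n_edge), function(e)
    transition_probs(Q, post$edge.length[e]))
  tip_states <- lapply(tree$tip.label, function(t)
    matrix$states[[match(t, matrix$taxa)]])
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  probs <- base::matrix(0, length(internal), k)
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    names(st) <- internal
    w <- prior[st[[as.character(root)]]]
    for (e in seq_len(n_edge)) {
      par_state <- st[[as.character(post$edge[e, 1])]]
      ch <- post$edge[e, 2]
      w <- w * if (ch <= n) sum(P[[e]][par_state, tip_states[[ch]]])
               else P[[e]][par_state, st[[as.character(ch)]]]
    }
    for (i in seq_along(internal))
      probs[i, st[[as.character(internal[i])]]] <-
        probs[i, st[[as.character(internal[i])]]] + w
  }
  probs / rowSums(probs)
}

# random small test case: tree with <= max_tips tips, k <= max_k states,
# random masked Q and random (possibly ambiguous) tip data
random_small_case <- function(max_tips = 5, max_k = 4, ambiguous = TRUE) {
  n <- sample(2:max_tips, 1)
  k <- sample(2:max_k, 1)
  tree <- ape::rtree(n)
  tree$tip.label <- paste0("t", seq_len(n))
  sp <- state_space(paste0("state", seq_len(k)))
  cfg <- rate_config(sp)
  rates <- stats::runif(cfg$n_bins, 0, 2) *
    stats::rbinom(cfg$n_bins, 1, 0.8)  # some rates 0
  Q <- build_q(rates, cfg)
  states <- vapply(seq_len(n), function(i) {
    if (ambiguous && stats::runif(1) < 0.2) {
      paste(sample(sp$codes, sample(2:k, 1)), collapse = "|")
    } else sample(sp$codes, 1)
  }, "")
  tm <- trait_matrix(tree$tip.label, states, sp)
  list(tree = tree, matrix = tm, Q = Q, space = sp)
}
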