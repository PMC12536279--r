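spAB <- state_space(c("low", "high"), c("A", "B"))
tree3 <- parse_newick("((t1:1,t2:1):1,t3:2);")
tm3 <- trait_matrix(c("t1", "t2", "t3"), c("A", "A", "B"), spAB)

test_that("free-parameter counting follows bins", {
  sp4 <- state_space(c("restricted", "anchor 2", "anchor 5", "anchor 10"))
  expect_equal(count_free_parameters(rate_config(sp4)), 12)
  sp6 <- state_space(c("anchor 2 (proper)", "anchor 2 (non-proper)",
                       "anchor 4", "anchor 5", "anchor 6", "anchor 10"))
  expect_equal(count_free_parameters(rate_config(sp6)), 30)
  sp1 <- state_space("only")
  expect_equal(count_free_parameters(rate_config(sp1)), 0)
  # shared bins collapse the count
  expect_equal(count_free_parameters(rate_config(spAB, bins = c(1, 1))), 1)
})

test_that("cyclical configurations wire each state to exactly one successor", {
  sp4 <- state_space(c("restricted", "anchor 2", "anchor 5", "anchor 10"))
  fwd <- build_cyclical_config(sp4)
  expect_equal(count_free_parameters(fwd), 4)
  on <- fwd$pairs[fwd$mask, ]
  expect_setequal(paste(on$from, on$to),
                  c("1 2", "2 3", "3 4", "4 1"))
  rev <- build_cyclical_config(sp4, orientation = "reverse")
  onr <- rev$pairs[rev$mask, ]
  expect_setequal(paste(onr$from, onr$to),
                  c("2 1", "3 2", "4 3", "1 4"))
  # k = 2: both orientations coincide
  f2 <- build_cyclical_config(spAB)
  r2 <- build_cyclical_config(spAB, orientation = "reverse")
  expect_identical(f2$mask, r2$mask)
  expect_error(build_cyclical_config(sp4, c("restricted", "anchor 2")),
               "permutation")
})

test_that("Q matrices have zero row sums and respect the mask", {
  sp4 <- state_space(c("restricted", "anchor 2", "anchor 5", "anchor 10"))
  cyc <- build_cyclical_config(sp4)
  Q <- build_q(c(0.1, 0.2, 0.3, 0.4), cyc)
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(Q[upper.tri(Q) | lower.tri(Q)] > 0), 4)
  expect_true(all(build_q(rep(0, 4), cyc) == 0))
  Q2 <- build_q(0.5, rate_config(spAB, bins = c(1, 1)))
  expect_equal(unname(Q2), matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2,
                                  byrow = TRUE))
  expect_error(build_q(c(-1, 1, 1, 1), cyc), "non-negative")
})

test_that("transition probabilities match the 2-state closed form and limits", {
  Q <- build_q(0.5, rate_config(spAB, bins = c(1, 1)))
  expect_equal(unname(transition_probs(Q, 0)), diag(2))
  # P_same(t) = (1 + exp(-2qt)) / 2
  expect_equal(transition_probs(Q, 1)[1, 1], (1 + exp(-1)) / 2,
               tolerance = 1e-10)
  expect_error(transition_probs(Q, -1), ">= 0")

  # long branches converge to the stationary distribution
  sp3 <- state_space(c("a", "b", "c"))
  cfg3 <- rate_config(sp3)
  set.seed(5)
  Q3 <- build_q(runif(6, 0.2, 1), cfg3)
  pi3 <- stationary_dist(Q3)
  P_inf <- transition_probs(Q3, 200)
  for (i in 1:3) expect_equal(unname(P_inf[i, ]), unname(pi3),
                              tolerance = 1e-9)

  # row-stochastic for rate x t up to 50
  for (t in c(1e-6, 0.1, 1, 10, 50)) {
    P <- transition_probs(Q3, t)
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("pruning likelihood matches hand-derived and degenerate cases", {
  Q <- build_q(0.5, rate_config(spAB, bins = c(1, 1)))
  # frozen value from the 2-state closed form, enumerated over both internal
  # nodes of ((t1:1,t2:1):1,t3:2) with tips A,A,B:
  # L = (pd2 (ps1^3 + pd1^3) + ps2 (pd1 ps1^2 + ps1 pd1^2)) / 2
  expect_equal(prune_loglik(tree3, tm3, Q), -1.985310233327,
               tolerance = 1e-9)
  expect_equal(prune_loglik(tree3, tm3, Q), enum_loglik(tree3, tm3, Q),
               tolerance = 1e-12)

  # single tip, zero branch: likelihood is the root-prior mass
  tip1 <- prune_to_taxa(tree3, "t1")
  tip1$edge.length <- 0
  tm1 <- trait_matrix("t1", "A", spAB)
  expect_equal(prune_loglik(tip1, tm1, Q), log(0.5))

  # zero rates, constant tips, uniform 3-state root: likelihood 1/3
  sp3 <- state_space(c("a", "b", "c"))
  tmc <- trait_matrix(c("t1", "t2", "t3"), c("A", "A", "A"), sp3)
  expect_equal(prune_loglik(tree3, tmc, matrix(0, 3, 3)), log(1 / 3))

  # taxa mismatch points to match_taxa
  tm_bad <- trait_matrix(c("t1", "t2"), c("A", "A"), spAB)
  expect_error(prune_loglik(tree3, tm_bad, Q), "match_taxa")
})

test_that("pruning equals brute-force enumeration on random small cases", {
  set.seed(2024)
  for (i in 1:100) {
    cs <- random_small_case(max_tips = 5, max_k = 4)
    ll_prune <- prune_loglik(cs$tree, cs$matrix, cs$Q)
    ll_enum <- enum_loglik(cs$tree, cs$matrix, cs$Q)
    if (is.finite(ll_enum)) {
      expect_equal(ll_prune, ll_enum, tolerance = 1e-9)
    } else {
      expect_identical(ll_prune, -Inf)
    }
  }
})

test_that("uniform-root likelihood is the mean of fixed-root likelihoods", {
  set.seed(99)
  for (i in 1:20) {
    cs <- random_small_case(max_tips = 5, max_k = 4)
    k <- cs$space$k
    lik_fixed <- vapply(cs$space$codes, function(s) {
      exp(prune_loglik(cs$tree, cs$matrix, cs$Q,
                       root_prior("fixed", cs$space, state = s)))
    }, 0)
    lik_unif <- exp(prune_loglik(cs$tree, cs$matrix, cs$Q))
    expect_equal(lik_unif, mean(lik_fixed), tolerance = 1e-12)
  }
})

test_that("likelihood is invariant under tip input order", {
  Q <- build_q(c(0.7, 0.2), rate_config(spAB))
  ll <- prune_loglik(tree3, tm3, Q)
  perm <- trait_matrix(c("t3", "t1", "t2"), c("B", "A", "A"), spAB)
  expect_equal(prune_loglik(tree3, perm, Q), ll, tolerance = 1e-14)
})

test_that("ambiguous and missing tips contribute partial likelihood on allowed states", {
  # fully ambiguous data: likelihood 1 regardless of Q
  tma <- trait_matrix(c("t1", "t2", "t3"), c(NA, "", "A|B"), spAB)
  tma$states[["t3"]] <- 1:2
  Q <- build_q(c(0.9, 0.4), rate_config(spAB))
  expect_equal(prune_loglik(tree3, trait_matrix(c("t1", "t2", "t3"),
                                                c(NA, NA, NA), spAB), Q), 0)
  # partial ambiguity agrees with the sum of resolved likelihoods
  tm_amb <- trait_matrix(c("t1", "t2", "t3"), c("A|B", "A", "B"), spAB)
  l_sum <- exp(prune_loglik(tree3, trait_matrix(c("t1", "t2", "t3"),
                                                c("A", "A", "B"), spAB), Q)) +
           exp(prune_loglik(tree3, trait_matrix(c("t1", "t2", "t3"),
                                                c("B", "A", "B"), spAB), Q))
  expect_equal(exp(prune_loglik(tree3, tm_amb, Q)), l_sum,
               tolerance = 1e-12)
})

test_that("likelihood agrees with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  x <- setNames(c("A", "A", "B"), c("t1", "t2", "t3"))
  Qm <- matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  f <- phytools::fitMk(tree3, x, fixedQ = Qm, pi = c(0.5, 0.5))
  Q <- build_q(0.5, rate_config(spAB, bins = c(1, 1)))
  expect_equal(prune_loglik(tree3, tm3, Q), as.numeric(stats::logLik(f)),
               tolerance = 1e-6)
})

test_that("maximum-likelihood rates match a grid-search oracle", {
  # symmetric shared-rate model: 1-D problem amenable to grid search
  set.seed(7)
  tree <- ape::rtree(4)
  tree$tip.label <- paste0("t", 1:4)
  sp <- spAB
  cfg <- rate_config(sp, bins = c(1, 1))
  sim <- sim_trait(scale_tree_depth(tree, 1), build_q(0.8, cfg), sp, seed = 3)
  fit <- ml_fit(scale_tree_depth(tree, 1), sim$matrix, cfg)
  grid <- seq(1e-4, 20, length.out = 4000)
  ll_grid <- vapply(grid, function(q)
    prune_loglik(scale_tree_depth(tree, 1), sim$matrix, build_q(q, cfg)), 0)
  q_star <- grid[which.max(ll_grid)]
  expect_true(abs(fit$rates - q_star) < 1e-2 ||
                abs(fit$loglik - max(ll_grid)) < 1e-6)
  # optimum beats random rate vectors
  set.seed(8)
  for (i in 1:10) {
    q_rand <- runif(1, 0, 15)
    expect_gte(fit$loglik + 1e-9,
               prune_loglik(scale_tree_depth(tree, 1), sim$matrix,
                            build_q(q_rand, cfg)))
  }
})

test_that("constant data drives the symmetric ML rate to the zero boundary", {
  tmc <- trait_matrix(c("t1", "t2", "t3"), c("A", "A", "A"), spAB)
  fit <- ml_fit(tree3, tmc, rate_config(spAB, bins = c(1, 1)))
  expect_equal(fit$rates, 0, tolerance = 1e-8)
})
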