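test_that("log Bayes factors reproduce the published root-test margins", {
  # best vs second-best log marginal likelihoods per family, one decimal
  published <- list(
    torricelli = list(a = -39.45, b = -40.46, bf = 2.0),
    ntng       = list(a = -86.44, b = -87.72, bf = 2.6),
    ramu       = list(a = -20.39, b = -21.21, bf = 1.6),
    tucanoan   = list(a = -8.43,  b = -9.52,  bf = 2.2),
    tupian     = list(a = -52.52, b = -54.43, bf = 3.8),
    papuanbig4 = list(a = -274.2, b = -275.1, bf = 1.8))
  for (fam in names(published)) {
    p <- published[[fam]]
    expect_equal(round(log_bayes_factor(p$a, p$b)$log_bf, 1), p$bf,
                 info = fam)
  }
  expect_equal(log_bayes_factor(-39.45, -40.46)$log_bf, 2.02)
  expect_equal(log_bayes_factor(-3, -3)$log_bf, 0)
  expect_error(log_bayes_factor(-Inf, -3), "finite")
})

test_that("log Bayes factor is antisymmetric", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(1, -50, 10); b <- rnorm(1, -50, 10)
    expect_equal(log_bayes_factor(a, b)$log_bf,
                 -log_bayes_factor(b, a)$log_bf)
  }
})

test_that("evidence labels form a step function with breakpoints 2, 5, 10", {
  expect_equal(interpret_bf(0), "none")
  expect_equal(interpret_bf(2), "none")        # strictly > 2
  expect_equal(interpret_bf(2.0001), "positive")
  expect_equal(interpret_bf(5), "positive")
  expect_equal(interpret_bf(5.0001), "strong")
  expect_equal(interpret_bf(7.64), "strong")
  expect_equal(interpret_bf(10), "strong")
  expect_equal(interpret_bf(10.0001), "very strong")
  expect_equal(interpret_bf(12), "very strong")
  expect_error(interpret_bf(-1), "reorder")
})

test_that("root restriction prefers the generating state under no change", {
  sp <- state_space(c("s1", "s2"))
  tr <- parse_newick("((t1:1,t2:1):1,t3:2);")
  tmA <- trait_matrix(c("t1", "t2", "t3"), c("A", "A", "A"), sp)
  cfg <- rate_config(sp, bins = c(1, 1))
  rt <- test_root_states(tmA, tr, config = cfg, prior = prior_spec(10),
                         K = 6, iterations = 400, burnin = 150, seed = 2)
  expect_equal(rt$best, "A")
  lml <- setNames(rt$table$lml, rt$table$code)
  expect_gt(lml[["A"]], lml[["B"]])
  expect_equal(nrow(rt$table), 2)  # one row per state, like the root tables
  expect_s3_class(rt$bf, "bayes_factor")
})

test_that("exchangeable data give equal root support within MC error", {
  sp <- state_space(c("s1", "s2"))
  tr <- parse_newick("(t1:1,t2:1);")
  tm <- trait_matrix(c("t1", "t2"), c("A", "B"), sp)
  cfg <- rate_config(sp, bins = c(1, 1))
  reps <- t(vapply(1:4, function(r) {
    rt <- test_root_states(tm, tr, config = cfg, prior = prior_spec(10),
                           K = 8, iterations = 800, burnin = 200,
                           seed = 10 + r)
    setNames(rt$table$lml, rt$table$code)
  }, c(A = 0, B = 0)))
  se <- sqrt(stats::var(reps[, "A"]) / 4 + stats::var(reps[, "B"]) / 4)
  expect_lt(abs(mean(reps[, "A"]) - mean(reps[, "B"])), 4 * se + 0.02)
})

test_that("iterative reduction respects threshold 0 and constant data", {
  sp <- state_space(c("s1", "s2"))
  tr <- scale_tree_depth(sim_tree(12, 1, seed = 5), 1)
  Q <- build_q(c(0.8, 0.8), rate_config(sp))
  sim <- sim_trait(tr, Q, sp, seed = 6)
  red0 <- iterative_reduction(sim$matrix, tr, prior_spec(10), threshold = 0,
                              max_rounds = 3,
                              settings = mcmc_settings(iterations = 1500,
                                                       burnin = 500,
                                                       thinning = 5,
                                                       seed = 7),
                              ss_K = 3, ss_iterations = 150, ss_burnin = 50)
  expect_length(red0$rounds, 1)  # nothing can drop below 0
  expect_equal(sum(red0$best_config$mask), 2)

  # constant tips: reduction walks toward the minimal model without error
  tmc <- trait_matrix(tr$tip.label, rep("A", 12), sp)
  redc <- iterative_reduction(tmc, tr, prior_spec(10), threshold = 0.5,
                              max_rounds = 4,
                              settings = mcmc_settings(iterations = 3000,
                                                       burnin = 1000,
                                                       thinning = 5,
                                                       seed = 8),
                              ss_K = 3, ss_iterations = 150, ss_burnin = 50)
  expect_s3_class(redc, "reduction_trace")
  expect_lt(sum(redc$best_config$mask), 2)
})

test_that("reduction recovers a superset of the true cyclical structure", {
  sp <- state_space(c("s1", "s2", "s3", "s4"))
  cfg_true <- build_cyclical_config(sp)
  Q <- build_q(rep(1.2, 4), cfg_true)
  on_names <- cfg_true$pairs$name[cfg_true$mask]
  ok <- 0
  for (r in 1:10) {
    tree <- scale_tree_depth(sim_tree(120, 1, seed = 60 + r), 1)
    sim <- sim_trait(tree, Q, sp, seed = 70 + r)
    red <- iterative_reduction(sim$matrix, tree, prior_spec(10),
                               threshold = 0.5, max_rounds = 4,
                               settings = mcmc_settings(iterations = 6000,
                                                        burnin = 2000,
                                                        thinning = 5,
                                                        seed = 80 + r),
                               ss_K = 5, ss_iterations = 250,
                               ss_burnin = 120)
    final_on <- red$best_config$pairs$name[red$best_config$mask]
    ok <- ok + all(on_names %in% final_on)
  }
  expect_gte(ok, 8)
})

test_that("model comparison ranks, labels, and detects orientation", {
  sp <- state_space(c("s1", "s2", "s3"))
  fwd <- build_cyclical_config(sp)
  rev <- build_cyclical_config(sp, orientation = "reverse")

  # duplicated model: BF within MC error of zero
  tr <- scale_tree_depth(sim_tree(25, 1, seed = 1), 1)
  sim <- sim_trait(tr, build_q(c(1, 1, 1), fwd), sp, seed = 2)
  cm_dup <- compare_models(list(m1 = fwd, m2 = fwd), sim$matrix, tr,
                           prior_spec(10), K = 6, iterations = 800,
                           burnin = 200, seed = 3)
  expect_lt(abs(cm_dup$pairwise["m1", "m2"]), 1)
  expect_equal(cm_dup$pairwise["m1", "m1"], 0)

  # direction-asymmetric data: the generating orientation wins usually
  wins <- 0
  for (r in 1:10) {
    tree <- scale_tree_depth(sim_tree(60, 1, seed = 30 + r), 1)
    simr <- sim_trait(tree, build_q(c(1.5, 1.5, 1.5), fwd), sp,
                      seed = 40 + r)
    cm <- compare_models(list(forward = fwd, reverse = rev), simr$matrix,
                         tree, prior_spec(10), K = 6, iterations = 250,
                         burnin = 120, seed = 50 + r)
    wins <- wins + (cm$table$model[1] == "forward")
  }
  expect_gte(wins, 8)
})

test_that("model reports list on-parameters as directed edges", {
  sp4 <- state_space(c("restricted", "anchor 2", "anchor 5", "anchor 10"))
  cyc <- build_cyclical_config(sp4)
  rep4 <- render_model_report(cyc, rates = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(nrow(rep4$edges), 4)
  expect_equal(rep4$edges$rate, c(0.1, 0.2, 0.3, 0.4))
  expect_length(rep4$off, 8)

  full <- render_model_report(rate_config(sp4))
  expect_equal(nrow(full$edges), 12)
  expect_length(full$off, 0)

  empty <- render_model_report(rate_config(sp4, mask = rep(FALSE, 12)))
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$off, 12)
})
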