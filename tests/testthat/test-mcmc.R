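sp2 <- state_space(c("low", "high"), c("A", "B"))
tree2 <- parse_newick("(t1:1,t2:1);")
ambig2 <- trait_matrix(c("t1", "t2"), c(NA, NA), sp2)

test_that("uninformative data return the prior: rate mean near 10", {
  s <- run_mcmc(ambig2, tree2, prior_spec(10),
                mcmc_settings(iterations = 60000, burnin = 5000,
                              thinning = 10, seed = 21), rj = TRUE)
  r <- s$rates[s$rates > 0]
  expect_gt(length(r), 1000)
  expect_lt(abs(mean(r) - 10), 1)
  # likelihood of fully ambiguous data is 1 (to matrix-exponential round-off)
  expect_lt(max(abs(s$loglik)), 1e-10)
})

test_that("posterior sample length follows iterations, burn-in and thinning", {
  s <- run_mcmc(ambig2, tree2, prior_spec(10),
                mcmc_settings(iterations = 1000, burnin = 200,
                              thinning = 8, seed = 2), rj = TRUE)
  expect_equal(nrow(s$rates), (1000 - 200) %/% 8)
  expect_equal(nrow(s$bins), nrow(s$rates))
  expect_length(s$loglik, nrow(s$rates))
})

test_that("constant data switch off the identified transition", {
  sp <- sp2
  tr <- scale_tree_depth(sim_tree(30, 1, seed = 7), 1)
  tmc <- trait_matrix(tr$tip.label, rep("A", 30), sp)
  s <- run_mcmc(tmc, tr, prior_spec(10),
                mcmc_settings(iterations = 30000, burnin = 5000,
                              thinning = 10, seed = 3), rj = TRUE)
  incl <- posterior_inclusion(s)
  # the rate away from the constant state is driven out of the model;
  # its conditional rates concentrate far below the prior mean
  expect_lt(incl[["qAB"]], 0.5)
  on_ab <- s$rates[s$rates[, "qAB"] > 0, "qAB"]
  expect_lt(mean(on_ab), 2)
})

test_that("independent chains agree on the posterior mean log-likelihood", {
  sp <- state_space(c("a", "b", "c"))
  Q <- build_q(c(1, 0.6, 0.8), build_cyclical_config(sp))
  tr <- scale_tree_depth(sim_tree(40, 1, seed = 11), 1)
  sim <- sim_trait(tr, Q, sp, seed = 12)
  runs <- lapply(c(101, 202), function(sd)
    run_mcmc(sim$matrix, tr, prior_spec(10),
             mcmc_settings(iterations = 8000, burnin = 3000,
                           thinning = 5, seed = sd), rj = TRUE))
  mll <- vapply(runs, function(s) mean(s$loglik), 0)
  se <- vapply(runs, function(s)
    stats::sd(s$loglik) / sqrt(anchorphylo:::ess_ips(s$loglik)), 0)
  expect_lt(abs(mll[1] - mll[2]), 3 * sqrt(sum(se^2)))
})

test_that("prior-only chain visits rate configurations uniformly", {
  # k = 2 has exactly 5 (mask, bin-partition) configurations:
  # both off, only qAB, only qBA, both on shared, both on separate
  s <- run_mcmc(ambig2, tree2, prior_spec(10),
                mcmc_settings(iterations = 90000, burnin = 5000,
                              thinning = 20, seed = 42), rj = TRUE,
                power = 0)
  cls <- apply(s$bins, 1, function(b) {
    if (all(b == 0)) "00"
    else if (b[1] > 0 && b[2] == 0) "10"
    else if (b[1] == 0) "01"
    else if (b[1] == b[2]) "shared" else "separate"
  })
  tab <- table(factor(cls, levels = c("00", "10", "01", "shared",
                                      "separate")))
  expect_true(all(tab > 0))
  expect_gt(stats::chisq.test(tab, p = rep(0.2, 5))$p.value, 1e-3)
})

test_that("split and merge moves invert each other structurally", {
  set.seed(77)
  bins <- c(1L, 1L, 2L, 0L, 1L, 2L)
  rates <- c(0.5, 1.5)
  partition <- function(b) {
    on <- which(b > 0)
    unname(lapply(split(on, b[on]), sort))
  }
  same_partition <- function(p1, p2) {
    length(p1) == length(p2) &&
      all(vapply(p1, function(g) any(vapply(p2, identical, TRUE, g)), TRUE))
  }
  sp <- anchorphylo:::rj_propose_split(bins, rates, 10)
  expect_false(is.null(sp))
  # the split partitions the chosen bin's members into two non-empty parts
  expect_equal(length(sp$rates), length(rates) + 1)
  expect_equal(sort(which(sp$bins > 0)), sort(which(bins > 0)))
  # merging the two offspring bins restores the original partition
  merged_once <- FALSE
  for (i in 1:50) {
    mg <- anchorphylo:::rj_propose_merge(sp$bins, sp$rates, 10)
    if (same_partition(partition(mg$bins), partition(bins))) {
      merged_once <- TRUE
      break
    }
  }
  expect_true(merged_once)
  # a merge is impossible with fewer than two bins
  expect_null(anchorphylo:::rj_propose_merge(c(1L, 0L), 0.7, 10))
  # a split is impossible without a multi-member bin
  expect_null(anchorphylo:::rj_propose_split(c(1L, 2L, 0L), c(1, 2), 10))
})

test_that("posterior inclusion is exact bookkeeping over the bins", {
  s <- run_mcmc(ambig2, tree2, prior_spec(10),
                mcmc_settings(iterations = 4000, burnin = 1000,
                              thinning = 5, seed = 5), rj = TRUE)
  incl <- posterior_inclusion(s)
  expect_true(all(incl >= 0 & incl <= 1))
  expect_equal(unname(incl), unname(colMeans(s$bins > 0)))
  # per-iteration configuration sizes are consistent with the rate record
  expect_equal(rowSums(s$bins > 0) > 0, s$n_bins > 0)
  expect_true(all(s$rates[s$bins == 0] == 0))
  expect_true(all(s$rates[s$bins > 0] > 0))

  # a parameter masked off in the template never turns on
  cfg <- rate_config(sp2, mask = c(TRUE, FALSE))
  s2 <- run_mcmc(ambig2, tree2, prior_spec(10),
                 mcmc_settings(iterations = 4000, burnin = 1000,
                               thinning = 5, seed = 6), rj = TRUE,
                 fixed_config = cfg)
  expect_equal(unname(posterior_inclusion(s2)[2]), 0)

  # non-RJ samples have no inclusion notion
  s3 <- run_mcmc(ambig2, tree2, prior_spec(10),
                 mcmc_settings(iterations = 2000, burnin = 500,
                               thinning = 5, seed = 7), rj = FALSE,
                 fixed_config = rate_config(sp2))
  expect_error(posterior_inclusion(s3), "reversible-jump")
  # and with a fixed full configuration, parameters are never zero
  expect_equal(unname(posterior_inclusion(s)[colMeans(s$bins > 0) == 1]),
               rep(1, sum(colMeans(s$bins > 0) == 1)))
})

test_that("an all-off fixed configuration errors on non-constant data", {
  tmv <- trait_matrix(c("t1", "t2"), c("A", "B"), sp2)
  cfg0 <- rate_config(sp2, mask = c(FALSE, FALSE))
  expect_error(run_mcmc(tmv, tree2, prior_spec(10),
                        mcmc_settings(iterations = 100, burnin = 10,
                                      thinning = 1, seed = 1),
                        rj = FALSE, fixed_config = cfg0), "not constant")
  # but is fine for constant data
  tmc <- trait_matrix(c("t1", "t2"), c("A", "A"), sp2)
  s <- run_mcmc(tmc, tree2, prior_spec(10),
                mcmc_settings(iterations = 100, burnin = 10, thinning = 1,
                              seed = 1), rj = FALSE, fixed_config = cfg0)
  expect_equal(unique(s$loglik), log(0.5))
})

test_that("convergence diagnostics flag drift and respect the null", {
  mk_sample <- function(ll) {
    n <- length(ll)
    structure(list(loglik = ll, rates = matrix(rexp(2 * n), n, 2,
                     dimnames = list(NULL, c("qAB", "qBA"))),
                   bins = matrix(1L, n, 2), rj = TRUE,
                   iteration = seq_len(n)),
              class = "posterior_sample")
  }
  flat <- convergence_report(mk_sample(rep(-5, 100)))
  expect_equal(flat$lik_iter_cor, 0)
  expect_true(flat$pass)

  drift <- convergence_report(mk_sample(seq(-100, -1)))
  expect_equal(drift$lik_iter_cor, 1, tolerance = 1e-12)
  expect_false(drift$pass)
  expect_match(drift$warnings[1], "drifting")

  # white noise: |cor| < 3/sqrt(n) in most replicates
  set.seed(13)
  hits <- sum(vapply(1:20, function(i) {
    abs(convergence_report(mk_sample(rnorm(400)))$lik_iter_cor) <
      3 / sqrt(400)
  }, TRUE))
  expect_gte(hits, 18)
})

test_that("tree rotation mode walks through the whole sample", {
  t1 <- parse_newick("((t1:1,t2:1):1,t3:2);")
  t2 <- parse_newick("((t1:1,t3:1):1,t2:2);")
  t3 <- parse_newick("((t2:1,t3:1):1,t1:2);")
  ts <- tree_set(list(t1, t2, t3))
  tm <- trait_matrix(c("t1", "t2", "t3"), c("A", "A", "B"), sp2)
  s <- run_mcmc(tm, ts, prior_spec(10),
                mcmc_settings(iterations = 600, burnin = 100, thinning = 1,
                              seed = 4), rj = FALSE,
                fixed_config = rate_config(sp2), tree_mode = "rotate")
  expect_setequal(unique(s$tree_index), 1:3)
  # deterministic rotation: index cycles with period 3
  expect_equal(unique(diff(s$tree_index) %% 3), 1)
  # MH mode also mixes over trees
  s2 <- run_mcmc(tm, ts, prior_spec(10),
                 mcmc_settings(iterations = 2000, burnin = 200,
                               thinning = 2, seed = 4), rj = FALSE,
                 fixed_config = rate_config(sp2))
  expect_gt(length(unique(s2$tree_index)), 1)
})
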