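test_that("transition probabilities are exact", {
  P0 <- transition_probability(2, 1, 0)
  expect_equal(unname(P0), diag(2))
  Pinf <- transition_probability(1, 1, 1e4)
  expect_equal(unname(Pinf), matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_error(transition_probability(1, 1, -1), ">= 0")
  expect_error(transition_probability(0, 0, 1), "both")
  ## independent matrix-exponential oracle
  skip_if_not_installed("Matrix")
  Q <- matrix(c(-2, 1, 2, -1), 2, 2)
  Pexp <- as.matrix(Matrix::expm(Q * 0.7))
  expect_lt(max(abs(transition_probability(2, 1, 0.7) - Pexp)), 1e-10)
})

test_that("gamma rate categories have mean one and spread by shape", {
  for (a in c(0.3, 1, 4)) {
    r <- gamma_rate_categories(a, 4)
    expect_equal(mean(r), 1)
    expect_true(all(r > 0))
  }
  expect_lt(diff(range(gamma_rate_categories(10, 4))),
            diff(range(gamma_rate_categories(0.5, 4))))
  expect_equal(gamma_rate_categories(1, 1), 1)
})

test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    tr <- random_small_tree(n)
    g <- runif(1, 0.2, 4); l <- runif(1, 0.2, 4)
    pattern <- setNames(rbinom(n, 1, 0.5), tr$tip.label)
    model <- gainloss_model(g, l, n_categories = 1L)
    expect_equal(family_loglik(tr, pattern, model),
                 enum_loglik(tr, pattern, g, l), tolerance = 1e-10)
  }
})

test_that("likelihoods define a proper distribution over leaf patterns", {
  tr <- read_newick("((A:0.4,B:0.9):0.3,(C:0.2,D:1.1):0.6);", text = TRUE)
  model <- gainloss_model(1.3, 0.7, gamma_shape = 0.8, n_categories = 4L)
  patterns <- as.matrix(expand.grid(rep(list(0:1), 4)))
  tot <- sum(vapply(seq_len(nrow(patterns)), function(i) {
    exp(family_loglik(tr, setNames(patterns[i, ], c("A", "B", "C", "D")),
                      model))
  }, 0))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("single-leaf pattern likelihood reduces to the root prior", {
  tr <- read_newick("(A:0.7);", text = TRUE)
  model <- gainloss_model(2, 6, n_categories = 1L)
  ## stationarity: the marginal at the leaf equals the root prior
  expect_equal(family_loglik(tr, c(A = 1), model), log(0.25),
               tolerance = 1e-12)
  expect_error(family_loglik(tr, c(B = 1), model), "every leaf")
})

test_that("fit_gainloss rejects degenerate input and respects time scaling", {
  tr <- random_small_tree(8)
  const <- matrix(1L, 8, 5, dimnames = list(tr$tip.label, paste0("f", 1:5)))
  expect_error(fit_gainloss(tr, const), "no signal")

  set.seed(55)
  cfg <- tiny_config(n_genomes = 50, tree_height_target = 1,
                     n_families = c(prophage = 150, plasmid = 0,
                                    transposon = 0, neutral = 0),
                     base_gain_rate = c(prophage = 1, plasmid = 0,
                                        transposon = 0, neutral = 0),
                     base_loss_rate = c(prophage = 2, plasmid = 0,
                                        transposon = 0, neutral = 0),
                     singleton_fraction = 0, n_defense_genes = 0,
                     defense_effect = 1, seed = 55)
  ds <- generate_dataset(cfg)
  f1 <- fit_gainloss(ds$tree, ds$matrix, K = 1)
  tr2 <- ds$tree
  tr2$edge.length <- tr2$edge.length * 2
  f2 <- fit_gainloss(tr2, ds$matrix, K = 1)
  expect_equal(f2$gain_rate / f1$gain_rate, 0.5, tolerance = 0.02)
  expect_equal(f2$loss_rate / f1$loss_rate, 0.5, tolerance = 0.02)
})

test_that("conditional expected transitions conserve the endpoint difference", {
  ## pathwise, N01 - N10 = 1{end present} - 1{start present}; the
  ## uniformization series must satisfy this identity exactly
  for (g in c(0.3, 2, 8)) for (l in c(0.5, 3)) for (t in c(0.05, 0.6, 3)) {
    et <- expected_transitions(g, l, t)
    net <- et$gains - et$losses
    expect_equal(unname(net), matrix(c(0, -1, 1, 0), 2, 2), tolerance = 1e-8)
  }
})

test_that("expected transitions match the occupancy-integral oracle", {
  for (case in list(c(2, 1, 0.7), c(0.5, 3, 1.2))) {
    et <- expected_transitions(case[1], case[2], case[3])
    or <- expected_transitions_oracle(case[1], case[2], case[3])
    expect_lt(max(abs(et$gains - or$gains)), 1e-4)
    expect_lt(max(abs(et$losses - or$losses)), 1e-4)
  }
})

test_that("branch expectations respect evidence and aggregate additively", {
  set.seed(77)
  tr <- random_small_tree(12)
  n_fam <- 30
  X <- matrix(rbinom(12 * n_fam, 1, 0.5), 12,
              dimnames = list(tr$tip.label, paste0("f", seq_len(n_fam))))
  X[, 1] <- 1L   # family fixed present
  model <- gainloss_model(1, 1e-4, gamma_shape = 1, n_categories = 4L)
  be <- branch_expected_events(tr, X, model)
  ## present everywhere with a negligible loss rate: no losses anywhere
  expect_lt(max(be$expected_losses[, 1]), 1e-3)
  expect_true(all(be$expected_gains >= 0))
  expect_true(all(be$p_gain >= 0 & be$p_gain <= 1 + 1e-12))

  agg_all <- aggregate_branch_events(be)
  sub <- c("f1", "f2", "f3")
  agg_sub <- aggregate_branch_events(be, sub)
  rest <- setdiff(colnames(X), sub)
  agg_rest <- aggregate_branch_events(be, rest)
  expect_equal(agg_all$expected_gains,
               agg_sub$expected_gains + agg_rest$expected_gains,
               tolerance = 1e-10)
})

test_that("total inferred flux tracks the true simulated event count", {
  cfg <- tiny_config(n_genomes = 60, seed = 21,
                     n_families = c(prophage = 80, plasmid = 60,
                                    transposon = 60, neutral = 100))
  ds <- generate_dataset(cfg)
  model <- fit_gainloss(ds$tree, ds$matrix, K = 4)
  be <- branch_expected_events(ds$tree, ds$matrix, model)
  true_gains <- sum(ds$family_history$events$event == "gain")
  expect_equal(sum(be$expected_gains), true_gains, tolerance = 0.15)
})
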