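test_that("Brownian covariance encodes shared path lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  C <- brownian_covariance(tr)
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  star <- read_newick("(A:1,B:1,C:1);", text = TRUE)
  expect_equal(unname(brownian_covariance(star)), diag(3))
  ## PSD on simulated trees
  for (s in 1:5) {
    tr2 <- simulate_tree(tiny_config(n_genomes = 30, seed = s), seed = s)
    ev <- eigen(brownian_covariance(tr2), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("degenerate and boundary fits reduce to the Poisson GLM", {
  y <- rep(7, 20)
  fit <- fit_poisson_pglmm(y, NULL, diag(20))
  expect_equal(unname(fit$coefficients[1]), log(7), tolerance = 1e-8)
  expect_equal(fit$sigma2_phy, 0)

  set.seed(2)
  y2 <- rpois(60, 12)             # no overdispersion at all
  fit2 <- fit_poisson_glmm_identity(y2)
  expect_equal(unname(fit2$coefficients[1]), log(mean(y2)), tolerance = 1e-2)
  expect_lt(fit2$sigma2_phy, 0.02)
})

test_that("identity-covariance fit agrees with lme4's observation-level fit", {
  skip_if_not_installed("lme4")
  set.seed(31)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  b <- rnorm(n, 0, sqrt(0.4))
  y <- rpois(n, exp(2 + 0.4 * x + b))
  fit <- fit_poisson_glmm_identity(y, cbind(x = x))
  obs <- factor(seq_len(n))
  g <- lme4::glmer(y ~ x + (1 | obs), family = poisson,
                   control = lme4::glmerControl(check.conv.singular = "ignore"))
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(g)),
               tolerance = 0.02)
  expect_equal(fit$sigma2_phy,
               as.numeric(lme4::VarCorr(g)$obs[1]), tolerance = 0.05)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 0.05)
})

test_that("estimates are invariant under joint permutation of genomes", {
  set.seed(41)
  tr <- simulate_tree(tiny_config(n_genomes = 40, seed = 41), seed = 41)
  C <- brownian_covariance(tr)
  eps <- drop(crossprod(chol(C / mean(diag(C))), rnorm(40))) * sqrt(0.3)
  x <- rbinom(40, 1, 0.5)
  y <- rpois(40, exp(2.5 + 0.3 * x + eps))
  f1 <- fit_poisson_pglmm(y, cbind(x = x), C)
  perm <- sample(40)
  f2 <- fit_poisson_pglmm(y[perm], cbind(x = x[perm]), C[perm, perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$sigma2_phy, f2$sigma2_phy, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("the optimum dominates the trivial null model", {
  set.seed(51)
  for (rep in 1:4) {
    tr <- simulate_tree(tiny_config(n_genomes = 30, seed = rep), seed = rep)
    C <- brownian_covariance(tr)
    y <- rpois(30, exp(1.5 + drop(crossprod(chol(C / mean(diag(C))),
                                            rnorm(30))) * 0.5))
    x <- rbinom(30, 1, 0.5)
    fit <- fit_poisson_pglmm(y, cbind(x = x), C)
    lfac <- sum(lgamma(y + 1))
    ll_null <- sum(y * 0 - 1) - lfac  # beta = 0, sigma2 = 0: mu = 1
    expect_gt(fit$loglik, ll_null)
  }
})

test_that("cAIC reduces to GLM AIC at the boundary and rho grows with sigma2", {
  set.seed(61)
  y <- rpois(50, 9)
  x <- rbinom(50, 1, 0.5)
  fit <- fit_poisson_glmm_identity(y, cbind(x = x))
  if (fit$sigma2_phy == 0) {
    glmfit <- glm(y ~ x, family = poisson)
    expect_equal(as.numeric(caic(fit)), AIC(glmfit), tolerance = 1e-6)
    expect_equal(attr(caic(fit), "rho"), 2)
  }
  ## effective dof from the hat-matrix trace is monotone in sigma2
  tr <- simulate_tree(tiny_config(n_genomes = 40, seed = 61), seed = 61)
  C <- brownian_covariance(tr)
  eps <- drop(crossprod(chol(C / mean(diag(C))), rnorm(40))) * sqrt(0.5)
  y2 <- rpois(40, exp(2 + eps))
  base <- fit_poisson_pglmm(y2, NULL, C)
  rhos <- sapply(c(1e-4, 0.1, 0.5, 1), function(s2) {
    forged <- base
    forged$sigma2_phy <- s2
    attr(caic(forged), "rho")
  })
  expect_true(all(diff(rhos) > 0))
  expect_gt(rhos[1], 1 - 1e-6)            # at least the fixed effects
  expect_lt(rhos[4], 1 + 40)              # at most fixed + random
})

test_that("the species battery counts, skips and reports correctly", {
  set.seed(71)
  cfg <- tiny_config(n_genomes = 50, seed = 71)
  ds <- generate_dataset(cfg)
  traits <- cbind(ds$traits,
                  RM = rbinom(nrow(ds$traits), 1, 0.5),
                  Abi = rep(1L, nrow(ds$traits)))   # constant: inestimable
  colnames(traits)[1] <- "CRISPR"
  y <- response_vectors(ds$matrix, ds$annotation)[1:3]
  C <- brownian_covariance(ds$tree)
  bat <- fit_species_battery(y, traits, C, "single")
  expect_equal(nrow(bat$table), 6L)            # 3 responses x 2 estimable
  expect_true("Abi" %in% bat$skipped$system)
  expect_true(all(bat$table$p >= 0 & bat$table$p <= 1))

  joint <- fit_species_battery(y, traits, C, "joint")
  expect_equal(nrow(joint$table), 6L)
  ## responses exclude defense-system gene families by construction
  ann <- ds$annotation
  expect_equal(unname(y$total),
               unname(rowSums(ds$matrix[, ann$defense_system == "none"])))
})
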