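test_that("defense clades follow the 80% purity rule", {
  tr <- read_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);", text = TRUE)
  trait <- c(A = 1, B = 1, C = 0, D = 0, E = 0)
  plus <- find_def_clades(tr, trait, 0.8, 1L)
  expect_equal(length(plus), 1L)
  expect_setequal(plus[[1]]$leaves, c("A", "B"))
  minus <- find_def_clades(tr, trait, 0.8, 0L)
  expect_equal(length(minus), 1L)
  expect_setequal(minus[[1]]$leaves, c("C", "D", "E"))

  all_plus <- find_def_clades(tr, setNames(rep(1, 5), names(trait)), 0.8, 1L)
  expect_equal(length(all_plus), 1L)
  expect_equal(all_plus[[1]]$size, 5L)   # criterion met at the root

  ## alternating cherries: each pure cherry stands alone, no merging
  tr8 <- read_newick(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);",
    text = TRUE)
  alt <- c(A = 1, B = 1, C = 0, D = 0, E = 1, F = 1, G = 0, H = 0)
  plus8 <- find_def_clades(tr8, alt, 0.8, 1L)
  expect_equal(length(plus8), 2L)
  expect_true(all(vapply(plus8, function(x) x$size, 0L) == 2L))
})

test_that("clades are disjoint and purity-valid on random trait maps", {
  set.seed(91)
  for (rep in 1:10) {
    tr <- random_small_tree(sample(6:20, 1))
    trait <- setNames(rbinom(ape::Ntip(tr), 1, runif(1, 0.2, 0.8)),
                      tr$tip.label)
    for (state in 0:1) {
      clades <- find_def_clades(tr, trait, 0.8, state)
      leaves <- unlist(lapply(clades, `[[`, "leaves"))
      expect_equal(anyDuplicated(leaves), 0L)
      for (cl in clades)
        expect_gte(mean(trait[cl$leaves] == state), 0.8)
      ## every leaf matching the state is inside some reported clade
      expect_true(all(names(trait)[trait == state] %in% leaves))
    }
  }
})

test_that("sister pairing applies the singleton-exclusion rule", {
  tr <- read_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);", text = TRUE)
  ## cherry of two singletons: pair excluded
  t1 <- c(A = 1, B = 0, C = 0, D = 0, E = 0)
  p1 <- pair_sisters(find_def_clades(tr, t1, 0.8, 1L),
                     find_def_clades(tr, t1, 0.8, 0L), tr)
  expect_equal(length(p1), 0L)
  ## two-leaf DEF+ against singleton DEF-: valid
  t2 <- c(A = 0, B = 1, C = 0, D = 1, E = 1)
  p2 <- pair_sisters(find_def_clades(tr, t2, 0.8, 1L),
                     find_def_clades(tr, t2, 0.8, 0L), tr)
  expect_equal(length(p2), 1L)
  expect_setequal(p2[[1]]$def_minus$leaves, "C")
  expect_setequal(p2[[1]]$def_plus$leaves, c("D", "E"))
})

test_that("clade rates divide expected events by internal branch length", {
  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  ids <- defenseflux:::branch_ids(tr)
  gains <- matrix(0, length(ids), 2, dimnames = list(ids, c("f1", "f2")))
  losses <- gains
  gains[c("A", "B"), "f1"] <- c(3, 1)   # 4 expected gains inside the cherry
  be <- forge_branch_events(tr, gains, losses)
  cherry <- find_def_clades(tr, c(A = 1, B = 1, C = 0), 0.8, 1L)[[1]]
  r <- clade_rates(be, tr, cherry, families = c("f1", "f2"))
  expect_true(r$defined)
  expect_equal(r$total_length, 2)       # stem branch excluded
  expect_equal(r$gain_rate, 2)          # 4 / 2
  expect_equal(r$loss_rate, 0)

  ## singleton-family exclusion via annotation
  ann <- data.frame(family_id = c("f1", "f2"),
                    mge_class = "none", cog_category = "K",
                    defense_system = "none", mge_resident = FALSE,
                    singleton = c(TRUE, FALSE))
  r2 <- clade_rates(be, tr, cherry, annotation = ann)
  expect_equal(r2$gain_rate, 0)         # all signal was in the singleton

  ## a single-leaf clade has no internal branches: undefined, flagged
  leafC <- find_def_clades(tr, c(A = 0, B = 0, C = 1), 0.8, 1L)[[1]]
  r3 <- clade_rates(be, tr, leafC, families = c("f1", "f2"))
  expect_false(r3$defined)
  expect_true(is.na(r3$gain_rate))
})

test_that("pair depth is the mean parent-to-leaf path and stratifies openly", {
  tr <- read_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);", text = TRUE)
  trait <- c(A = 1, B = 1, C = 0, D = 0, E = 0)
  pair <- pair_sisters(find_def_clades(tr, trait, 0.8, 1L),
                       find_def_clades(tr, trait, 0.8, 0L), tr)[[1]]
  expect_equal(clade_depth(tr, pair), mean(c(2, 2, 2, 3, 3)))  # = 2.4
  expect_equal(clade_depth(tr, pair, "max"), 3)

  expect_equal(stratify(c(1e-6, 1e-5, 5e-4, 1e-3, 2e-3)),
               c("recent", "intermediate", "intermediate", "intermediate",
                 "old"))
})

test_that("log-ratio Wilcoxon matches exact signed-rank behaviour", {
  expect_equal(test_logratios(c(0.8, -0.8))$p, 1)
  r6 <- test_logratios(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  expect_equal(r6$p, 0.03125)           # 2/2^6, two-sided exact
  expect_equal(test_logratios(0.5)$p, 1)
  r <- test_logratios(c(log(2), log(4), Inf, NA, log(3)))
  expect_equal(r$n, 3)
  expect_equal(r$n_undefined, 2)
  expect_equal(r$median_ratio, 3)
  expect_error(test_logratios(c(NA_real_, Inf)), "undefined")
})

test_that("d'Agostino skewness test matches its reference implementation", {
  v <- c(0.12, -1.4, 2.3, 0.5, -0.7, 1.9, 3.2, -0.3, 0.8, -2.1,
         4.5, 0.05, -0.6, 1.1, 2.8, -1.9, 0.4, 5.2, -0.2, 0.9)
  sk <- skewness_test(v)
  ## frozen scipy.stats values for this fixed vector
  expect_equal(sk$skewness, 0.6388333658697519, tolerance = 1e-12)
  expect_lt(abs(sk$z - 1.3826866009872323), 1e-10)
  expect_lt(abs(sk$p - 0.16676098210770596), 1e-10)

  sym <- c(-2, -1, 0, 1, 2, 2, 1, 0, -1, -2)
  s0 <- skewness_test(sym)
  expect_equal(s0$skewness, 0)
  expect_equal(s0$z, 0)
  expect_equal(s0$p, 1)

  set.seed(7)
  ex <- rexp(200)
  se <- skewness_test(ex)
  expect_gt(se$skewness, 0)
  expect_lt(se$p, 0.01)

  expect_error(skewness_test(rnorm(7)), "insufficient n")
})
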