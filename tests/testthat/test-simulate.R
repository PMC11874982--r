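test_that("simulate_tree hits the requested size and height", {
  cfg <- tiny_config(n_genomes = 5)
  tr <- simulate_tree(cfg, seed = 1)
  expect_equal(ape::Ntip(tr), 5L)
  d <- ape::dist.nodes(tr)[1:5, 1:5]
  expect_true(all(d[upper.tri(d)] > 0))
  ## rescaling contract: mean root-to-tip path equals the target exactly
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(mean(depths[1:5]), cfg$tree_height_target, tolerance = 1e-12)

  pure_birth <- simulation_config(n_genomes = 4, birth_rate = 1,
                                  death_rate = 0, seed = 2)
  tb <- simulate_tree(pure_birth, seed = 2)
  expect_equal(tb$Nnode, 3L)   # binary tree combinatorics
})

test_that("MGE histories follow the two-state dynamics", {
  cfg <- tiny_config(n_genomes = 30, mge_gain_rate = 0, mge_loss_rate = 2,
                     n_mge_families = 20)
  tr <- simulate_tree(cfg, seed = 3)
  h <- simulate_mge_history(tr, cfg, seed = 3)
  ## gain rate 0 => stationary root prior is all-absent; nothing can happen
  expect_equal(sum(h$root_states), 0L)
  expect_equal(nrow(h$events), 0L)

  ## symmetric rates + long branches => occupancy near 1/2
  cfg2 <- tiny_config(n_genomes = 40, tree_height_target = 5,
                      mge_gain_rate = 1, mge_loss_rate = 1,
                      n_mge_families = 150)
  tr2 <- simulate_tree(cfg2, seed = 4)
  h2 <- simulate_mge_history(tr2, cfg2, seed = 4)
  expect_equal(mean(h2$leaf_states), 0.5, tolerance = 0.06)
})

test_that("per-branch MGE gain counts match the stationary-flux expectation", {
  ## on a fixed two-leaf tree the expected number of gains per family on a
  ## branch of length t is bounded below by pi0 * (first-gain probability);
  ## for small rate*t it is ~ pi0 * g * t. Use a short branch.
  tr <- read_newick("(A:0.02,B:0.02);", text = TRUE)
  cfg <- tiny_config(mge_gain_rate = 2, mge_loss_rate = 4,
                     n_mge_families = 4000)
  set.seed(9)
  h <- simulate_mge_history(tr, cfg)
  n_gains <- sum(h$events$event == "gain")
  pi0 <- 4 / 6
  expected <- pi0 * 2 * 0.02 * 4000 * 2   # pi0 * g * t per branch, 2 branches
  expect_lt(abs(n_gains - expected) / expected, 0.15)
})

test_that("defense linkage dial behaves at its extremes", {
  cfg1 <- tiny_config(n_genomes = 40, defense_linkage = 1,
                      defense_independent_gain_rate = 0,
                      defense_loss_linkage = 1)
  tr <- simulate_tree(cfg1, seed = 5)
  mge <- simulate_mge_history(tr, cfg1, seed = 5)
  def <- simulate_defense_history(tr, mge, cfg1, seed = 5)
  gains <- def$history$events[def$history$events$event == "gain", ]
  mge_gain_branches <- unique(mge$events$branch[mge$events$event == "gain"])
  expect_true(all(gains$branch %in% mge_gain_branches))

  cfg0 <- tiny_config(n_genomes = 40, defense_linkage = 0,
                      defense_independent_gain_rate = 0)
  def0 <- simulate_defense_history(tr, mge, cfg0, seed = 5)
  expect_equal(sum(def0$traits), 0L)   # no gain mechanism, root absent
})

test_that("co-gain fraction is monotone in the linkage probability", {
  cofrac <- sapply(c(0, 0.3, 0.6, 0.9, 1), function(p) {
    k <- 0; n <- 0
    for (s in 1:4) {
      cfg <- tiny_config(n_genomes = 60, defense_linkage = p,
                         defense_independent_gain_rate = 40, seed = s)
      tr <- simulate_tree(cfg, seed = s)
      mge <- simulate_mge_history(tr, cfg, seed = s + 50)
      def <- simulate_defense_history(tr, mge, cfg, seed = s + 100)
      tbl <- branch_event_table_from_history(tr, def$history, mge)
      k <- k + sum(tbl$def_gain & tbl$mge_gain)
      n <- n + sum(tbl$def_gain)
    }
    k / n
  })
  expect_true(all(diff(cofrac) >= -0.05))   # monotone up to MC noise
  expect_gt(cofrac[5], cofrac[1])
})

test_that("defense presence modulates gene-family gain rates via phi", {
  ## phi = 0: no gains while defense present anywhere
  cfg <- tiny_config(n_genomes = 30, defense_effect = 1e-9,
                     defense_linkage = 1, defense_independent_gain_rate = 5)
  tr <- simulate_tree(cfg, seed = 6)
  mge <- simulate_mge_history(tr, cfg, seed = 6)
  def <- simulate_defense_history(tr, mge, cfg, seed = 6)
  segs <- defenseflux:::defense_segments(tr, def$history)
  fams <- simulate_gene_families(tr, def$history, cfg, seed = 6)
  ev <- fams$history$events
  ev <- ev[ev$event == "gain" & !startsWith(ev$unit, "SGL_") &
             !startsWith(ev$unit, "DSG_"), ]
  for (i in seq_len(nrow(ev))) {
    sg <- segs[[ev$branch[i]]]
    blen <- sum(sg$to - sg$from)
    pos <- ev$position[i] * blen
    seg <- sg[sg$from <= pos & pos <= sg$to, , drop = FALSE]
    expect_equal(unname(seg$def[1]), 0L)  # gains only on defense-free segments
  }

  ## phi = 0.5 halves the realized per-length gain rate on DEF+ segments
  cfg2 <- tiny_config(n_genomes = 60, defense_effect = 0.5,
                      tree_height_target = 0.05,
                      n_families = c(prophage = 300, plasmid = 0,
                                     transposon = 0, neutral = 0),
                      base_gain_rate = c(prophage = 40, plasmid = 0,
                                         transposon = 0, neutral = 0),
                      base_loss_rate = c(prophage = 40, plasmid = 0,
                                         transposon = 0, neutral = 0),
                      defense_linkage = 1,
                      defense_independent_gain_rate = 10,
                      singleton_fraction = 0)
  tr2 <- simulate_tree(cfg2, seed = 7)
  mge2 <- simulate_mge_history(tr2, cfg2, seed = 7)
  def2 <- simulate_defense_history(tr2, mge2, cfg2, seed = 7)
  segs2 <- defenseflux:::defense_segments(tr2, def2$history)
  len_def <- sum(sapply(segs2, function(s) sum((s$to - s$from)[s$def == 1])))
  len_free <- sum(sapply(segs2, function(s) sum((s$to - s$from)[s$def == 0])))
  skip_if(len_def < 0.2 || len_free < 0.2)  # need residence on both states
  fams2 <- simulate_gene_families(tr2, def2$history, cfg2, seed = 7)
  ev2 <- fams2$history$events
  ev2 <- ev2[ev2$event == "gain" & !startsWith(ev2$unit, "DSG_"), ]
  in_def <- vapply(seq_len(nrow(ev2)), function(i) {
    sg <- segs2[[ev2$branch[i]]]
    blen <- sum(sg$to - sg$from)
    pos <- ev2$position[i] * blen
    seg <- sg[sg$from <= pos & pos <= sg$to, , drop = FALSE]
    seg$def[1] == 1L
  }, TRUE)
  rate_def <- sum(in_def) / len_def
  rate_free <- sum(!in_def) / len_free
  expect_equal(rate_def / rate_free, 0.5, tolerance = 0.25)
})

test_that("histories replay exactly and datasets are deterministic", {
  cfg <- tiny_config(seed = 11)
  ds <- generate_dataset(cfg)
  expect_identical(replay_history(ds$tree, ds$mge_history),
                   ds$mge_history$leaf_states)
  rp <- replay_history(ds$tree, ds$family_history)
  expect_identical(rp[rownames(ds$matrix), colnames(ds$matrix)], ds$matrix)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)

  ## files pass the readers and reproduce the in-memory objects
  ds2 <- load_dataset(d1)
  expect_identical(ds2$matrix, ds$matrix[ds2$tree$tip.label, ])
  expect_identical(unname(ds2$traits), unname(ds$traits[ds2$tree$tip.label, ,
                                                        drop = FALSE]))

  ## a class with zero families is absent from the annotation
  cfg0 <- tiny_config(n_families = c(prophage = 10, plasmid = 0,
                                     transposon = 5, neutral = 10),
                      singleton_fraction = 0, seed = 12)
  ds0 <- generate_dataset(cfg0)
  expect_false("plasmid" %in% ds0$annotation$mge_class)
})
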