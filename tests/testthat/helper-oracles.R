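## Independent oracles and small fixtures shared across the suite.

## Exhaustive likelihood of a 0/1 leaf pattern: sum over every assignment
## of internal-node states of prior x product of branch transition
## probabilities. Independent of the pruning recursion.
enum_loglik <- function(tree, pattern, g, l) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  states <- rep(NA_integer_, n_node)
  states[seq_len(n_tip)] <- as.integer(pattern[tree$tip.label])
  pi <- c(l, g) / (g + l)
  root <- n_tip + 1L
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probability(g, l, tree$edge.length[e]))
  combos <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    states[internal] <- combos[r, ]
    p <- pi[states[root] + 1L]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Ps[[e]][states[tree$edge[e, 1]] + 1L,
                       states[tree$edge[e, 2]] + 1L]
    total <- total + p
  }
  log(total)
}

## Deterministic fine-discretization oracle for conditional expected
## transition counts: the jump-time integral
## E[N01 * 1{X_t = b} | X_0 = a] = g * int_0^t P_a0(u) P_1b(t - u) du
## (the chain sits in state 1 right after the counted jump), evaluated by
## the trapezoid rule on the closed-form transition matrix — independent of
## the uniformization series.
expected_transitions_oracle <- function(g, l, t, n_grid = 4001) {
  u <- seq(0, t, length.out = n_grid)
  h <- u[2] - u[1]
  Pt <- transition_probability(g, l, t)
  Pu <- lapply(u, function(x) transition_probability(g, l, x))
  Pv <- lapply(u, function(x) transition_probability(g, l, t - x))
  gains <- losses <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  trap <- function(f) h * (sum(f) - (f[1] + f[length(f)]) / 2)
  for (a in 1:2) for (b in 1:2) {
    jump01 <- vapply(seq_along(u),
                     function(i) Pu[[i]][a, 1] * Pv[[i]][2, b], 0)
    jump10 <- vapply(seq_along(u),
                     function(i) Pu[[i]][a, 2] * Pv[[i]][1, b], 0)
    gains[a, b] <- g * trap(jump01) / Pt[a, b]
    losses[a, b] <- l * trap(jump10) / Pt[a, b]
  }
  list(gains = gains, losses = losses)
}

## Random small tree with strictly positive branch lengths.
random_small_tree <- function(n_tip) {
  tree <- ape::rtree(n_tip, br = function(k) runif(k, 0.05, 1.5))
  validate_strain_tree(tree)
}

## A tiny simulation config for fast dataset fixtures.
tiny_config <- function(...) {
  defaults <- list(n_genomes = 25,
                   n_families = c(prophage = 15, plasmid = 10,
                                  transposon = 10, neutral = 20),
                   n_mge_families = 5, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

## Forge a branch_events object from explicit matrices (used to test the
## clade-rate arithmetic against hand computations).
forge_branch_events <- function(tree, gains, losses) {
  po <- defenseflux:::postorder_edges(tree)
  ids <- po$labels[po$edge[, 2]]
  gains <- gains[ids, , drop = FALSE]
  losses <- losses[ids, , drop = FALSE]
  structure(list(branch = ids, branch_length = po$length,
                 is_terminal = po$edge[, 2] <= po$n_tip,
                 expected_gains = gains, expected_losses = losses,
                 p_gain = 1 * (gains > 0), p_loss = 1 * (losses > 0)),
            class = "branch_events")
}
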