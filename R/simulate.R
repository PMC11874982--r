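## Synthetic species-level datasets with known ground truth: a birth-death
## strain tree, MGE presence histories evolving as two-state Markov chains,
## a defense system whose gains/losses ride MGE gains/losses with tunable
## linkage, and class-labelled gene families whose gain rate is multiplied
## by `defense_effect` wherever the defense system is present.

#' Simulation configuration
#'
#' Defaults describe a typical well-sampled bacterial species: a
#' high-turnover birth-death strain tree of 200 genomes with mean
#' root-to-tip divergence 0.02 substitutions/site in core genes, fast MGE
#' turnover relative to the core-gene clock, strong defense-MGE linkage and
#' a defense system that halves the gene-gain rate while present. All rates
#' are events per substitution/site.
#'
#' @param n_genomes number of leaves (>= 3)
#' @param birth_rate,death_rate birth-death rates (birth > death >= 0)
#' @param tree_height_target mean root-to-tip path length after rescaling
#' @param mge_gain_rate,mge_loss_rate two-state rates for each MGE element
#' @param n_mge_families number of independently evolving MGE elements
#' @param defense_linkage probability that a defense gain rides a branch
#'   carrying at least one MGE gain (`p_link`)
#' @param defense_independent_gain_rate background defense gain rate
#' @param defense_loss_linkage probability that a present defense is lost on
#'   a branch carrying at least one MGE loss (`q_link`)
#' @param n_families named integer vector: gene families per class
#'   (`prophage`, `plasmid`, `transposon`, `neutral`)
#' @param base_gain_rate,base_loss_rate named per-class rates
#' @param defense_effect multiplier on gene gain rate while defense present
#'   (`phi` > 0; < 1 means defense suppresses gene influx)
#' @param singleton_fraction fraction (of total families) of injected
#'   species-wise singleton families
#' @param n_defense_genes gene families emitted with the defense system's
#'   own presence pattern (flagged `defense_system != "none"`)
#' @param defense_system name of the simulated system
#' @param seed integer seed used by [generate_dataset()]
#' @return object of class `"simulation_config"`
#' @export
simulation_config <- function(n_genomes = 200,
                              birth_rate = 1,
                              death_rate = 0.9,
                              tree_height_target = 0.02,
                              mge_gain_rate = 100,
                              mge_loss_rate = 200,
                              n_mge_families = 10,
                              defense_linkage = 0.95,
                              defense_independent_gain_rate = 2,
                              defense_loss_linkage = 0.9,
                              n_families = c(prophage = 150, plasmid = 100,
                                             transposon = 100, neutral = 250),
                              base_gain_rate = c(prophage = 40, plasmid = 30,
                                                 transposon = 30, neutral = 15),
                              base_loss_rate = c(prophage = 120, plasmid = 90,
                                                 transposon = 90, neutral = 45),
                              defense_effect = 0.5,
                              singleton_fraction = 0.1,
                              n_defense_genes = 3,
                              defense_system = "CRISPR",
                              seed = 1L) {
  cfg <- list(n_genomes = as.integer(n_genomes), birth_rate = birth_rate,
              death_rate = death_rate, tree_height_target = tree_height_target,
              mge_gain_rate = mge_gain_rate, mge_loss_rate = mge_loss_rate,
              n_mge_families = as.integer(n_mge_families),
              defense_linkage = defense_linkage,
              defense_independent_gain_rate = defense_independent_gain_rate,
              defense_loss_linkage = defense_loss_linkage,
              n_families = n_families, base_gain_rate = base_gain_rate,
              base_loss_rate = base_loss_rate, defense_effect = defense_effect,
              singleton_fraction = singleton_fraction,
              n_defense_genes = as.integer(n_defense_genes),
              defense_system = defense_system, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_genomes >= 3,
            cfg$birth_rate > cfg$death_rate, cfg$death_rate >= 0,
            cfg$tree_height_target > 0,
            cfg$mge_gain_rate >= 0, cfg$mge_loss_rate >= 0,
            cfg$n_mge_families >= 1,
            cfg$defense_linkage >= 0, cfg$defense_linkage <= 1,
            cfg$defense_independent_gain_rate >= 0,
            cfg$defense_loss_linkage >= 0, cfg$defense_loss_linkage <= 1,
            all(cfg$n_families >= 0), all(cfg$base_gain_rate >= 0),
            all(cfg$base_loss_rate >= 0), cfg$defense_effect > 0,
            cfg$singleton_fraction >= 0, cfg$singleton_fraction <= 1)
  classes <- c("prophage", "plasmid", "transposon", "neutral")
  if (!all(classes %in% names(cfg$n_families)) ||
      !all(classes %in% names(cfg$base_gain_rate)) ||
      !all(classes %in% names(cfg$base_loss_rate)))
    stop("n_families/base_gain_rate/base_loss_rate must name classes ",
         paste(classes, collapse = ", "), call. = FALSE)
  if (!cfg$defense_system %in% DEFENSE_SYSTEMS)
    stop("defense_system must be one of ",
         paste(DEFENSE_SYSTEMS, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys mirror [simulation_config()] arguments
#' @return a `"simulation_config"`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("n_families", "base_gain_rate", "base_loss_rate"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(simulation_config, vals)
}

#' Simulate a birth-death strain tree
#'
#' Birth-death tree conditioned on `n_genomes` extant tips
#' (via [ape::rphylo()]), with branch lengths rescaled so that the mean
#' root-to-tip path equals `tree_height_target` substitutions/site.
#'
#' @param config a [simulation_config()]
#' @param seed optional seed (set before drawing); `NULL` continues the
#'   current RNG stream
#' @return a `"phylo"` strain tree with labelled internal nodes
#' @export
simulate_tree <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- NULL
  for (try in 1:10) {
    tree <- tryCatch(
      ape::rphylo(config$n_genomes, config$birth_rate, config$death_rate,
                  fossils = FALSE),
      error = function(e) NULL)
    if (!is.null(tree) && ape::Ntip(tree) == config$n_genomes) break
    tree <- NULL
  }
  if (is.null(tree))
    stop("birth-death simulation failed to reach ", config$n_genomes,
         " tips after bounded retries", call. = FALSE)
  tree$tip.label <- sprintf("G%03d", seq_len(ape::Ntip(tree)))
  depths <- ape::node.depth.edgelength(tree)
  mean_tip_depth <- mean(depths[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length * config$tree_height_target / mean_tip_depth
  validate_strain_tree(tree)
}

## -- low-level path simulation -----------------------------------------

## One branch of a two-state chain; returns event positions (fractions of
## the branch) and the end state.
sim_branch_2state <- function(state, t, gain, loss) {
  pos <- numeric(0); ev <- character(0)
  tau <- 0
  repeat {
    rate <- if (state == 0L) gain else loss
    if (rate <= 0) break
    tau <- tau + rexp(1L, rate)
    if (tau >= t) break
    state <- 1L - state
    pos <- c(pos, tau / t)
    ev <- c(ev, if (state == 1L) "gain" else "loss")
  }
  list(position = pos, event = ev, end_state = state)
}

## Piecewise version: `segments` has columns from, to (absolute times) and
## def (0/1 defense state); gain rate is gain * phi^def within a segment.
sim_branch_piecewise <- function(state, t, gain, loss, phi, segments) {
  pos <- numeric(0); ev <- character(0)
  for (s in seq_len(nrow(segments))) {
    tau <- segments$from[s]
    seg_end <- segments$to[s]
    g_eff <- gain * if (segments$def[s] == 1L) phi else 1
    repeat {
      rate <- if (state == 0L) g_eff else loss
      if (rate <= 0) break
      tau <- tau + rexp(1L, rate)
      if (tau >= seg_end) break
      state <- 1L - state
      pos <- c(pos, tau / t)
      ev <- c(ev, if (state == 1L) "gain" else "loss")
    }
  }
  list(position = pos, event = ev, end_state = state)
}

## Edges in parent-before-child order plus lookup tables.
edge_order <- function(tree) {
  cw <- ape::reorder.phylo(tree, "cladewise")
  labels <- c(tree$tip.label, tree$node.label)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  list(edge = cw$edge, length = cw$edge.length, labels = labels, root = root,
       n_tip = ape::Ntip(tree))
}

new_event_history <- function(events, root_states, leaf_states, node_states) {
  structure(list(events = events, root_states = root_states,
                 leaf_states = leaf_states, node_states = node_states),
            class = "event_history")
}

empty_events <- function() {
  data.frame(branch = character(0), unit = character(0),
             event = character(0), position = numeric(0))
}

#' Simulate MGE presence histories on a tree
#'
#' Each MGE element evolves as an independent two-state (absent/present)
#' continuous-time Markov chain along the tree, with the root state drawn
#' from the stationary distribution.
#'
#' @param tree strain tree
#' @param config a [simulation_config()]
#' @param seed optional seed
#' @return an `"event_history"`: `events` (branch, unit, event, position in
#'   (0,1)), `root_states`, `leaf_states` (genomes x elements) and
#'   `node_states` (all nodes x elements)
#' @export
simulate_mge_history <- function(tree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eo <- edge_order(tree)
  g <- config$mge_gain_rate; l <- config$mge_loss_rate
  pi1 <- if (g + l > 0) g / (g + l) else 0
  units <- sprintf("MGE_%03d", seq_len(config$n_mge_families))
  n_nodes <- length(eo$labels)
  node_states <- matrix(0L, n_nodes, length(units),
                        dimnames = list(eo$labels, units))
  ev_list <- vector("list", length(units))
  root_states <- setNames(integer(length(units)), units)
  for (f in seq_along(units)) {
    root_states[f] <- rbinom(1L, 1L, pi1)
    state <- integer(n_nodes)
    state[eo$root] <- root_states[f]
    pos <- numeric(0); ev <- character(0); br <- character(0)
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chd <- eo$edge[e, 2]
      sim <- sim_branch_2state(state[par], eo$length[e], g, l)
      state[chd] <- sim$end_state
      if (length(sim$position)) {
        pos <- c(pos, sim$position); ev <- c(ev, sim$event)
        br <- c(br, rep(eo$labels[chd], length(sim$position)))
      }
    }
    node_states[, f] <- state
    ev_list[[f]] <- data.frame(branch = br, unit = rep(units[f], length(br)),
                               event = ev, position = pos)
  }
  events <- do.call(rbind, c(list(empty_events()), ev_list))
  leaf_states <- node_states[seq_len(eo$n_tip), , drop = FALSE]
  new_event_history(events, root_states, leaf_states, node_states)
}

#' Simulate a defense-system history linked to MGE gains and losses
#'
#' The defense system starts absent at the root. On each branch carrying at
#' least one MGE gain, an absent defense is gained with probability
#' `defense_linkage` (placed at the first MGE gain); background gains occur
#' at `defense_independent_gain_rate` while absent. On each branch carrying
#' at least one MGE loss, a present defense is lost with probability
#' `defense_loss_linkage`.
#'
#' @param tree strain tree
#' @param mge_history output of [simulate_mge_history()] on the same tree
#' @param config a [simulation_config()]
#' @param seed optional seed
#' @return list with `history` (an `"event_history"` for the single defense
#'   unit) and `traits` (genomes x 1 0/1 matrix named after the system)
#' @export
simulate_defense_history <- function(tree, mge_history, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eo <- edge_order(tree)
  n_nodes <- length(eo$labels)
  sys <- config$defense_system
  state <- integer(n_nodes)           # defense starts absent at the root
  pos_all <- numeric(0); ev_all <- character(0); br_all <- character(0)
  mge_ev <- mge_history$events
  first_pos <- function(branch, type) {
    p <- mge_ev$position[mge_ev$branch == branch & mge_ev$event == type]
    if (length(p)) min(p) else NA_real_
  }
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; chd <- eo$edge[e, 2]
    blen <- eo$length[e]
    lab <- eo$labels[chd]
    s <- state[par]
    ## candidate events on this branch, in fractional position units
    cand_pos <- numeric(0); cand_type <- character(0); cand_ok <- logical(0)
    pg <- first_pos(lab, "gain")
    if (!is.na(pg)) {
      cand_pos <- c(cand_pos, pg); cand_type <- c(cand_type, "gain")
      cand_ok <- c(cand_ok, runif(1L) < config$defense_linkage)
    }
    pl <- first_pos(lab, "loss")
    if (!is.na(pl)) {
      cand_pos <- c(cand_pos, pl); cand_type <- c(cand_type, "loss")
      cand_ok <- c(cand_ok, runif(1L) < config$defense_loss_linkage)
    }
    if (config$defense_independent_gain_rate > 0 && blen > 0) {
      k <- rpois(1L, config$defense_independent_gain_rate * blen)
      if (k > 0) {
        bg <- sort(runif(k))
        cand_pos <- c(cand_pos, bg)
        cand_type <- c(cand_type, rep("gain", k))
        cand_ok <- c(cand_ok, rep(TRUE, k))   # thinned by the state check
      }
    }
    if (length(cand_pos)) {
      o <- order(cand_pos)
      for (i in o) {
        if (!cand_ok[i]) next
        if (cand_type[i] == "gain" && s == 0L) {
          s <- 1L
          pos_all <- c(pos_all, cand_pos[i]); ev_all <- c(ev_all, "gain")
          br_all <- c(br_all, lab)
        } else if (cand_type[i] == "loss" && s == 1L) {
          s <- 0L
          pos_all <- c(pos_all, cand_pos[i]); ev_all <- c(ev_all, "loss")
          br_all <- c(br_all, lab)
        }
      }
    }
    state[chd] <- s
  }
  node_states <- matrix(state, ncol = 1, dimnames = list(eo$labels, sys))
  leaf_states <- node_states[seq_len(eo$n_tip), , drop = FALSE]
  events <- data.frame(branch = br_all, unit = rep(sys, length(br_all)),
                       event = ev_all, position = pos_all)
  history <- new_event_history(events, setNames(0L, sys), leaf_states,
                               node_states)
  list(history = history, traits = leaf_states)
}

## Defense state segments (absolute time within each branch), from the
## defense history. Returns a list keyed by branch id.
defense_segments <- function(tree, defense_history) {
  eo <- edge_order(tree)
  segs <- vector("list", nrow(eo$edge))
  names(segs) <- eo$labels[eo$edge[, 2]]
  dev <- defense_history$events
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; chd <- eo$edge[e, 2]
    blen <- eo$length[e]
    lab <- eo$labels[chd]
    s0 <- defense_history$node_states[par, 1]
    p <- sort(dev$position[dev$branch == lab])
    bounds <- c(0, p, 1) * blen
    st <- s0
    def <- integer(length(bounds) - 1L)
    for (k in seq_along(def)) { def[k] <- st; st <- 1L - st }
    ## events strictly alternate the state, so toggling per boundary is exact
    segs[[e]] <- data.frame(from = bounds[-length(bounds)],
                            to = bounds[-1], def = def)
  }
  segs
}

#' Simulate gene-family presence/absence under defense-modulated gain rates
#'
#' Each family belongs to a class (`prophage`, `plasmid`, `transposon`,
#' `neutral`) with class-specific base gain/loss rates; the gain rate is
#' multiplied by `defense_effect` on tree segments where the defense system
#' is present. Singleton families (present in exactly one genome) are
#' injected at `singleton_fraction`, and `n_defense_genes` families carrying
#' the defense system's own presence pattern are emitted and flagged.
#'
#' @param tree strain tree
#' @param defense_history the `history` element of
#'   [simulate_defense_history()]
#' @param config a [simulation_config()]
#' @param seed optional seed
#' @return list with `matrix` (genomes x families), `annotation`
#'   (data.frame as in [read_annotation()]) and `history` (ground-truth
#'   `"event_history"` of the stochastically evolved families)
#' @export
simulate_gene_families <- function(tree, defense_history, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eo <- edge_order(tree)
  segs <- defense_segments(tree, defense_history)
  classes <- c("prophage", "plasmid", "transposon", "neutral")
  n_nodes <- length(eo$labels)
  fam_ids <- character(0); fam_class <- character(0)
  for (cl in classes)
    if (config$n_families[[cl]] > 0) {
      ids <- sprintf("%s_%04d", toupper(substr(cl, 1, 2)),
                     seq_len(config$n_families[[cl]]))
      fam_ids <- c(fam_ids, ids)
      fam_class <- c(fam_class, rep(cl, length(ids)))
    }
  n_fam <- length(fam_ids)
  leaf_states <- matrix(0L, eo$n_tip, n_fam,
                        dimnames = list(eo$labels[seq_len(eo$n_tip)], fam_ids))
  root_states <- setNames(integer(n_fam), fam_ids)
  ev_list <- vector("list", n_fam)
  phi <- config$defense_effect
  for (f in seq_len(n_fam)) {
    cl <- fam_class[f]
    g <- config$base_gain_rate[[cl]]; l <- config$base_loss_rate[[cl]]
    pi1 <- if (g + l > 0) g / (g + l) else 0
    root_states[f] <- rbinom(1L, 1L, pi1)
    state <- integer(n_nodes)
    state[eo$root] <- root_states[f]
    pos <- numeric(0); ev <- character(0); br <- character(0)
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chd <- eo$edge[e, 2]
      sim <- sim_branch_piecewise(state[par], eo$length[e], g, l, phi,
                                  segs[[e]])
      state[chd] <- sim$end_state
      if (length(sim$position)) {
        pos <- c(pos, sim$position); ev <- c(ev, sim$event)
        br <- c(br, rep(eo$labels[chd], length(sim$position)))
      }
    }
    leaf_states[, f] <- state[seq_len(eo$n_tip)]
    ev_list[[f]] <- data.frame(branch = br, unit = rep(fam_ids[f], length(br)),
                               event = ev, position = pos)
  }
  events <- do.call(rbind, c(list(empty_events()), ev_list))

  ## injected species-wise singletons (one gain on a terminal branch)
  n_single <- round(config$singleton_fraction * sum(config$n_families))
  if (n_single > 0) {
    active <- classes[config$n_families[classes] > 0]
    s_class <- sample(active, n_single, replace = TRUE,
                      prob = config$n_families[active])
    s_genome <- sample(eo$n_tip, n_single, replace = TRUE)
    s_ids <- sprintf("SGL_%04d", seq_len(n_single))
    s_mat <- matrix(0L, eo$n_tip, n_single,
                    dimnames = list(rownames(leaf_states), s_ids))
    s_mat[cbind(s_genome, seq_len(n_single))] <- 1L
    leaf_states <- cbind(leaf_states, s_mat)
    fam_class <- c(fam_class, s_class)
    fam_ids <- c(fam_ids, s_ids)
    root_states <- c(root_states, setNames(integer(n_single), s_ids))
    events <- rbind(events, data.frame(
      branch = eo$labels[s_genome], unit = s_ids,
      event = rep("gain", n_single), position = runif(n_single)))
  }

  ## gene families belonging to the defense system itself
  if (config$n_defense_genes > 0) {
    d_ids <- sprintf("DSG_%s_%02d", config$defense_system,
                     seq_len(config$n_defense_genes))
    d_mat <- matrix(rep(defense_history$leaf_states[, 1],
                        config$n_defense_genes),
                    ncol = config$n_defense_genes,
                    dimnames = list(rownames(leaf_states), d_ids))
    storage.mode(d_mat) <- "integer"
    leaf_states <- cbind(leaf_states, d_mat)
    fam_class <- c(fam_class, rep("none", config$n_defense_genes))
    fam_ids <- c(fam_ids, d_ids)
    root_states <- c(root_states, setNames(integer(config$n_defense_genes),
                                           d_ids))
    dh <- defense_history$events
    if (nrow(dh))
      events <- rbind(events, do.call(rbind, lapply(d_ids, function(id) {
        data.frame(branch = dh$branch, unit = id, event = dh$event,
                   position = dh$position)
      })))
  }

  defense_label <- ifelse(startsWith(fam_ids, "DSG_"),
                          config$defense_system, "none")
  is_mge_class <- fam_class %in% c("prophage", "plasmid", "transposon")
  cog_pool <- c("J", "K", "L", "E", "C", "M", "P", "T")
  cog <- ifelse(is_mge_class, "X", sample(cog_pool, length(fam_ids),
                                          replace = TRUE))
  cog[defense_label != "none"] <- "V"
  annotation <- data.frame(
    family_id = fam_ids,
    mge_class = ifelse(defense_label != "none" | fam_class == "neutral",
                       "none", fam_class),
    cog_category = cog,
    defense_system = defense_label,
    mge_resident = is_mge_class & defense_label == "none",
    singleton = colSums(leaf_states) == 1L)
  history <- new_event_history(events, root_states, leaf_states,
                               node_states = NULL)
  list(matrix = leaf_states, annotation = annotation, history = history)
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_tree()], [simulate_mge_history()],
#' [simulate_defense_history()] and [simulate_gene_families()] under a
#' single seed and (optionally) writes the standard file bundle:
#' `tree.nwk`, `matrix.Rtab`, `traits.tsv`, `annotation.tsv`, `events.tsv`
#' and `config.yml`. Byte-identical for identical config + seed.
#'
#' @param config a [simulation_config()]
#' @param out_dir optional output directory (created if needed)
#' @return list with `tree`, `matrix`, `traits`, `annotation`,
#'   `mge_history`, `defense_history`, `family_history`, `config`
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  tree <- simulate_tree(config)
  mge <- simulate_mge_history(tree, config)
  def <- simulate_defense_history(tree, mge, config)
  fams <- simulate_gene_families(tree, def$history, config)
  bundle <- list(tree = tree, matrix = fams$matrix, traits = def$traits,
                 annotation = fams$annotation, mge_history = mge,
                 defense_history = def$history, family_history = fams$history,
                 config = config)
  log_stage("simulate", seed = config$seed, n_genomes = ape::Ntip(tree),
            n_families = ncol(fams$matrix),
            n_events = nrow(fams$history$events))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_rtab(fams$matrix, file.path(out_dir, "matrix.Rtab"))
    write_trait_table(def$traits, file.path(out_dir, "traits.tsv"))
    write_annotation(fams$annotation, file.path(out_dir, "annotation.tsv"))
    all_ev <- rbind(mge$events, def$history$events, fams$history$events)
    write_table(all_ev[order(all_ev$unit, all_ev$branch, all_ev$position), ],
                file.path(out_dir, "events.tsv"))
    cfg <- unclass(config)
    cfg$n_families <- as.list(cfg$n_families)
    cfg$base_gain_rate <- as.list(cfg$base_gain_rate)
    cfg$base_loss_rate <- as.list(cfg$base_loss_rate)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yml"))
  }
  bundle
}

#' Replay an event history from root states
#'
#' Recomputes leaf states by applying the recorded gains and losses along
#' the tree; used to verify that emitted matrices and histories agree.
#'
#' @param tree strain tree
#' @param history an `"event_history"`
#' @return genomes x units integer matrix
#' @export
replay_history <- function(tree, history) {
  eo <- edge_order(tree)
  units <- names(history$root_states)
  n_nodes <- length(eo$labels)
  out <- matrix(0L, eo$n_tip, length(units),
                dimnames = list(eo$labels[seq_len(eo$n_tip)], units))
  ev <- history$events
  for (f in seq_along(units)) {
    state <- integer(n_nodes)
    state[eo$root] <- history$root_states[f]
    fe <- ev[ev$unit == units[f], , drop = FALSE]
    n_on <- table(fe$branch)
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chd <- eo$edge[e, 2]
      lab <- eo$labels[chd]
      k <- if (lab %in% names(n_on)) n_on[[lab]] else 0L
      ## events strictly alternate states, so parity determines the child
      state[chd] <- if (k %% 2L == 0L) state[par] else 1L - state[par]
    }
    out[, f] <- state[seq_len(eo$n_tip)]
  }
  out
}

#' Ground-truth per-branch event counts
#'
#' True numbers of gains and losses per branch and family from a simulated
#' history, in the same layout as [branch_expected_events()] so that
#' [clade_rates()] and [clade_flux_table()] can run on ground truth.
#'
#' @param tree strain tree
#' @param history an `"event_history"` (e.g. `family_history` of
#'   [generate_dataset()])
#' @return object of class `"branch_events"` whose `expected_gains` /
#'   `expected_losses` hold the true counts and whose `p_gain` / `p_loss`
#'   are event indicators
#' @export
branch_counts_from_history <- function(tree, history) {
  eo <- edge_order(tree)
  ids <- eo$labels[eo$edge[, 2]]
  units <- names(history$root_states)
  ev <- history$events
  count_mat <- function(type) {
    sub <- ev[ev$event == type, c("branch", "unit")]
    m <- matrix(0, length(ids), length(units), dimnames = list(ids, units))
    if (nrow(sub)) {
      tab <- table(factor(sub$branch, levels = ids),
                   factor(sub$unit, levels = units))
      m <- m + unclass(tab)
    }
    m
  }
  gains <- count_mat("gain")
  losses <- count_mat("loss")
  structure(list(branch = ids, branch_length = eo$length,
                 is_terminal = eo$edge[, 2] <= eo$n_tip,
                 expected_gains = gains, expected_losses = losses,
                 p_gain = 1 * (gains > 0), p_loss = 1 * (losses > 0)),
            class = "branch_events")
}

#' Ground-truth per-branch event table
#'
#' Collapses simulated histories to the binary per-branch event calls used
#' by the linkage statistics: whether the defense system and whether any
#' MGE element was gained/lost on each branch.
#'
#' @param tree strain tree
#' @param defense_history defense `"event_history"`
#' @param mge_history MGE `"event_history"`
#' @return data.frame: branch, def_gain, def_loss, mge_gain, mge_loss,
#'   branch_length, is_terminal
#' @export
branch_event_table_from_history <- function(tree, defense_history,
                                            mge_history) {
  eo <- edge_order(tree)
  ids <- eo$labels[eo$edge[, 2]]
  has_event <- function(ev, type)
    ids %in% ev$branch[ev$event == type]
  data.frame(
    branch = ids,
    def_gain = as.integer(has_event(defense_history$events, "gain")),
    def_loss = as.integer(has_event(defense_history$events, "loss")),
    mge_gain = as.integer(has_event(mge_history$events, "gain")),
    mge_loss = as.integer(has_event(mge_history$events, "loss")),
    branch_length = eo$length,
    is_terminal = eo$edge[, 2] <= eo$n_tip)
}
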