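## DEF+ clades and their DEF- sisters: detection by the 80%-purity rule,
## per-clade gain/loss rates (expected events per unit branch length,
## singletons excluded, stem branch excluded), log-ratio tests, depth
## stratification and the d'Agostino skewness test.

## Descendant-leaf bookkeeping per node.
node_leaf_counts <- function(tree, trait, state = 1L) {
  po <- postorder_edges(tree)
  x <- as.integer(trait[tree$tip.label] == state)
  n_leaves <- c(rep(1L, po$n_tip), integer(po$n_node - po$n_tip))
  n_match <- c(x, integer(po$n_node - po$n_tip))
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chd <- po$edge[e, 2]
    n_leaves[par] <- n_leaves[par] + n_leaves[chd]
    n_match[par] <- n_match[par] + n_match[chd]
  }
  list(po = po, n_leaves = n_leaves, n_match = n_match)
}

descendant_tips <- function(tree, node) {
  if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
  tree$tip.label[unlist(ape::prop.part(tree)[[node - ape::Ntip(tree)]])]
}

#' Find maximal defense-defined clades
#'
#' Clades in which at least `purity` of the leaves carry (`state = 1`,
#' DEF+) or lack (`state = 0`, DEF-) the defense system, and that are not
#' nested inside any larger qualifying clade. Single leaves qualify as
#' singleton clades.
#'
#' @param tree strain tree
#' @param trait named 0/1 vector over all leaves
#' @param purity minimal fraction of matching leaves (default 0.8)
#' @param state 1 for DEF+ clades, 0 for DEF-
#' @return list of clades: `node` (internal id), `label`, `leaves`, `size`
#' @export
find_def_clades <- function(tree, trait, purity = 0.8, state = 1L) {
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait must cover all leaves", call. = FALSE)
  cnt <- node_leaf_counts(tree, trait, state)
  po <- cnt$po
  qual <- cnt$n_match / cnt$n_leaves >= purity
  ## a clade is reported iff it qualifies and no ancestor qualifies
  anc_qual <- logical(po$n_node)
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
    par <- po$edge[e, 1]; chd <- po$edge[e, 2]
    anc_qual[chd] <- anc_qual[par] || qual[par]
  }
  keep <- which(qual & !anc_qual)
  lapply(keep, function(v) {
    leaves <- descendant_tips(tree, v)
    list(node = v, label = po$labels[v], leaves = leaves,
         size = length(leaves))
  })
}

#' Pair DEF+ clades with DEF- sister clades
#'
#' Pairs whose two clades are children of the same node; pairs in which
#' both clades are singletons (single genomes) are excluded.
#'
#' @param def_plus,def_minus clade lists from [find_def_clades()]
#' @param tree strain tree
#' @return list of pairs: `def_plus`, `def_minus`, `parent` (node id)
#' @export
pair_sisters <- function(def_plus, def_minus, tree) {
  parent_of <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  pairs <- list()
  for (cp in def_plus) for (cm in def_minus) {
    if (parent_of[cp$node] != 0 && parent_of[cp$node] == parent_of[cm$node]) {
      if (cp$size == 1L && cm$size == 1L) next    # both singletons
      pairs[[length(pairs) + 1L]] <-
        list(def_plus = cp, def_minus = cm, parent = parent_of[cp$node])
    }
  }
  pairs
}

## Edge indices (rows of tree$edge) strictly inside a clade: all edges
## whose parent is the clade node or a descendant of it. The stem branch
## is excluded by construction.
clade_edges <- function(tree, node) {
  inside <- logical(ape::Ntip(tree) + tree$Nnode)
  inside[node] <- TRUE
  cw <- stats::reorder(tree, "cladewise")
  keep <- logical(nrow(cw$edge))
  for (e in seq_len(nrow(cw$edge))) {
    if (inside[cw$edge[e, 1]]) {
      keep[e] <- TRUE
      inside[cw$edge[e, 2]] <- TRUE
    }
  }
  ## map back to tree$edge order via child ids
  match(cw$edge[keep, 2], tree$edge[, 2])
}

#' Gain and loss rates within a clade
#'
#' Rate = summed expected events over the clade's internal branches
#' (families passing the filter; species-wise singletons excluded) divided
#' by the summed internal branch length. The clade's stem branch is
#' excluded from both sums. Singleton clades (single leaves) have no
#' internal branches and return `NA` rates with `defined = FALSE`.
#'
#' @param be a `"branch_events"` object (or a ground-truth equivalent with
#'   `branch`, `expected_gains`, `expected_losses` matrices)
#' @param tree strain tree
#' @param clade one clade from [find_def_clades()]
#' @param families family ids to include (default: all non-singleton)
#' @param annotation optional annotation used to drop singleton families
#'   when `families` is `NULL`
#' @return list: `gain_rate`, `loss_rate`, `total_length`, `defined`
#' @export
clade_rates <- function(be, tree, clade, families = NULL, annotation = NULL) {
  if (is.null(families)) {
    families <- colnames(be$expected_gains)
    if (!is.null(annotation))
      families <- setdiff(families,
                          annotation$family_id[annotation$singleton])
  }
  idx <- match(families, colnames(be$expected_gains))
  if (anyNA(idx)) stop("unknown family id", call. = FALSE)
  edges <- clade_edges(tree, clade$node)
  if (!length(edges))
    return(list(gain_rate = NA_real_, loss_rate = NA_real_,
                total_length = 0, defined = FALSE))
  rows <- match(branch_ids(tree)[edges], be$branch)
  len <- sum(tree$edge.length[edges])
  if (len <= 0)
    return(list(gain_rate = NA_real_, loss_rate = NA_real_,
                total_length = len, defined = FALSE))
  list(gain_rate = sum(be$expected_gains[rows, idx]) / len,
       loss_rate = sum(be$expected_losses[rows, idx]) / len,
       total_length = len, defined = TRUE)
}

#' Depth of a sister pair
#'
#' Mean path length from the pair's parent node to its descendant leaves
#' (substitutions/site). `method = "max"` uses the maximum leaf distance
#' instead.
#'
#' @param tree strain tree
#' @param pair one pair from [pair_sisters()]
#' @param method `"mean"` (default) or `"max"`
#' @return depth (scalar)
#' @export
clade_depth <- function(tree, pair, method = c("mean", "max")) {
  method <- match.arg(method)
  depths <- ape::node.depth.edgelength(tree)
  tips <- c(match(pair$def_plus$leaves, tree$tip.label),
            match(pair$def_minus$leaves, tree$tip.label))
  d <- depths[tips] - depths[pair$parent]
  if (method == "mean") mean(d) else max(d)
}

#' Stratify depths into recent / intermediate / old
#'
#' Open intervals: `depth < recent` is "recent", `depth > old` is "old",
#' anything else (boundaries included) is "intermediate".
#'
#' @param depth numeric vector of pair depths
#' @param recent,old cutoffs in substitutions/site
#' @return character vector of stratum labels
#' @export
stratify <- function(depth, recent = 1e-5, old = 1e-3) {
  ifelse(depth < recent, "recent", ifelse(depth > old, "old", "intermediate"))
}

#' Wilcoxon signed-rank test of log-ratios against zero
#'
#' Two-sided test that DEF+/DEF- log rate ratios are centred at 0;
#' non-finite log-ratios (a zero rate on either side) are dropped and
#' counted.
#'
#' @param log_ratios numeric vector
#' @return list: `median_ratio` (back-transformed), `p`, `n`, `n_undefined`
#' @export
test_logratios <- function(log_ratios) {
  finite <- log_ratios[is.finite(log_ratios)]
  if (!length(finite)) stop("all log-ratios undefined", call. = FALSE)
  p <- suppressWarnings(wilcox.test(finite, mu = 0)$p.value)
  list(median_ratio = exp(median(finite)), p = p, n = length(finite),
       n_undefined = sum(!is.finite(log_ratios)))
}

#' d'Agostino test of sample skewness
#'
#' Biased sample skewness `g1 = m3 / m2^(3/2)` with d'Agostino's normal
#' approximation of its null distribution (the transformation behind
#' scipy's `skewtest`). Two-sided. Requires `n >= 8` for validity.
#'
#' @param values numeric vector, `n >= 8`
#' @return list: `skewness` (g1), `z`, `p`, `n`
#' @export
skewness_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) stop("insufficient n for skewtest (need >= 8)", call. = FALSE)
  m <- values - mean(values)
  m2 <- mean(m^2); m3 <- mean(m^3)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  z <- delta * asinh(y / alpha)       # continuous in y; z = 0 at g1 = 0
  list(skewness = g1, z = z, p = 2 * pnorm(-abs(z)), n = n)
}

#' Sister-clade flux table
#'
#' Detects DEF+ and DEF- clades, pairs sisters, and computes per-pair,
#' per-family-class gain/loss rates, log-ratios, depth and stratum.
#'
#' @param tree strain tree
#' @param trait named 0/1 defense presence vector over leaves
#' @param be a `"branch_events"` object (inferred or ground truth)
#' @param annotation family annotation (classes and singleton flags)
#' @param classes family classes to report (`"all"` pools every
#'   non-singleton, non-defense family)
#' @param purity clade purity threshold
#' @param recent,old depth cutoffs for [stratify()]
#' @return data.frame, one row per pair x class
#' @export
clade_flux_table <- function(tree, trait, be, annotation,
                             classes = c("all", "prophage", "plasmid",
                                         "transposon"),
                             purity = 0.8, recent = 1e-5, old = 1e-3) {
  plus <- find_def_clades(tree, trait, purity, state = 1L)
  minus <- find_def_clades(tree, trait, purity, state = 0L)
  pairs <- pair_sisters(plus, minus, tree)
  if (!length(pairs)) return(data.frame())
  keep_base <- !annotation$singleton & annotation$defense_system == "none"
  rows <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    depth <- clade_depth(tree, pr)
    stratum <- stratify(depth, recent, old)
    for (cl in classes) {
      fams <- annotation$family_id[keep_base &
        (if (cl == "all") TRUE else annotation$mge_class == cl)]
      if (!length(fams)) next
      rp <- clade_rates(be, tree, pr$def_plus, fams)
      rm_ <- clade_rates(be, tree, pr$def_minus, fams)
      lg <- if (isTRUE(rp$defined) && isTRUE(rm_$defined) &&
                rp$gain_rate > 0 && rm_$gain_rate > 0)
        log(rp$gain_rate / rm_$gain_rate) else NA_real_
      ll <- if (isTRUE(rp$defined) && isTRUE(rm_$defined) &&
                rp$loss_rate > 0 && rm_$loss_rate > 0)
        log(rp$loss_rate / rm_$loss_rate) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        pair = i, class = cl,
        plus_label = pr$def_plus$label, minus_label = pr$def_minus$label,
        plus_size = pr$def_plus$size, minus_size = pr$def_minus$size,
        gain_rate_plus = rp$gain_rate, gain_rate_minus = rm_$gain_rate,
        loss_rate_plus = rp$loss_rate, loss_rate_minus = rm_$loss_rate,
        log_gain_ratio = lg, log_loss_ratio = ll,
        depth = depth, stratum = stratum)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-stratum summary of log gain-ratios
#'
#' Median ratio, Wilcoxon p, and (where `n >= 8`) d'Agostino skewness per
#' depth stratum for one family class.
#'
#' @param flux output of [clade_flux_table()]
#' @param class family class to summarize
#' @param value `"log_gain_ratio"` or `"log_loss_ratio"`
#' @return data.frame, one row per stratum
#' @export
stratum_summary <- function(flux, class = "all", value = "log_gain_ratio") {
  sub <- flux[flux$class == class, ]
  out <- lapply(unique(sub$stratum), function(st) {
    v <- sub[[value]][sub$stratum == st]
    fin <- v[is.finite(v)]
    sk <- if (length(fin) >= 8) skewness_test(fin)
          else list(skewness = NA_real_, z = NA_real_, p = NA_real_)
    wp <- if (length(fin)) suppressWarnings(wilcox.test(fin, mu = 0)$p.value)
          else NA_real_
    data.frame(stratum = st, n = length(fin),
               n_undefined = sum(!is.finite(v)),
               median_log_ratio = if (length(fin)) median(fin) else NA_real_,
               wilcoxon_p = wp, skewness = sk$skewness, skew_z = sk$z,
               skew_p = sk$p)
  })
  do.call(rbind, out)
}
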