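## Maximum-likelihood two-state (absent/present) gain/loss model over gene
## families on a fixed tree: discretized-gamma rate categories scaling gain
## and loss jointly, stationary root frequencies, Felsenstein pruning, and
## per-branch posterior expected transition counts via uniformization.

#' Two-state transition probability matrix
#'
#' Closed form for the absent/present chain with gain rate `g` (0 -> 1) and
#' loss rate `l` (1 -> 0) over time `t`:
#' `P01(t) = g/(g+l) * (1 - exp(-(g+l) t))`.
#'
#' @param g,l non-negative rates (not both zero)
#' @param t non-negative time (substitutions/site)
#' @return 2x2 matrix, rows = state at time 0 (`"0"`, `"1"`)
#' @export
transition_probability <- function(g, l, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  if (g < 0 || l < 0) stop("rates must be >= 0", call. = FALSE)
  s <- g + l
  if (s == 0) stop("g and l must not both be zero", call. = FALSE)
  e <- exp(-s * t)
  p01 <- g / s * (1 - e)
  p10 <- l / s * (1 - e)
  matrix(c(1 - p01, p10, p01, 1 - p10), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Discretized-gamma rate multipliers
#'
#' `K` equal-probability categories of a gamma distribution with shape and
#' rate `alpha` (mean 1), represented by their quantile midpoints and
#' normalized to mean exactly 1.
#'
#' @param alpha gamma shape (> 0)
#' @param K number of categories
#' @return numeric vector of length `K` with mean 1
#' @export
gamma_rate_categories <- function(alpha, K) {
  stopifnot(alpha > 0, K >= 1)
  if (K == 1) return(1)
  r <- qgamma((seq_len(K) - 0.5) / K, shape = alpha, rate = alpha)
  r / mean(r)
}

#' Construct a gain/loss model
#'
#' @param gain_rate,loss_rate positive rates (events per substitution/site)
#' @param gamma_shape shape of the shared rate-category gamma
#' @param n_categories number of discretized-gamma categories
#' @return object of class `"gainloss_model"` with stationary `root_prior`
#' @export
gainloss_model <- function(gain_rate, loss_rate, gamma_shape = 1,
                           n_categories = 4L) {
  stopifnot(gain_rate > 0, loss_rate > 0, gamma_shape > 0, n_categories >= 1)
  pi1 <- gain_rate / (gain_rate + loss_rate)
  structure(list(gain_rate = gain_rate, loss_rate = loss_rate,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 rate_categories = gamma_rate_categories(gamma_shape,
                                                         n_categories),
                 root_prior = c("0" = 1 - pi1, "1" = pi1)),
            class = "gainloss_model")
}

#' @export
print.gainloss_model <- function(x, ...) {
  cat("Two-state gain/loss model\n",
      "  gain rate: ", format(x$gain_rate, digits = 6), "\n",
      "  loss rate: ", format(x$loss_rate, digits = 6), "\n",
      "  gamma shape: ", format(x$gamma_shape, digits = 6),
      " (", x$n_categories, " categories)\n",
      "  root prior (present): ", format(x$root_prior[2], digits = 6), "\n",
      sep = "")
  if (!is.null(x$loglik))
    cat("  log-likelihood: ", format(x$loglik, digits = 8), "\n", sep = "")
  invisible(x)
}

## Postorder edge structure shared by pruning passes.
postorder_edges <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  list(edge = po$edge, length = po$edge.length,
       n_tip = ape::Ntip(tree), n_node = ape::Ntip(tree) + tree$Nnode,
       root = ape::Ntip(tree) + 1L,
       labels = c(tree$tip.label, tree$node.label))
}

## 2 x n_fam slice of a (2, n_fam, n_node) array without dimension drop.
slice2 <- function(A, i) matrix(A[, , i], nrow = 2)

## Per-family log-likelihoods at a single rate category, vectorized over
## the columns of X (genomes x families, rows in tip order). Postorder
## guarantees every edge's child subtree is complete when the edge is
## visited, so each child's (rescaled) partials are final before its stem
## message is formed.
pruning_pass <- function(po, X, g, l, keep = FALSE) {
  n_fam <- ncol(X)
  D <- array(1, c(2, n_fam, po$n_node))          # inside partials
  M <- vector("list", nrow(po$edge))             # per-edge child messages
  P <- vector("list", nrow(po$edge))
  logscale <- numeric(n_fam)
  for (i in seq_len(po$n_tip))
    D[, , i] <- rbind(1 - X[i, ], X[i, ])
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chd <- po$edge[e, 2]
    Dc <- slice2(D, chd)
    if (chd > po$n_tip) {                        # child complete: rescale
      sc <- pmax(Dc[1, ], Dc[2, ])
      sc[sc == 0] <- 1
      Dc <- Dc / rep(sc, each = 2)
      D[, , chd] <- Dc
      logscale <- logscale + log(sc)
    }
    P[[e]] <- transition_probability(g, l, po$length[e])
    M[[e]] <- P[[e]] %*% Dc
    D[, , par] <- slice2(D, par) * M[[e]]
  }
  Dr <- slice2(D, po$root)
  ll <- log(colSums(Dr * c(l, g) / (g + l))) + logscale
  if (!keep) return(list(loglik = ll))
  list(loglik = ll, D = D, M = M, P = P)
}

logsumexp_rows <- function(mat) {
  m <- apply(mat, 2, max)
  m + log(colSums(exp(sweep(mat, 2, m))))
}

#' Log-likelihood of one phyletic pattern
#'
#' Category-averaged Felsenstein pruning likelihood of a 0/1 leaf pattern
#' under a [gainloss_model()], with the stationary root prior.
#'
#' @param tree strain tree
#' @param pattern named 0/1 vector covering all leaves
#' @param model a `"gainloss_model"`
#' @return log-likelihood (scalar)
#' @export
family_loglik <- function(tree, pattern, model) {
  if (!all(tree$tip.label %in% names(pattern)))
    stop("pattern must provide a state for every leaf", call. = FALSE)
  X <- matrix(pattern[tree$tip.label], ncol = 1,
              dimnames = list(tree$tip.label, "fam"))
  matrix_loglik(tree, X, model)[1]
}

## Vectorized category-averaged log-likelihoods for all columns of X,
## through the compiled pruning kernel.
matrix_loglik <- function(tree, X, model) {
  po <- postorder_edges(tree)
  X <- X[tree$tip.label, , drop = FALSE]
  storage.mode(X) <- "integer"
  lls <- pruning_loglik_cpp(po$edge, po$length, po$n_tip, po$n_node, X,
                            model$gain_rate, model$loss_rate,
                            model$rate_categories)
  ## average over equal-probability categories on the likelihood scale
  logsumexp_rows(t(lls)) - log(ncol(lls))
}

#' Fit the gain/loss model by maximum likelihood
#'
#' Maximizes the summed category-averaged pruning log-likelihood over
#' (gain rate, loss rate, gamma shape) by bounded quasi-Newton (L-BFGS-B on
#' the log scale) from a fixed multi-start grid: rates in \{0.1, 1, 10\}
#' times a data-scale factor, shape in \{0.5, 1, 5\}. Deterministic.
#'
#' @param tree strain tree
#' @param X presence matrix (genomes x families); at least two non-constant
#'   columns required
#' @param K number of gamma categories (default 4)
#' @return a fitted `"gainloss_model"` with `loglik` and `optim` details
#' @export
fit_gainloss <- function(tree, X, K = 4L) {
  X <- match_tree_data(tree, X)
  cs <- colSums(X)
  non_constant <- sum(cs > 0 & cs < nrow(X))
  if (non_constant < 2)
    stop("no signal: need >= 2 non-constant family patterns", call. = FALSE)
  po <- postorder_edges(tree)
  Xi <- X
  storage.mode(Xi) <- "integer"
  ## scale rates relative to tree size so the grid covers the right regime
  scale0 <- 1 / mean(po$length[po$length > 0])
  nll <- function(par) {
    g <- exp(par[1]); l <- exp(par[2])
    alpha <- if (K > 1) exp(par[3]) else 1
    rates <- gamma_rate_categories(alpha, K)
    lls <- pruning_loglik_cpp(po$edge, po$length, po$n_tip, po$n_node, Xi,
                              g, l, rates)
    -sum(logsumexp_rows(t(lls)) - log(ncol(lls)))
  }
  grid <- expand.grid(g = log(c(0.1, 1, 10) * scale0 * 0.1),
                      l = log(c(0.1, 1, 10) * scale0 * 0.1),
                      a = if (K > 1) log(c(0.5, 1, 5)) else 0)
  grid_val <- apply(grid, 1, function(p) nll(if (K > 1) p else p[1:2]))
  starts <- grid[order(grid_val)[seq_len(min(3, nrow(grid)))], , drop = FALSE]
  lower <- c(log(1e-4 * scale0), log(1e-4 * scale0), log(0.05))
  upper <- c(log(1e3 * scale0), log(1e3 * scale0), log(50))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    if (K == 1) p0 <- p0[1:2]
    opt <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B",
            lower = if (K > 1) lower else lower[1:2],
            upper = if (K > 1) upper else upper[1:2],
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best)) stop("gain/loss optimization failed", call. = FALSE)
  model <- gainloss_model(exp(best$par[1]), exp(best$par[2]),
                          if (K > 1) exp(best$par[3]) else 1, K)
  model$loglik <- -best$value
  model$convergence <- best$convergence
  model
}

## Probability that a path from a to b over time t contains no 0->1 (gain)
## transition, divided out later against P_ab. Closed forms.
prob_no_gain <- function(g, l, t) {
  out <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  out[1, 1] <- exp(-g * t)
  out[2, 2] <- exp(-l * t)
  out[2, 1] <- if (abs(l - g) < 1e-12) l * t * exp(-l * t)
               else l * (exp(-g * t) - exp(-l * t)) / (l - g)
  out
}

prob_no_loss <- function(g, l, t) {
  m <- prob_no_gain(l, g, t)     # symmetry: swap the roles of the states
  m[c(2, 1), c(2, 1)]
}

#' Conditional expected transition counts on one branch
#'
#' Expected numbers of 0 -> 1 (gain) and 1 -> 0 (loss) transitions over a
#' branch of length `t`, conditional on the endpoint states, computed by
#' uniformization with the Poisson series truncated at `tol` tail mass.
#'
#' @param g,l gain/loss rates
#' @param t branch length
#' @param tol truncation tail mass
#' @return list of 2x2 matrices `gains` and `losses` indexed by
#'   (start state, end state)
#' @export
expected_transitions <- function(g, l, t, tol = 1e-10) {
  zero <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  if (t == 0 || g + l == 0) return(list(gains = zero, losses = zero))
  lam <- g + l
  R <- matrix(c(1 - g / lam, l / lam, g / lam, 1 - l / lam), 2, 2)
  Eg <- matrix(c(0, 0, R[1, 2], 0), 2, 2)   # uniformized jumps that gain
  El <- matrix(c(0, R[2, 1], 0, 0), 2, 2)   # uniformized jumps that lose
  n_max <- max(2L, qpois(1 - tol, lam * t) + 2L)
  pois <- dpois(seq_len(n_max), lam * t)
  Rn <- R                                   # R^n
  Cg <- Eg; Cl <- El                        # C(n) recursions
  num_g <- pois[1] * Cg
  num_l <- pois[1] * Cl
  for (n in seq_len(n_max - 1L)) {
    Cg <- R %*% Cg + Eg %*% Rn
    Cl <- R %*% Cl + El %*% Rn
    Rn <- Rn %*% R
    num_g <- num_g + pois[n + 1L] * Cg
    num_l <- num_l + pois[n + 1L] * Cl
  }
  P <- transition_probability(g, l, t)
  P[P < 1e-300] <- 1e-300
  dimnames(num_g) <- dimnames(num_l) <- dimnames(zero)
  list(gains = num_g / P, losses = num_l / P)
}

#' Per-branch posterior expected gains and losses
#'
#' For every branch and family: the posterior expected number of 0 -> 1 and
#' 1 -> 0 transitions given the leaf data, and the posterior probability of
#' at least one gain/loss, averaged over rate categories. Endpoint joint
#' posteriors come from inside-outside pruning; conditional expected counts
#' from [expected_transitions()] (uniformization).
#'
#' @param tree strain tree
#' @param X presence matrix (genomes x families)
#' @param model fitted [gainloss_model()]
#' @return object of class `"branch_events"`: `branch` (child-node labels),
#'   `branch_length`, `is_terminal`, and branch x family matrices
#'   `expected_gains`, `expected_losses`, `p_gain`, `p_loss`
#' @export
branch_expected_events <- function(tree, X, model) {
  X <- match_tree_data(tree, X)
  po <- postorder_edges(tree)
  n_fam <- ncol(X)
  n_edge <- nrow(po$edge)
  rates <- model$rate_categories
  K <- length(rates)
  cat_res <- vector("list", K)
  lls <- matrix(0, n_fam, K)
  for (k in seq_len(K)) {
    g <- model$gain_rate * rates[k]
    l <- model$loss_rate * rates[k]
    pp <- pruning_pass(po, X, g, l, keep = TRUE)
    lls[, k] <- pp$loglik
    pi <- c(l, g) / (g + l)
    ## outside pass (preorder = reversed postorder edges)
    U <- array(NA_real_, c(2, n_fam, po$n_node))
    U[, , po$root] <- pi
    Eg <- matrix(0, n_edge, n_fam)
    El <- matrix(0, n_edge, n_fam)
    Pg <- matrix(0, n_edge, n_fam)
    Pl <- matrix(0, n_edge, n_fam)
    for (e in rev(seq_len(n_edge))) {
      par <- po$edge[e, 1]; chd <- po$edge[e, 2]
      sib <- setdiff(which(po$edge[, 1] == par), e)
      FF <- slice2(U, par)
      for (s in sib) FF <- FF * pp$M[[s]]
      ## joint endpoint posterior J[a,b] over families
      P <- pp$P[[e]]
      D <- slice2(pp$D, chd)
      J00 <- FF[1, ] * P[1, 1] * D[1, ]
      J01 <- FF[1, ] * P[1, 2] * D[2, ]
      J10 <- FF[2, ] * P[2, 1] * D[1, ]
      J11 <- FF[2, ] * P[2, 2] * D[2, ]
      tot <- J00 + J01 + J10 + J11
      tot[tot == 0] <- 1
      et <- expected_transitions(g, l, po$length[e])
      Eg[e, ] <- (J00 * et$gains[1, 1] + J01 * et$gains[1, 2] +
                  J10 * et$gains[2, 1] + J11 * et$gains[2, 2]) / tot
      El[e, ] <- (J00 * et$losses[1, 1] + J01 * et$losses[1, 2] +
                  J10 * et$losses[2, 1] + J11 * et$losses[2, 2]) / tot
      if (po$length[e] > 0) {
        Pmat <- pp$P[[e]]
        png <- prob_no_gain(g, l, po$length[e]) / Pmat
        pnl <- prob_no_loss(g, l, po$length[e]) / Pmat
        Pg[e, ] <- (J00 * (1 - png[1, 1]) + J01 * (1 - png[1, 2]) +
                    J10 * (1 - png[2, 1]) + J11 * (1 - png[2, 2])) / tot
        Pl[e, ] <- (J00 * (1 - pnl[1, 1]) + J01 * (1 - pnl[1, 2]) +
                    J10 * (1 - pnl[2, 1]) + J11 * (1 - pnl[2, 2])) / tot
      }
      ## outside partials of the child, rescaled per family for stability
      Uc <- rbind(FF[1, ] * P[1, 1] + FF[2, ] * P[2, 1],
                  FF[1, ] * P[1, 2] + FF[2, ] * P[2, 2])
      sc <- pmax(Uc[1, ], Uc[2, ]); sc[sc == 0] <- 1
      U[, , chd] <- Uc / rep(sc, each = 2)
    }
    cat_res[[k]] <- list(Eg = Eg, El = El, Pg = Pg, Pl = Pl)
  }
  ## posterior category weights per family
  mx <- apply(lls, 1, max)
  w <- exp(lls - mx)
  w <- w / rowSums(w)
  acc <- function(fld) {
    out <- matrix(0, n_edge, n_fam)
    for (k in seq_len(K))
      out <- out + sweep(cat_res[[k]][[fld]], 2, w[, k], `*`)
    dimnames(out) <- list(po$labels[po$edge[, 2]], colnames(X))
    out
  }
  structure(list(branch = po$labels[po$edge[, 2]],
                 branch_length = po$length,
                 is_terminal = po$edge[, 2] <= po$n_tip,
                 expected_gains = acc("Eg"), expected_losses = acc("El"),
                 p_gain = acc("Pg"), p_loss = acc("Pl")),
            class = "branch_events")
}

#' Aggregate branch events over a family set
#'
#' Expected counts are additive over families; the probability of at least
#' one event on a branch combines per-family posteriors as
#' `1 - prod(1 - p)`.
#'
#' @param be a `"branch_events"` object
#' @param families character vector of family ids (default: all)
#' @return data.frame: branch, branch_length, is_terminal, expected_gains,
#'   expected_losses, p_ge1_gain, p_ge1_loss
#' @export
aggregate_branch_events <- function(be, families = NULL) {
  idx <- if (is.null(families)) seq_len(ncol(be$expected_gains))
         else match(families, colnames(be$expected_gains))
  if (anyNA(idx)) stop("unknown family id", call. = FALSE)
  data.frame(
    branch = be$branch,
    branch_length = be$branch_length,
    is_terminal = be$is_terminal,
    expected_gains = rowSums(be$expected_gains[, idx, drop = FALSE]),
    expected_losses = rowSums(be$expected_losses[, idx, drop = FALSE]),
    p_ge1_gain = 1 - apply(1 - be$p_gain[, idx, drop = FALSE], 1, prod),
    p_ge1_loss = 1 - apply(1 - be$p_loss[, idx, drop = FALSE], 1, prod))
}

#' Call binary per-branch events from posterior probabilities
#'
#' An event is called on a branch when the posterior probability of at
#' least one event (over the family set) exceeds `threshold`.
#'
#' @inheritParams aggregate_branch_events
#' @param threshold posterior probability cutoff (default 0.5)
#' @return data.frame: branch, gain, loss (0/1), branch_length, is_terminal
#' @export
call_branch_events <- function(be, families = NULL, threshold = 0.5) {
  agg <- aggregate_branch_events(be, families)
  data.frame(branch = agg$branch,
             gain = as.integer(agg$p_ge1_gain > threshold),
             loss = as.integer(agg$p_ge1_loss > threshold),
             branch_length = agg$branch_length,
             is_terminal = agg$is_terminal)
}
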