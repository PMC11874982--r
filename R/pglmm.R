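## Per-species Poisson phylogenetic GLMM: Y_i ~ Poisson(mu_i),
## log mu_i = beta0 + sum_j beta_j X_ij + eps_i, eps ~ N(0, sigma2_phy * C),
## with C the Brownian-motion covariance of the strain tree. Estimation by
## Laplace approximation with an inner Newton solve for the random effects;
## the identity-covariance counterpart and conditional AIC support the
## model comparison reported downstream.

#' Brownian-motion phylogenetic covariance
#'
#' `C[i, j]` is the shared root-to-MRCA path length of leaves i and j;
#' `C[i, i]` the root-to-leaf distance. Computed with [ape::vcv()].
#'
#' @param tree rooted strain tree with non-negative branch lengths
#' @param rescale divide by the mean diagonal (unit mean variance); the
#'   fixed-effect estimates are invariant, `sigma2_phy` rescales
#' @return symmetric PSD matrix ordered like `tree$tip.label`
#' @export
brownian_covariance <- function(tree, rescale = FALSE) {
  tree <- validate_strain_tree(tree)
  C <- ape::vcv(tree)
  C <- C[tree$tip.label, tree$tip.label]
  if (rescale) C <- C / mean(diag(C))
  C
}

## Cholesky with a tiny ridge fallback for semi-definite C (zero-length
## branches can make leaves exactly collinear).
safe_chol <- function(C) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(C + diag(1e-8 * mean(diag(C)), nrow(C)))
  ch
}

#' Fit a Poisson phylogenetic GLMM by Laplace approximation
#'
#' Maximizes the Laplace-approximate marginal likelihood over the fixed
#' effects and `sigma2_phy >= 0` (profiled on the log scale with a boundary
#' check at zero). The inner Newton solve for the random effects iterates
#' to 1e-8. Wald p-values: `2 * pnorm(-|beta / se|)`.
#'
#' @param y non-negative integer response (one per genome, ordered like `C`)
#' @param X predictor matrix (genomes x predictors) or `NULL` for an
#'   intercept-only model; an intercept column is added internally
#' @param C phylogenetic covariance from [brownian_covariance()]
#' @param rescale rescale `C` to unit mean diagonal before fitting
#'   (numerical conditioning; on by default)
#' @param max_restarts bounded restarts before flagging non-convergence
#' @return object of class `"pglmm_fit"`: `coefficients`, `se`, `p`,
#'   `sigma2_phy`, `loglik` (Laplace marginal), `cond_loglik`, `converged`,
#'   `n_genomes`, plus internals used by [caic()]
#' @export
fit_poisson_pglmm <- function(y, X = NULL, C, rescale = TRUE,
                              max_restarts = 3L) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(y < 0) || any(y != floor(y))) stop("y must be counts", call. = FALSE)
  Xd <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("y and X must align", call. = FALSE)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    Xd <- cbind(Xd, X)
  }
  if (nrow(C) != n) stop("y and C must align", call. = FALSE)
  C <- unname(as.matrix(C))
  if (rescale) C <- C / mean(diag(C))
  p <- ncol(Xd)
  chC <- safe_chol(C)
  Cinv <- chol2inv(chC)
  logdetC <- 2 * sum(log(diag(chC)))
  lfac <- sum(lgamma(y + 1))

  glm0 <- glm.fit(Xd, y, family = poisson())
  beta0 <- glm0$coefficients
  ll_glm <- sum(y * log(glm0$fitted.values) - glm0$fitted.values) - lfac

  b_cache <- rep(0, n)
  neg_laplace <- function(par) {
    beta <- par[seq_len(p)]
    sigma2 <- exp(par[p + 1])
    eta_fix <- drop(Xd %*% beta)
    Sinv <- Cinv / sigma2
    b <- b_cache
    ok <- FALSE
    for (it in 1:100) {
      mu <- exp(eta_fix + b)
      mu <- pmin(mu, 1e12)
      grad <- (y - mu) - drop(Sinv %*% b)
      H <- Sinv
      diag(H) <- diag(H) + mu
      delta <- tryCatch(solve(H, grad), error = function(e) NULL)
      if (is.null(delta)) return(1e10)
      ## step-halving on the penalized objective
      f_old <- sum(y * (eta_fix + b) - mu) - 0.5 * drop(crossprod(b, Sinv %*% b))
      step <- 1
      repeat {
        b_new <- b + step * delta
        mu_new <- pmin(exp(eta_fix + b_new), 1e12)
        f_new <- sum(y * (eta_fix + b_new) - mu_new) -
          0.5 * drop(crossprod(b_new, Sinv %*% b_new))
        if (is.finite(f_new) && f_new >= f_old - 1e-12) break
        step <- step / 2
        if (step < 1e-8) break
      }
      b <- b + step * delta
      if (max(abs(step * delta)) < 1e-8) { ok <- TRUE; break }
    }
    b_cache <<- b
    mu <- pmin(exp(eta_fix + b), 1e12)
    H <- Cinv / sigma2
    diag(H) <- diag(H) + mu
    chH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(chH)) return(1e10)
    ll <- sum(y * (eta_fix + b) - mu) - lfac -
      0.5 * drop(crossprod(b, (Cinv %*% b))) / sigma2 -
      0.5 * (n * log(sigma2) + logdetC) -
      sum(log(diag(chH)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  for (s2_start in c(0.1, 1, 0.01)[seq_len(max_restarts)]) {
    b_cache <- rep(0, n)
    opt <- tryCatch(
      optim(c(beta0, log(s2_start)), neg_laplace, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  converged <- !is.null(best) && best$convergence == 0 &&
    best$value < 1e9

  sigma2 <- if (is.null(best)) 0 else unname(exp(best$par[p + 1]))
  boundary <- is.null(best) || -best$value <= ll_glm + 1e-6 || sigma2 < 1e-5
  if (boundary) {
    beta <- beta0
    sigma2 <- 0
    b <- rep(0, n)
    mu <- glm0$fitted.values
    loglik <- ll_glm
    XtWX <- crossprod(Xd * mu, Xd)
    covb <- chol2inv(chol(XtWX))
    converged <- glm0$converged %||% TRUE
  } else {
    beta <- best$par[seq_len(p)]
    neg_laplace(best$par)          # refresh b_cache at the optimum
    b <- b_cache
    mu <- pmin(exp(drop(Xd %*% beta) + b), 1e12)
    loglik <- -best$value
    ## GLS-style covariance on the working scale: V = W^-1 + sigma2 C
    V <- diag(1 / mu) + sigma2 * C
    Vinv_X <- solve(V, Xd)
    covb <- chol2inv(chol(crossprod(Xd, Vinv_X)))
  }
  se <- sqrt(diag(covb))
  z <- beta / se
  fit <- list(coefficients = setNames(beta, colnames(Xd)),
              se = setNames(se, colnames(Xd)),
              p = setNames(2 * pnorm(-abs(z)), colnames(Xd)),
              sigma2_phy = sigma2,
              loglik = loglik,
              cond_loglik = sum(y * log(pmax(mu, 1e-300)) - mu) - lfac,
              converged = isTRUE(converged),
              n_genomes = n,
              random_effects = b, fitted = mu,
              Xd = Xd, Cinv = Cinv, n_fixed = p)
  class(fit) <- "pglmm_fit"
  fit
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat("Poisson phylogenetic GLMM (Laplace), n =", x$n_genomes, "\n")
  tab <- data.frame(beta = x$coefficients, se = x$se, p = x$p)
  print(format(tab, digits = 4))
  cat("sigma2_phy =", format(x$sigma2_phy, digits = 4),
      " logLik =", format(x$loglik, digits = 8),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  invisible(x)
}

#' Identity-covariance (non-phylogenetic) counterpart
#'
#' Same model and code path as [fit_poisson_pglmm()] with `C` replaced by
#' the identity matrix: an observation-level random effect capturing
#' non-phylogenetic overdispersion.
#'
#' @inheritParams fit_poisson_pglmm
#' @return a `"pglmm_fit"`
#' @export
fit_poisson_glmm_identity <- function(y, X = NULL) {
  fit_poisson_pglmm(y, X, diag(length(y)), rescale = FALSE)
}

#' Conditional Akaike information criterion
#'
#' `cAIC = -2 * conditional log-likelihood + 2 * rho`, where `rho` is the
#' effective number of degrees of freedom: the trace of the hat matrix
#' mapping the working response onto the fitted linear predictor in the
#' augmented (fixed + random) weighted least-squares problem
#' (Vaida-Blanchard style). At `sigma2_phy = 0`, `rho` equals the number of
#' fixed effects and cAIC reduces to the AIC of the Poisson GLM.
#' Differences below 2 are conventionally read as model equivalence.
#'
#' @param fit a converged `"pglmm_fit"`
#' @return cAIC (scalar); the effective dof is attached as `attr(, "rho")`
#' @export
caic <- function(fit) {
  if (!inherits(fit, "pglmm_fit")) stop("need a pglmm_fit", call. = FALSE)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  p <- fit$n_fixed
  if (fit$sigma2_phy == 0) {
    rho <- p
  } else {
    W <- fit$fitted
    Tmat <- cbind(fit$Xd, diag(fit$n_genomes))
    TWT <- crossprod(Tmat * W, Tmat)
    A <- TWT
    idx <- p + seq_len(fit$n_genomes)
    A[idx, idx] <- A[idx, idx] + fit$Cinv / fit$sigma2_phy
    H <- tryCatch(solve(A, TWT), error = function(e) {
      ## near-boundary sigma2 makes A badly scaled; a ridge on the order of
      ## machine precision times the diagonal restores the solve
      solve(A + diag(1e-10 * mean(diag(A)), nrow(A)), TWT)
    })
    rho <- sum(diag(H))
  }
  out <- -2 * fit$cond_loglik + 2 * rho
  attr(out, "rho") <- rho
  out
}

#' Fit the per-species battery of defense-system models
#'
#' For each response vector: in `"single"` mode one PGLMM per defense
#' system (a single binary predictor, optionally plus the count of other
#' defense systems); in `"joint"` mode one PGLMM with all estimable systems
#' as predictors. Systems whose within-species prevalence is 0 or 1 are
#' skipped as inestimable. Each model is paired with its
#' identity-covariance counterpart and both cAICs are reported.
#'
#' @param responses named list (or genomes x responses matrix) of count
#'   vectors, defense-system genes already excluded
#' @param traits genomes x systems 0/1 matrix
#' @param C phylogenetic covariance (aligned with the responses)
#' @param mode `"single"` or `"joint"`
#' @param other_defense_covariate add the total number of other defense
#'   systems as an extra predictor (single mode)
#' @return list with `table` (one row per response x system: beta, se, p,
#'   sigma2_phy, caic_pglmm, caic_identity, delta_caic, n_genomes,
#'   converged), `fits`, and `skipped`
#' @export
fit_species_battery <- function(responses, traits, C,
                                mode = c("single", "joint"),
                                other_defense_covariate = FALSE) {
  mode <- match.arg(mode)
  if (is.matrix(responses))
    responses <- setNames(lapply(seq_len(ncol(responses)),
                                 function(j) responses[, j]),
                          colnames(responses))
  prev <- colMeans(traits)
  estimable <- names(prev)[prev > 0 & prev < 1]
  inestimable <- setdiff(colnames(traits), estimable)
  skipped <- data.frame(system = inestimable,
                        reason = rep("constant predictor",
                                     length(inestimable)))
  rows <- list(); fits <- list()
  for (resp_name in names(responses)) {
    y <- responses[[resp_name]]
    if (mode == "joint") {
      X <- traits[, estimable, drop = FALSE]
      fit <- fit_poisson_pglmm(y, X, C)
      fit_id <- fit_poisson_glmm_identity(y, X)
      ca <- if (fit$converged) as.numeric(caic(fit)) else NA_real_
      ca_id <- if (fit_id$converged) as.numeric(caic(fit_id)) else NA_real_
      for (sys in estimable) {
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp_name, system = sys,
          beta = fit$coefficients[sys], se = fit$se[sys], p = fit$p[sys],
          sigma2_phy = fit$sigma2_phy, caic_pglmm = ca,
          caic_identity = ca_id, delta_caic = ca - ca_id,
          n_genomes = fit$n_genomes, converged = fit$converged)
      }
      fits[[resp_name]] <- fit
    } else {
      for (sys in estimable) {
        X <- traits[, sys, drop = FALSE]
        if (other_defense_covariate) {
          others <- rowSums(traits[, setdiff(colnames(traits), sys),
                                   drop = FALSE])
          X <- cbind(X, other_defense = others)
        }
        fit <- fit_poisson_pglmm(y, X, C)
        fit_id <- fit_poisson_glmm_identity(y, X)
        ca <- if (fit$converged) as.numeric(caic(fit)) else NA_real_
        ca_id <- if (fit_id$converged) as.numeric(caic(fit_id)) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp_name, system = sys,
          beta = fit$coefficients[sys], se = fit$se[sys], p = fit$p[sys],
          sigma2_phy = fit$sigma2_phy, caic_pglmm = ca,
          caic_identity = ca_id, delta_caic = ca - ca_id,
          n_genomes = fit$n_genomes, converged = fit$converged)
        fits[[paste(resp_name, sys, sep = ".")]] <- fit
      }
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(response = character(0), system = character(0))
  rownames(table) <- NULL
  if (nrow(skipped))
    log_stage("pglmm", skipped = paste(skipped$system, collapse = ","))
  list(table = table, fits = fits, skipped = skipped)
}

#' Build response vectors from a presence matrix
#'
#' Per-genome gene counts with defense-system gene families excluded:
#' `total`, one response per MGE marker class, and one per COG category.
#'
#' @param mat presence matrix (genomes x families)
#' @param annotation family annotation ([read_annotation()] layout)
#' @param cog_categories include per-COG-category responses
#' @return named list of count vectors
#' @export
response_vectors <- function(mat, annotation, cog_categories = FALSE) {
  ann <- annotation[match(colnames(mat), annotation$family_id), ]
  keep <- ann$defense_system == "none"
  out <- list(total = rowSums(mat[, keep, drop = FALSE]))
  for (cl in c("prophage", "plasmid", "transposon")) {
    sel <- keep & ann$mge_class == cl
    if (any(sel)) out[[cl]] <- rowSums(mat[, sel, drop = FALSE])
  }
  if (cog_categories) {
    for (letter in sort(unique(ann$cog_category[keep]))) {
      sel <- keep & ann$cog_category == letter
      if (any(sel)) out[[paste0("COG_", letter)]] <-
          rowSums(mat[, sel, drop = FALSE])
    }
  }
  out
}
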