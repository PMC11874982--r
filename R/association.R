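## Effect sizes and the two species-level classification criteria:
## statistical significance (P < 0.05) and magnitude above the smallest
## significant effect size (|ES| > SSES) within a response x system group.

#' Effect size of a model coefficient
#'
#' Relative difference in expected counts under the log link:
#' `ES = exp(beta) - 1` (e.g. +0.25 means 25% more genes when the defense
#' system is present).
#'
#' @param beta coefficient, or a `"pglmm_fit"` together with `coefficient`
#' @param coefficient coefficient name when `beta` is a fit
#' @return relative difference (scalar)
#' @export
effect_size <- function(beta, coefficient = NULL) {
  if (inherits(beta, "pglmm_fit")) {
    if (!beta$converged) stop("fit did not converge", call. = FALSE)
    beta <- beta$coefficients[[coefficient]]
  }
  exp(beta) - 1
}

#' Raw relative difference in group means
#'
#' The alternative reading of a "relative difference":
#' `(mean(y | x = 1) - mean(y | x = 0)) / mean(y | x = 0)`.
#'
#' @param y counts
#' @param x binary predictor
#' @return relative difference (scalar)
#' @export
relative_difference <- function(y, x) {
  m0 <- mean(y[x == 0]); m1 <- mean(y[x == 1])
  (m1 - m0) / m0
}

#' Smallest significant effect size within a group
#'
#' The minimal `|ES|` among results with `p < alpha`, computed separately
#' for each response variable and defense system across species.
#'
#' @param es effect sizes across species (one group)
#' @param p matching p-values
#' @param alpha significance level
#' @return SSES, or `NA` when no result in the group is significant
#' @export
compute_sses <- function(es, p, alpha = 0.05) {
  sig <- !is.na(p) & p < alpha & !is.na(es)
  if (!any(sig)) return(NA_real_)
  min(abs(es[sig]))
}

#' Classify associations under both criteria
#'
#' `class_p` is the sign of the effect when `p < alpha`, otherwise null;
#' `class_sses` is the sign when `|ES| > SSES` (strict), otherwise null.
#'
#' @param es effect sizes
#' @param p p-values
#' @param sses threshold from [compute_sses()] for the same group
#' @param alpha significance level
#' @return data.frame with `effect_size`, `p`, `class_p`, `class_sses`
#' @export
classify <- function(es, p, sses, alpha = 0.05) {
  sgn <- ifelse(es > 0, "positive", ifelse(es < 0, "negative", "null"))
  class_p <- ifelse(!is.na(p) & p < alpha, sgn, "null")
  class_sses <- if (is.na(sses)) rep("null", length(es))
                else ifelse(abs(es) > sses, sgn, "null")
  data.frame(effect_size = es, p = p, class_p = class_p,
             class_sses = class_sses)
}

#' Classify a multi-species battery table
#'
#' Groups a battery table by response and system, computes the group-wise
#' SSES, applies both classifications, and tallies the counts of positive
#' and negative species per criterion.
#'
#' @param table data.frame with columns `species`, `response`, `system`,
#'   `beta`, `p` (e.g. row-bound outputs of [fit_species_battery()] with a
#'   `species` column added); non-converged rows should be removed first
#' @param alpha significance level
#' @return list with `results` (the table plus `effect_size`, `sses`,
#'   `class_p`, `class_sses`) and `summary` (per response x system counts
#'   and positive:negative ratios under each criterion)
#' @export
associate_battery <- function(table, alpha = 0.05) {
  stopifnot(all(c("response", "system", "beta", "p") %in% colnames(table)))
  table$effect_size <- effect_size(table$beta)
  key <- interaction(table$response, table$system, drop = TRUE)
  table$sses <- NA_real_
  table$class_p <- table$class_sses <- NA_character_
  for (k in levels(key)) {
    i <- which(key == k)
    sses <- compute_sses(table$effect_size[i], table$p[i], alpha)
    cl <- classify(table$effect_size[i], table$p[i], sses, alpha)
    table$sses[i] <- sses
    table$class_p[i] <- cl$class_p
    table$class_sses[i] <- cl$class_sses
  }
  agg <- do.call(rbind, lapply(levels(key), function(k) {
    i <- which(key == k)
    data.frame(response = table$response[i][1], system = table$system[i][1],
               n_species = length(i),
               pos_p = sum(table$class_p[i] == "positive"),
               neg_p = sum(table$class_p[i] == "negative"),
               pos_sses = sum(table$class_sses[i] == "positive"),
               neg_sses = sum(table$class_sses[i] == "negative"))
  }))
  agg$ratio_p <- ifelse(agg$neg_p > 0, agg$pos_p / agg$neg_p, NA_real_)
  agg$ratio_sses <- ifelse(agg$neg_sses > 0, agg$pos_sses / agg$neg_sses,
                           NA_real_)
  list(results = table, summary = agg)
}
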