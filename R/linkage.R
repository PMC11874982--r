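## Branch-level co-occurrence of defense-system and MGE gains/losses:
## co-event fractions with exact binomial CIs, the length-weighted
## independence expectation, binomial deviation tests, conditional
## probabilities, risk ratios and Fisher's exact test, with a
## terminal/internal branch split.

check_event_table <- function(tbl) {
  needed <- c("def_gain", "def_loss", "mge_gain", "mge_loss",
              "branch_length", "is_terminal")
  missing <- setdiff(needed, colnames(tbl))
  if (length(missing))
    stop("branch event table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tbl
}

event_cols <- function(event = c("gain", "loss")) {
  event <- match.arg(event)
  c(def = paste0("def_", event), mge = paste0("mge_", event))
}

#' 2x2 contingency table of branch-level events
#'
#' Exposure is an MGE event on the branch, outcome a defense event:
#' `a` = both, `b` = MGE only, `c` = defense only, `d` = neither.
#'
#' @param tbl branch event table (see
#'   [branch_event_table_from_history()] / [call_branch_events()])
#' @param event `"gain"` or `"loss"`
#' @return named integer vector `c(a, b, c, d)`
#' @export
as_contingency <- function(tbl, event = c("gain", "loss")) {
  tbl <- check_event_table(tbl)
  cc <- event_cols(event)
  def <- tbl[[cc["def"]]] == 1
  mge <- tbl[[cc["mge"]]] == 1
  c(a = sum(def & mge), b = sum(!def & mge),
    c = sum(def & !mge), d = sum(!def & !mge))
}

#' Fraction of defense events that co-occur with an MGE event
#'
#' Percentage of defense-event branches that also carry the matching MGE
#' event, with the exact Clopper-Pearson 95% binomial CI.
#'
#' @inheritParams as_contingency
#' @return list: `percent`, `ci` (length 2, percent scale), `k`, `n`
#' @export
cogain_fraction <- function(tbl, event = c("gain", "loss")) {
  tbl <- check_event_table(tbl)
  cc <- event_cols(event)
  def <- tbl[[cc["def"]]] == 1
  n <- sum(def)
  if (n == 0) stop("no defense ", match.arg(event), " events", call. = FALSE)
  k <- sum(def & tbl[[cc["mge"]]] == 1)
  ci <- binom.test(k, n)$conf.int
  list(percent = 100 * k / n, ci = 100 * as.numeric(ci), k = k, n = n)
}

#' Expected co-occurrence under independent placement
#'
#' The null expectation for [cogain_fraction()] when defense events are
#' placed independently of MGE events: with `weight = "length"` (default)
#' defense events land on branches proportionally to branch length, so the
#' expectation is the length share of MGE-event branches; with
#' `weight = "count"` it is their branch-count share.
#'
#' @inheritParams as_contingency
#' @param weight `"length"` or `"count"`
#' @return percentage (scalar)
#' @export
independence_expectation <- function(tbl, event = c("gain", "loss"),
                                     weight = c("length", "count")) {
  tbl <- check_event_table(tbl)
  weight <- match.arg(weight)
  cc <- event_cols(event)
  mge <- tbl[[cc["mge"]]] == 1
  if (weight == "length")
    100 * sum(tbl$branch_length[mge]) / sum(tbl$branch_length)
  else 100 * mean(mge)
}

#' Two-sided exact binomial deviation test
#'
#' @param k observed successes
#' @param n trials
#' @param p0 null success probability, strictly inside (0, 1)
#' @return p-value
#' @export
binomial_deviation_test <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  if (k < 0 || k > n) stop("k must be in [0, n]", call. = FALSE)
  binom.test(k, n, p0)$p.value
}

#' Conditional probabilities of a defense event
#'
#' `P(defense event | MGE event)` and `P(defense event | no MGE event)` per
#' branch, each with its exact 95% binomial CI.
#'
#' @inheritParams as_contingency
#' @return list of two lists (`given_mge`, `given_no_mge`) with
#'   `probability` and `ci`
#' @export
conditional_probabilities <- function(tbl, event = c("gain", "loss")) {
  ct <- as_contingency(tbl, event)
  one <- function(k, n) {
    if (n == 0) return(list(probability = NA_real_, ci = c(NA_real_, NA_real_)))
    list(probability = unname(k / n),
         ci = as.numeric(binom.test(k, n)$conf.int))
  }
  list(given_mge = one(ct["a"], ct["a"] + ct["b"]),
       given_no_mge = one(ct["c"], ct["c"] + ct["d"]))
}

#' Risk ratio of a branch-level 2x2 table
#'
#' `RR = [a/(a+b)] / [c/(c+d)]` with the standard log-method 95% CI
#' `exp(log RR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. A zero
#' unexposed numerator (`c = 0`) yields an infinite RR, flagged without CI.
#'
#' @param ct contingency vector from [as_contingency()], or a branch event
#'   table (then `event` selects the comparison)
#' @inheritParams as_contingency
#' @return list: `rr`, `ci`, `finite`
#' @export
risk_ratio <- function(ct, event = c("gain", "loss")) {
  if (is.data.frame(ct)) ct <- as_contingency(ct, event)
  a <- ct[["a"]]; b <- ct[["b"]]; cc <- ct[["c"]]; d <- ct[["d"]]
  if (a + b == 0 || cc + d == 0)
    stop("empty exposure margin", call. = FALSE)
  p1 <- a / (a + b); p0 <- cc / (cc + d)
  if (cc == 0)
    return(list(rr = Inf, ci = c(NA_real_, NA_real_), finite = FALSE))
  rr <- p1 / p0
  if (a == 0)
    return(list(rr = 0, ci = c(NA_real_, NA_real_), finite = FALSE))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  list(rr = rr, ci = exp(log(rr) + c(-1.96, 1.96) * se), finite = TRUE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration (tables with probability
#' at most that of the observed one).
#'
#' @inheritParams risk_ratio
#' @return p-value
#' @export
fisher_exact <- function(ct, event = c("gain", "loss")) {
  if (is.data.frame(ct)) ct <- as_contingency(ct, event)
  m <- matrix(c(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]]), 2, 2,
              byrow = TRUE)
  fisher.test(m)$p.value
}

#' Split a branch event table by branch type
#'
#' @param tbl branch event table
#' @return list with `terminal` and `internal` subsets
#' @export
split_by_branch_type <- function(tbl) {
  tbl <- check_event_table(tbl)
  list(terminal = tbl[tbl$is_terminal, , drop = FALSE],
       internal = tbl[!tbl$is_terminal, , drop = FALSE])
}

#' Full linkage summary
#'
#' All linkage statistics for gains and losses, on all branches and
#' separately on terminal and internal branches. Subsets without defense
#' events are skipped (logged).
#'
#' @param tbl branch event table
#' @return data.frame, one row per event type x branch subset
#' @export
linkage_summary <- function(tbl) {
  tbl <- check_event_table(tbl)
  subsets <- c(list(all = tbl), split_by_branch_type(tbl))
  rows <- list()
  for (sub_name in names(subsets)) {
    sub <- subsets[[sub_name]]
    for (event in c("gain", "loss")) {
      cc <- event_cols(event)
      if (nrow(sub) == 0 || sum(sub[[cc["def"]]]) == 0) {
        log_stage("linkage", subset = sub_name, event = event,
                  skipped = "no defense events")
        next
      }
      cf <- cogain_fraction(sub, event)
      expct <- independence_expectation(sub, event)
      ct <- as_contingency(sub, event)
      rr <- tryCatch(risk_ratio(ct), error = function(e)
        list(rr = NA_real_, ci = c(NA_real_, NA_real_), finite = FALSE))
      cp <- conditional_probabilities(sub, event)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = sub_name, event = event,
        n_branches = nrow(sub), n_def_events = cf$n,
        cofraction_pct = cf$percent,
        cofraction_lo = cf$ci[1], cofraction_hi = cf$ci[2],
        expected_pct = expct,
        binom_p = binomial_deviation_test(cf$k, cf$n,
                                          min(max(expct / 100, 1e-12),
                                              1 - 1e-12)),
        p_def_given_mge = cp$given_mge$probability,
        p_def_given_no_mge = cp$given_no_mge$probability,
        rr = rr$rr, rr_lo = rr$ci[1], rr_hi = rr$ci[2],
        fisher_p = fisher_exact(ct))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
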