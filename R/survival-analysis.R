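# Lifespan assay statistics: Kaplan-Meier curves, the log-rank
# (Mantel-Cox) test, and per-group lifespan summaries.
#
# Survival records are data.frames with columns: animal_id, group, day
# (days from adult day 1), event ("death" or "censored"). Censored
# animals (crawled off, ruptured, bagged, burrowed) stay in the risk set
# up to their last observed day; deaths and censorings tied on the same
# day are handled with deaths first, the standard convention.

check_survival_records <- function(records) {
  stopifnot(all(c("animal_id", "group", "day", "event") %in% names(records)))
  if (any(records$day < 0)) stop("negative day")
  if (!all(records$event %in% c("death", "censored")))
    stop("event must be 'death' or 'censored'")
  if (anyDuplicated(records$animal_id)) stop("duplicate animal_id")
  invisible(records)
}

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate via [survival::survfit()]; the curve is
#' anchored at survival 1 on day 0.
#'
#' @param records Survival records data.frame.
#' @param group Group label.
#' @return List of class `km_curve`: `group`, `times`, `survival`,
#'   `at_risk`, `events`, `censored`.
#' @export
km_estimate <- function(records, group) {
  check_survival_records(records)
  d <- records[records$group == group, , drop = FALSE]
  if (!nrow(d)) stop("no records for group '", group, "'")
  sf <- survival::survfit(
    survival::Surv(d$day, d$event == "death") ~ 1, conf.type = "none")
  structure(
    list(group = group,
         times = c(0, sf$time),
         survival = c(1, sf$surv),
         at_risk = c(nrow(d), sf$n.risk),
         events = c(0, sf$n.event),
         censored = c(0, sf$n.censor)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> group %s: %d animals, %d deaths\n",
              x$group, x$at_risk[1L], sum(x$events)))
  print(data.frame(time = x$times, at_risk = x$at_risk, events = x$events,
                   survival = round(x$survival, 4)))
  invisible(x)
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' At each distinct death time, expected deaths per group come from the
#' hypergeometric model; the statistic is (O - E)^2 / V summed over death
#' times, referred to a chi-squared distribution with 1 df (two-sided).
#' Computed via [survival::survdiff()] (rho = 0).
#'
#' @param records Survival records data.frame.
#' @param groupA,groupB Group labels.
#' @return List of class `logrank_result`: `chi2`, `df`, `p`, `observed`,
#'   `expected` (named per group), `n`. With zero deaths overall, `chi2`
#'   and `p` are `NA` and `note` explains why.
#' @export
logrank_test <- function(records, groupA, groupB) {
  check_survival_records(records)
  d <- records[records$group %in% c(groupA, groupB), , drop = FALSE]
  if (!any(d$group == groupA) || !any(d$group == groupB))
    stop("both groups must be non-empty")
  if (!any(d$event == "death")) {
    return(structure(list(chi2 = NA_real_, df = 1L, p = NA_real_,
                          observed = NULL, expected = NULL,
                          n = table(d$group), note = "no deaths"),
                     class = "logrank_result"))
  }
  grp <- factor(d$group, levels = c(groupA, groupB))
  sd_ <- survival::survdiff(
    survival::Surv(d$day, d$event == "death") ~ grp, rho = 0)
  chi2 <- unname(sd_$chisq)
  structure(
    list(chi2 = chi2, df = 1L,
         p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
         observed = stats::setNames(sd_$obs, c(groupA, groupB)),
         expected = stats::setNames(sd_$exp, c(groupA, groupB)),
         n = stats::setNames(as.vector(sd_$n), c(groupA, groupB)),
         note = NA_character_),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result> ")
  if (!is.na(x$note)) { cat(x$note, "\n"); return(invisible(x)) }
  cat(sprintf("chi2 = %.4g (df %d), p = %.4g\n", x$chi2, x$df, x$p))
  print(data.frame(n = as.vector(x$n), observed = x$observed,
                   expected = x$expected))
  invisible(x)
}

#' Per-group lifespan summary
#'
#' Mean lifespan over death events only (censored animals counted
#' separately), with s.e.m. and optional percent change versus a
#' reference group.
#'
#' @param records Survival records data.frame.
#' @param group Group label.
#' @param reference Optional reference group for percent change.
#' @return List: `group`, `mean_lifespan`, `sem`, `n_deaths`,
#'   `n_censored`, `pct_change` (`NA` without a reference).
#' @export
summarize_lifespan <- function(records, group, reference = NULL) {
  check_survival_records(records)
  d <- records[records$group == group, , drop = FALSE]
  if (!nrow(d)) stop("no records for group '", group, "'")
  deaths <- d$day[d$event == "death"]
  mean_ls <- if (length(deaths)) mean(deaths) else NA_real_
  sem <- if (length(deaths) > 1L) stats::sd(deaths) / sqrt(length(deaths)) else NA_real_
  pct <- NA_real_
  if (!is.null(reference)) {
    ref_deaths <- records$day[records$group == reference &
                              records$event == "death"]
    if (length(ref_deaths) && length(deaths))
      pct <- 100 * (mean_ls - mean(ref_deaths)) / mean(ref_deaths)
  }
  list(group = group, mean_lifespan = mean_ls, sem = sem,
       n_deaths = length(deaths), n_censored = sum(d$event == "censored"),
       pct_change = pct)
}
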