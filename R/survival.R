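#' Median-split stratification of a score
#'
#' Samples at or below the median score go to the `"low"` group, samples
#' strictly above to `"high"`. With all scores distinct and an even sample
#' count the split is exactly even; ties at the median fall to `"low"`.
#'
#' @param scores Named numeric vector (names = sample ids) with >= 4
#'   samples.
#' @return `data.frame` of class `stratification` with columns
#'   `sample_id`, `score`, `group` (factor, levels `low`, `high`), and a
#'   `split_value` attribute holding the median.
#' @export
median_stratify <- function(scores) {
  if (length(scores) < 4L) stop("need >= 4 samples to stratify")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("'scores' must be named by sample id")
  med <- stats::median(scores)
  if (all(scores == scores[[1L]]))
    stop("degenerate split: all scores identical")
  grp <- factor(ifelse(scores > med, "high", "low"),
                levels = c("low", "high"))
  out <- data.frame(sample_id = names(scores), score = as.numeric(scores),
                    group = grp, stringsAsFactors = FALSE)
  attr(out, "split_value") <- med
  class(out) <- c("stratification", "data.frame")
  out
}

# Join survival records onto a stratification; every stratified sample must
# have a record.
join_survival <- function(records, strat) {
  records <- survival_records(records)
  stopifnot(inherits(strat, "stratification"))
  missing <- setdiff(strat$sample_id, records$sample_id)
  if (length(missing))
    stop("no survival record for sample(s): ",
         paste(missing, collapse = ", "))
  idx <- match(strat$sample_id, records$sample_id)
  data.frame(sample_id = strat$sample_id, time = records$time[idx],
             event = records$event[idx], group = strat$group,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves per stratification group
#'
#' Product-limit estimate of the survival function in each group; censored
#' times reduce the risk set without introducing steps.
#'
#' @param records Survival `data.frame` (`sample_id`, `time`, `event`).
#' @param strat A [median_stratify] result covering samples present in
#'   `records`.
#' @return `data.frame` with one row per distinct observed time per group:
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(records, strat) {
  d <- join_survival(records, strat)
  if (any(table(d$group) == 0L))
    stop("empty stratification group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit, censored = TRUE)
  grp <- sub("^group=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, n_censor = sm$n.censor,
             survival = sm$surv, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard chi-square (1 df) log-rank comparison of the event incidence
#' between the low and high groups.
#'
#' @inheritParams km_estimate
#' @return List with `statistic` and `p_value`.
#' @export
logrank_test <- function(records, strat) {
  d <- join_survival(records, strat)
  if (any(table(d$group) == 0L)) stop("both groups must be non-empty")
  if (sum(d$event) == 0L) stop("log-rank test needs >= 1 event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  stat <- sd_$chisq
  list(statistic = as.numeric(stat),
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Hazard ratio (high vs. low) from a single-covariate Cox model
#'
#' Fits a proportional-hazards model with the stratification group as the
#' only covariate (Efron handling of tied event times) and reports
#' `HR = exp(beta)` for the high group relative to low, with a 95% Wald CI
#' from the observed information. A monotone partial likelihood (all
#' events in one group before any in the other, so the estimate diverges)
#' is flagged and the CI reported as unbounded.
#'
#' @inheritParams km_estimate
#' @return List with `hazard_ratio`, `hr_ci_low`, `hr_ci_high`,
#'   `cox_p_value` and `monotone` (logical flag).
#' @export
cox_hr <- function(records, strat) {
  d <- join_survival(records, strat)
  if (any(table(d$group) == 0L)) stop("both groups must be non-empty")
  if (sum(d$event) == 0L) stop("Cox model needs >= 1 event")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = d,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[["grouphigh"]])
  se <- sqrt(unname(fit$var[1L, 1L]))
  monotone <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) ||
    se > 100
  if (monotone) {
    return(list(hazard_ratio = exp(beta), hr_ci_low = 0,
                hr_ci_high = Inf, cox_p_value = NA_real_, monotone = TRUE))
  }
  list(hazard_ratio = exp(beta),
       hr_ci_low = exp(beta - stats::qnorm(0.975) * se),
       hr_ci_high = exp(beta + stats::qnorm(0.975) * se),
       cox_p_value = 2 * stats::pnorm(-abs(beta / se)),
       monotone = FALSE)
}

#' Median-split survival comparison
#'
#' The full stratified survival analysis for one score: median split,
#' Kaplan-Meier curves per group, log-rank test, and the high-vs-low Cox
#' hazard ratio.
#'
#' @param records Survival `data.frame` (`sample_id`, `time`, `event`).
#' @param scores Named per-sample score vector.
#' @return List of class `survival_comparison`: `stratification`,
#'   `km_curves`, `logrank_statistic`, `logrank_p`, `hazard_ratio`,
#'   `hr_ci_low`, `hr_ci_high`, `monotone`.
#' @export
compare_survival <- function(records, scores) {
  strat <- median_stratify(scores)
  lr <- logrank_test(records, strat)
  cx <- cox_hr(records, strat)
  structure(list(stratification = strat,
                 km_curves = km_estimate(records, strat),
                 logrank_statistic = lr$statistic,
                 logrank_p = lr$p_value,
                 hazard_ratio = cx$hazard_ratio,
                 hr_ci_low = cx$hr_ci_low, hr_ci_high = cx$hr_ci_high,
                 monotone = cx$monotone),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  n <- table(x$stratification$group)
  cat(sprintf(paste0("survival_comparison: n_low = %d, n_high = %d\n",
                     "  log-rank chi-square = %.3f (p = %.3g)\n",
                     "  HR (high vs low) = %.3f [%.3f, %.3f]\n"),
              n[["low"]], n[["high"]], x$logrank_statistic, x$logrank_p,
              x$hazard_ratio, x$hr_ci_low, x$hr_ci_high))
  invisible(x)
}
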