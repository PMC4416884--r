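#' Cox likelihood-ratio statistic of a risk score
#'
#' Fits a univariate Cox proportional-hazards model of the survival outcome
#' on the risk score (Breslow ties) and returns
#' `2 * (log PL at fitted beta - log PL at beta = 0)`. Approximately
#' chi-squared with 1 df when the risk is uninformative. Invariant under
#' strictly increasing affine transforms of the risk.
#'
#' @param risk numeric per-sample risk scores (non-constant).
#' @param surv aligned `survival_data`.
#' @return The likelihood-ratio statistic (a single non-negative number).
#' @export
likelihood_ratio <- function(risk, surv) {
  check_risk(risk, surv)
  if (sd(risk) == 0) abort("risk is constant; likelihood ratio undefined")
  fit <- tryCatch(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ risk,
                    ties = "breslow"),
    error = function(e) abort(paste0("CoxPH fit failed: ", conditionMessage(e))))
  if (anyNA(fit$coefficients)) abort("CoxPH fit did not converge to a finite coefficient")
  max(0, 2 * (fit$loglik[2] - fit$loglik[1]))
}

#' Harrell's concordance index
#'
#' The fraction of usable sample pairs in which the higher-risk sample
#' experiences the event first. A pair is usable when the sample with the
#' shorter time has an observed event (pairs with tied times are not
#' usable); tied risks count 1/2. 0.5 is chance, 1 perfect.
#'
#' @inheritParams likelihood_ratio
#' @return The concordance index, in \[0, 1\].
#' @export
harrell_c <- function(risk, surv) {
  check_risk(risk, surv)
  time <- surv$time
  event <- surv$event
  # usable: t_i < t_j and event_i == 1
  shorter <- outer(time, time, `<`)
  usable <- shorter & (event == 1)
  n_usable <- sum(usable)
  if (n_usable == 0) abort("no usable (comparable) pairs")
  higher <- outer(risk, risk, `>`)[usable]
  tied <- outer(risk, risk, `==`)[usable]
  (sum(higher) + 0.5 * sum(tied)) / n_usable
}

#' Cox-Snell R-squared of a risk score
#'
#' `1 - exp(-LR / n)` with `LR` the [likelihood_ratio()] statistic and `n`
#' the number of samples; a survival-model R-squared computable from the
#' likelihood ratio alone. Always in \[0, 1).
#'
#' @inheritParams likelihood_ratio
#' @return R-squared, in \[0, 1).
#' @export
r_squared <- function(risk, surv) {
  1 - exp(-likelihood_ratio(risk, surv) / nrow(surv))
}

#' Two-group log-rank test after a median split of the risk
#'
#' Samples with risk above the median form the high-risk group (ties at the
#' median go to the low-risk group); the two groups' survival curves are
#' compared with the two-sample log-rank chi-squared test (1 df).
#'
#' @inheritParams likelihood_ratio
#' @return A list: `p_value`, `statistic` (log-rank chi-squared), `split`
#'   (the median risk), `groups` (factor of `"low"`/`"high"` per sample),
#'   `n_low`, `n_high`.
#' @export
logrank_median_split <- function(risk, surv) {
  check_risk(risk, surv)
  split <- median(risk)
  grp <- factor(ifelse(risk > split, "high", "low"), levels = c("low", "high"))
  if (nlevels(droplevels(grp)) < 2) {
    abort("median split left a group empty (risks all tied)")
  }
  sd_fit <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  stat <- sd_fit$chisq
  list(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = unname(stat),
       split = split,
       groups = grp,
       n_low = sum(grp == "low"),
       n_high = sum(grp == "high"))
}

check_risk <- function(risk, surv) {
  if (length(risk) != nrow(surv)) abort("risk and survival data lengths differ")
  if (anyNA(risk) || any(!is.finite(risk))) abort("risk contains non-finite values")
  if (sum(surv$event) < 1) abort("survival data has no events")
  invisible(TRUE)
}

#' Evaluate a risk score against censored survival
#'
#' Computes the four statistics used to benchmark the predictor: Cox
#' likelihood ratio, Harrell's C index, Cox-Snell R-squared and the
#' median-split log-rank p-value.
#'
#' @inheritParams likelihood_ratio
#' @return A one-row tibble of class `evaluation_report`:
#'   `likelihood_ratio`, `c_index`, `r_squared`, `logrank_p`,
#'   `logrank_chisq`, `split`, `n_low`, `n_high`, `n`.
#' @export
evaluate_risk <- function(risk, surv) {
  lr <- likelihood_ratio(risk, surv)
  ls <- logrank_median_split(risk, surv)
  out <- tibble::tibble(
    likelihood_ratio = lr,
    c_index = harrell_c(risk, surv),
    r_squared = 1 - exp(-lr / nrow(surv)),
    logrank_p = ls$p_value,
    logrank_chisq = ls$statistic,
    split = ls$split,
    n_low = ls$n_low,
    n_high = ls$n_high,
    n = nrow(surv))
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Kaplan-Meier curve data for the median-split risk groups
#'
#' @inheritParams likelihood_ratio
#' @return A tibble with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival` (Kaplan-Meier estimate), suitable for step plots.
#' @export
km_curve_data <- function(risk, surv) {
  ls <- logrank_median_split(risk, surv)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ ls$groups)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  tibble::tibble(group = sub("^ls\\$groups=", "", strata),
                 time = fit$time,
                 n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 survival = fit$surv)
}
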