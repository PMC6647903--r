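#' Build survival endpoints from clinical records
#'
#' Disease-specific survival (DSS): the event is death from breast
#' cancer; patients alive at last contact and other-cause deaths are
#' censored at their follow-up time. Overall survival (OS): the event is
#' death from any cause; only patients alive at last contact are
#' censored.
#'
#' @param clinical data.frame with columns `followup_years` (> 0) and
#'   `cause` (`"breast_cancer_death"` / `"other_death"` / `"alive"`).
#' @return data.frame of class `survival_endpoints` with columns
#'   `time_years` and `event` (0/1).
#' @export
build_dss <- function(clinical) {
  check_clinical(clinical)
  endpoints(clinical$followup_years,
            as.integer(clinical$cause == "breast_cancer_death"))
}

#' @rdname build_dss
#' @export
build_os <- function(clinical) {
  check_clinical(clinical)
  endpoints(clinical$followup_years, as.integer(clinical$cause != "alive"))
}

check_clinical <- function(clinical) {
  stopifnot(is.data.frame(clinical),
            all(c("followup_years", "cause") %in% names(clinical)))
  if (any(clinical$followup_years <= 0))
    stop("follow-up times must be positive")
  if (!all(clinical$cause %in% c("breast_cancer_death", "other_death",
                                 "alive")))
    stop("unknown cause values")
  invisible(clinical)
}

#' @rdname build_dss
#' @param time_years positive follow-up times.
#' @param event 0/1 event indicators.
#' @export
endpoints <- function(time_years, event) {
  stopifnot(length(time_years) == length(event), all(time_years > 0),
            all(event %in% c(0L, 1L)))
  structure(data.frame(time_years = time_years, event = as.integer(event)),
            class = c("survival_endpoints", "data.frame"))
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator with Greenwood standard errors and 95%
#' confidence intervals on the complementary log-log scale, clipped to
#' `[0, 1]`. With no events the curve is flat at 1.
#'
#' @param ep a [endpoints()] data.frame.
#' @return object of class `km_curve`: `event_times`, `survival`,
#'   `greenwood_se`, `lower`, `upper`, `n_at_risk`, `n_events`, plus the
#'   underlying `survfit` object in `$fit`.
#' @export
km_estimate <- function(ep) {
  stopifnot(inherits(ep, "survival_endpoints"), nrow(ep) >= 1L)
  fit <- survival::survfit(
    survival::Surv(time_years, event) ~ 1,
    data = ep, conf.type = "log-log", conf.int = 0.95)
  is_event <- fit$n.event > 0
  structure(list(
    event_times = fit$time[is_event],
    survival = fit$surv[is_event],
    greenwood_se = (fit$std.err * fit$surv)[is_event],
    lower = pmax(fit$lower, 0)[is_event],
    upper = pmin(fit$upper, 1)[is_event],
    n_at_risk = fit$n.risk[is_event],
    n_events = fit$n.event[is_event],
    fit = fit
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d event times, S(last) = %.3f\n",
              length(x$event_times),
              if (length(x$survival)) min(x$survival) else 1))
  invisible(x)
}

#' Survival probability at a time point
#'
#' Right-continuous step-function value of the Kaplan-Meier curve at
#' `t`, with its 95% confidence interval. Times before the first
#' observation give survival 1.
#'
#' @param curve a [km_estimate()] result.
#' @param t time in years (default 10).
#' @return list with `estimate`, `lower`, `upper`.
#' @export
survival_at <- function(curve, t = 10) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  s <- summary(curve$fit, times = t, extend = TRUE)
  list(estimate = s$surv,
       lower = if (is.na(s$lower)) 0 else max(s$lower, 0),
       upper = if (is.na(s$upper)) 1 else min(s$upper, 1))
}

#' Two-group log-rank test
#'
#' Observed-versus-expected event counts over the shared risk sets,
#' one degree of freedom.
#'
#' @param ep a [endpoints()] data.frame.
#' @param group binary group vector (two non-empty levels).
#' @return list with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(ep, group) {
  stopifnot(inherits(ep, "survival_endpoints"),
            length(group) == nrow(ep))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L || any(table(group) == 0))
    stop("exactly two non-empty groups are required")
  sd <- survival::survdiff(
    survival::Surv(time_years, event) ~ g,
    data = cbind(ep, g = group))
  list(chisq = sd$chisq, df = 1L,
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximisation of the partial likelihood with Efron
#' handling of tied event times (Breslow available). Wald 95% confidence
#' intervals and p-values per coefficient. Constant covariates are
#' rejected, and monotone-likelihood (complete separation) fits are
#' flagged as errors with the offending coefficient in the message.
#'
#' @param ep a [endpoints()] data.frame.
#' @param covariates data.frame or matrix of covariates (factors
#'   allowed in a data.frame).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: `coefficients`, `hazard_ratios`,
#'   `ci95` (matrix), `p_values`, `log_partial_likelihood`,
#'   `loglik_null`, `n`, `n_events`, and the `coxph` object in `$fit`.
#' @export
cox_fit <- function(ep, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(ep, "survival_endpoints"))
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(ep))
  if (nrow(ep) <= ncol(covariates))
    stop("need more observations than covariates")
  constant <- vapply(covariates, function(v) length(unique(v)) < 2L,
                     logical(1))
  if (any(constant))
    stop("constant covariate(s): ",
         paste(names(covariates)[constant], collapse = ", "))
  dat <- cbind(ep, covariates)
  form <- stats::as.formula(paste(
    "survival::Surv(time_years, event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        stop("monotone partial likelihood or non-convergence: ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- co / se
  ci <- cbind(lower = exp(co - 1.96 * se), upper = exp(co + 1.96 * se))
  structure(list(coefficients = co,
                 hazard_ratios = exp(co),
                 ci95 = ci,
                 p_values = 2 * pnorm(-abs(z)),
                 se = se,
                 log_partial_likelihood = fit$loglik[2],
                 loglik_null = fit$loglik[1],
                 n = fit$n, n_events = fit$nevent,
                 covariate_names = names(covariates),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    lower95 = x$ci95[, 1], upper95 = x$ci95[, 2],
                    p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Cox model table in long form
#'
#' One row per fitted coefficient: coefficient, hazard ratio, 95% CI
#' and p-value; convenient for writing the evaluation TSV.
#'
#' @param fit a [cox_fit()] result.
#' @return data.frame.
#' @export
cox_table <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  data.frame(term = names(fit$coefficients),
             coef = unname(fit$coefficients),
             hr = unname(fit$hazard_ratios),
             hr_lower95 = unname(fit$ci95[, 1]),
             hr_upper95 = unname(fit$ci95[, 2]),
             p_value = unname(fit$p_values),
             row.names = NULL)
}

#' Harrell's concordance index
#'
#' Over usable pairs (the patient with the shorter observed time had an
#' event), the fraction in which the higher risk score belongs to the
#' patient with the shorter time; score ties count 1/2.
#'
#' @param scores risk scores (higher = higher predicted risk).
#' @param ep a [endpoints()] data.frame.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(scores, ep) {
  stopifnot(inherits(ep, "survival_endpoints"),
            length(scores) == nrow(ep))
  if (nrow(ep) < 2L || sum(ep$event) == 0L)
    stop("need at least two records and one event")
  cc <- harrell_cindex_cpp(as.numeric(scores), ep$time_years, ep$event)
  if (cc$usable == 0) stop("no usable (comparable) pairs")
  cc$concordant / cc$usable
}

#' Percentile-bootstrap confidence interval for the C-index
#'
#' Resamples patients with replacement and reports the percentile
#' interval of the resampled C-index.
#'
#' @param scores risk scores.
#' @param ep a [endpoints()] data.frame.
#' @param n_boot number of resamples.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `estimate`, `lower`, `upper`, `n_boot`.
#' @export
cindex_bootstrap_ci <- function(scores, ep, n_boot = 2000L, seed = 1L,
                                conf = 0.95) {
  est <- concordance_index(scores, ep)
  n <- nrow(ep)
  boots <- with_seed(derive_seed(seed, n_boot, 8L), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(concordance_index(scores[idx], endpoints(
        ep$time_years[idx], ep$event[idx])), error = function(e) NA_real_)
    }, numeric(1))
  })
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  list(estimate = est, lower = unname(qs[1]), upper = unname(qs[2]),
       n_boot = n_boot)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' Twice the gain in log partial likelihood of the full over the nested
#' model, referred to a chi-square distribution with degrees of freedom
#' equal to the difference in parameter count. Requires the models to be
#' fitted on the same endpoints with nested covariate sets.
#'
#' @param fit_nested,fit_full [cox_fit()] results.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
compare_models_lrt <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "cox_fit"), inherits(fit_full, "cox_fit"))
  if (fit_nested$n != fit_full$n || fit_nested$n_events != fit_full$n_events)
    stop("models must be fitted on the same endpoints")
  if (!all(fit_nested$covariate_names %in% fit_full$covariate_names))
    stop("covariates of the nested model must be a subset of the full model")
  df <- length(fit_full$coefficients) - length(fit_nested$coefficients)
  if (df < 0) stop("full model has fewer parameters than the nested model")
  chisq <- max(0, 2 * (fit_full$log_partial_likelihood -
                         fit_nested$log_partial_likelihood))
  p <- if (df == 0) 1 else pchisq(chisq, df = df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p_value = p)
}

#' Proportional-hazards check via Schoenfeld residuals
#'
#' Tests a non-zero slope of the scaled Schoenfeld residuals against
#' time for each covariate; covariates with p below `alpha` violate the
#' proportionality assumption (the evaluation layer drops such
#' covariates from multivariate models, mirroring common practice).
#'
#' @param fit a [cox_fit()] result.
#' @param alpha significance level.
#' @return data.frame with columns `term`, `p_value`, `violates`.
#' @export
check_proportionality <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cox_fit"))
  zp <- survival::cox.zph(fit$fit)
  tab <- zp$table
  terms <- setdiff(rownames(tab), "GLOBAL")
  data.frame(term = terms,
             p_value = tab[terms, "p"],
             violates = tab[terms, "p"] < alpha,
             row.names = NULL)
}
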