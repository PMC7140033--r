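#' Median split of a continuous marker
#'
#' Splits records at the cohort median of the marker: values above the
#' median are `"High"`, values at or below it (including ties at the
#' median) are `"Low"`.
#'
#' @param records Survival-record data frame (see [survival_records()]).
#' @return Factor of group labels with levels `High`, `Low` (High first, the
#'   reference level used by [cox_ph_fit()]).
#' @export
median_split <- function(records) {
  if (nrow(records) < 2L) stop("need at least 2 records to split")
  med <- median(records$marker)
  if (all(records$marker == records$marker[1L]))
    stop("all marker values are equal; no median split possible")
  factor(ifelse(records$marker > med, "High", "Low"), levels = c("High", "Low"))
}

#' Kaplan-Meier product-limit curves
#'
#' One curve per group: S(t) = prod over event times t_i <= t of
#' (1 - d_i/n_i). The median survival is the first event time at which S
#' drops to 0.5 or below, `NA` if the curve never reaches it.
#'
#' @param records Survival-record data frame.
#' @param groups Optional factor/character of group labels (one per record);
#'   a single pooled curve when omitted.
#' @return Named list (one element per group) of `km_curve` lists with
#'   `time` (event times), `survival`, `at_risk`, `n_event`, `median`,
#'   `group`.
#' @export
km_estimator <- function(records, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(records))
  groups <- as.character(groups)
  out <- lapply(split(seq_len(nrow(records)), groups), function(idx) {
    fit <- survival::survfit(
      survival::Surv(time, event) ~ 1,
      data = records[idx, , drop = FALSE])
    ev <- fit$n.event > 0
    surv_at_events <- fit$surv[ev]
    med <- if (any(surv_at_events <= 0.5))
      fit$time[ev][which(surv_at_events <= 0.5)[1L]] else NA_real_
    list(time = fit$time[ev], survival = fit$surv[ev],
         at_risk = fit$n.risk[ev], n_event = fit$n.event[ev], median = med)
  })
  for (g in names(out)) out[[g]]$group <- g
  lapply(out, function(cv) structure(cv, class = "km_curve"))
}

#' Two-group log-rank test
#'
#' chi-square = (O1 - E1)^2 / V with expectations and hypergeometric
#' variance accumulated over the pooled event times; p from chi-square with
#' 1 degree of freedom. Invariant to swapping the group labels.
#'
#' @param records Survival-record data frame.
#' @param groups Two-level factor/character of group labels.
#' @return List with `chisq`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(records, groups) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("log-rank test needs exactly 2 groups")
  if (sum(records$event) < 1L) stop("no events; log-rank variance is zero")
  df <- cbind(records, .grp = groups)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ .grp, data = df)
  chisq <- unname(sd_fit$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE),
       observed = setNames(sd_fit$obs, levels(groups)),
       expected = setNames(sd_fit$exp, levels(groups)))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Newton-Raphson, Efron handling of tied event
#' times by default) of survival on the median-split marker group, age and
#' stage. The marker group is coded against the `High` reference and stage
#' against stage I, so hazard ratios read as risk in Low-marker patients and
#' advanced stages relative to those references.
#'
#' @param records Survival-record data frame.
#' @param covariates Subset of `c("marker_group", "age", "stage")`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Data frame of class `cox_result`: `term`, `coef`, `HR`,
#'   `CI_low`, `CI_high`, `p`; the fitted `survival::coxph` object is
#'   attached as attribute `fit`.
#' @export
cox_ph_fit <- function(records, covariates = c("marker_group", "age", "stage"),
                       ties = c("efron", "breslow"), conf_level = 0.95) {
  ties <- match.arg(ties)
  covariates <- match.arg(covariates, several.ok = TRUE)
  if (sum(records$event) < 1L) stop("no events; Cox model is undefined")
  df <- records
  df$marker_group <- median_split(records)
  df$stage <- factor(as.character(df$stage), levels = c("I", "II", "III", "IV"))
  df$stage <- droplevels(df$stage)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(covariates, collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = ties)
  if (!is.null(fit$info) && isTRUE(grepl("infinite", fit$info)))
    warning("possible monotone likelihood (perfect separation)")
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  ci <- sm$conf.int
  out <- data.frame(term = rownames(co), coef = co[, "coef"],
                    HR = co[, "exp(coef)"],
                    CI_low = ci[, 3L], CI_high = ci[, 4L],
                    p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", "data.frame")
  out
}
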