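# Survival machinery: Kaplan-Meier, log-rank, Cox (Efron ties),
# time-dependent ROC with inverse-probability-of-censoring weights, binary
# ROC, and the generic two-group / correlation statistics.

#' Kaplan-Meier fit of a single group
#'
#' Product-limit estimator with Greenwood standard errors and a
#' Brookmeyer-Crowley style median CI on the log-log scale. The median is
#' the first time at which the survival estimate drops to 0.5 or below;
#' with no such time it is reported as `NA` ("not reached").
#'
#' @param time positive survival times.
#' @param event 0/1 event indicators.
#' @return Object of class `km_fit`: list with `time`, `n_risk`,
#'   `n_event`, `surv`, `std_err` (Greenwood, on the survival scale),
#'   `median`, `median_ci` (95%), and the underlying `survfit` object.
#' @export
km_fit <- function(time, event) {
  assert_survival(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit, rmean = max(time))$table
  med <- unname(tab["median"])
  ci <- unname(c(tab["0.95LCL"], tab["0.95UCL"]))
  structure(
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         surv = fit$surv, std_err = fit$std.err * fit$surv,
         median = med, median_ci = ci,
         rmean = unname(tab[grep("rmean$", names(tab))][1L]),
         survfit = fit),
    class = "km_fit"
  )
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected chi-square log-rank statistic with
#' `groups - 1` degrees of freedom.
#'
#' @param time,event survival data.
#' @param group per-sample group labels (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  assert_survival(time, event)
  group <- factor(group)
  if (nlevels(group) < 2L || any(table(group) == 0L)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Wraps `survival::coxph` with Efron tie handling and Newton-Raphson
#' maximization; reports per-covariate hazard ratios with Wald 95% CIs and
#' p-values. Non-convergence or separation is flagged, never silently
#' returned.
#'
#' @param time,event survival data.
#' @param covariates data.frame (or named matrix) of covariates, one row
#'   per sample.
#' @return Object of class `cox_fit`: data.frame `coefficients` (term,
#'   coef, hr, lower, upper, p), `loglik` (at the optimum), `converged`.
#' @export
cox_fit <- function(time, event, covariates) {
  assert_survival(time, event)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time)) {
    stop("`covariates` must have one row per sample", call. = FALSE)
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|singular",
                conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  coefs <- data.frame(
    term = rownames(co),
    coef = unname(co[, "coef"]),
    hr = unname(co[, "exp(coef)"]),
    lower = unname(ci[, "lower .95"]),
    upper = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (any(!is.finite(coefs$coef))) converged <- FALSE
  structure(list(coefficients = coefs, loglik = fit$loglik[2L],
                 converged = converged, fit = fit),
            class = "cox_fit")
}

# Left-continuous step evaluation of a KM curve given its jump times and
# values: S(t-) if left = TRUE, S(t) otherwise.
km_step_eval <- function(jump_times, surv, t, left = FALSE) {
  vapply(t, function(ti) {
    if (left) {
      i <- sum(jump_times < ti)
    } else {
      i <- sum(jump_times <= ti)
    }
    if (i == 0L) 1 else surv[i]
  }, numeric(1))
}

#' Time-dependent ROC with KM censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each horizon t: cases are
#' subjects with an observed event at or before t, controls are subjects
#' still under observation beyond t. Censoring is handled by inverse
#' probability of censoring weighting: case i gets weight `1 / G(T_i-)`
#' and every control gets `1 / G(t)`, where G is the Kaplan-Meier estimate
#' of the censoring survival function. The AUC is the weighted fraction of
#' concordant case/control pairs (ties counted 1/2).
#'
#' @param time,event survival data.
#' @param marker numeric risk marker (higher = predicted earlier event).
#' @param horizons evaluation times; each must not exceed the last
#'   observed time.
#' @return Object of class `time_roc`: data.frame `auc` (horizon, auc,
#'   n_case, n_control) and list `curves` of sensitivity/specificity
#'   grids per horizon.
#' @export
time_roc <- function(time, event, marker, horizons) {
  assert_survival(time, event)
  if (length(marker) != length(time) || any(!is.finite(marker))) {
    stop("`marker` must be finite and aligned with `time`", call. = FALSE)
  }
  if (any(horizons > max(time))) {
    stop("horizon(s) beyond the last observed time: ",
         paste(horizons[horizons > max(time)], collapse = ", "),
         call. = FALSE)
  }
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  jt <- cfit$time[cfit$n.event > 0]
  js <- cfit$surv[cfit$n.event > 0]

  res <- lapply(horizons, function(h) {
    case <- which(event == 1 & time <= h)
    ctrl <- which(time > h)
    if (length(case) == 0L || length(ctrl) == 0L) {
      return(list(auc = NA_real_, n_case = length(case),
                  n_control = length(ctrl), curve = NULL))
    }
    w_case <- 1 / km_step_eval(jt, js, time[case], left = TRUE)
    w_ctrl <- rep(1 / km_step_eval(jt, js, h), length(ctrl))
    mc <- marker[case]
    mk <- marker[ctrl]
    conc <- outer(mc, mk, ">") + 0.5 * outer(mc, mk, "==")
    wmat <- outer(w_case, w_ctrl)
    auc <- sum(conc * wmat) / sum(wmat)
    thr <- sort(unique(marker))
    sens <- vapply(thr, function(c) sum(w_case[mc > c]) / sum(w_case), numeric(1))
    spec <- vapply(thr, function(c) sum(w_ctrl[mk <= c]) / sum(w_ctrl), numeric(1))
    list(auc = auc, n_case = length(case), n_control = length(ctrl),
         curve = data.frame(threshold = thr, sensitivity = sens,
                            specificity = spec))
  })
  structure(
    list(auc = data.frame(horizon = horizons,
                          auc = vapply(res, `[[`, numeric(1), "auc"),
                          n_case = vapply(res, `[[`, numeric(1), "n_case"),
                          n_control = vapply(res, `[[`, numeric(1), "n_control")),
         curves = lapply(res, `[[`, "curve")),
    class = "time_roc"
  )
}

#' Binary ROC and AUC by concordant-pair counting
#'
#' AUC equals the Mann-Whitney U statistic divided by `n1 * n0`, with tied
#' marker values counted 1/2.
#'
#' @param labels 0/1 (or two-level) class labels; the second factor level /
#'   value 1 is "positive".
#' @param marker numeric marker, higher = more positive.
#' @return list with `auc` and `curve` (data.frame threshold, tpr, fpr).
#' @export
binary_roc <- function(labels, marker) {
  if (length(labels) != length(marker) || any(!is.finite(marker))) {
    stop("`marker` must be finite and aligned with `labels`", call. = FALSE)
  }
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) != 2L) {
    stop("`labels` must contain both classes (0/1)", call. = FALSE)
  }
  r <- rank(marker)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(marker)))
  tpr <- vapply(thr, function(c) mean(marker[y == 1L] > c), numeric(1))
  fpr <- vapply(thr, function(c) mean(marker[y == 0L] > c), numeric(1))
  list(auc = auc, curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact for groups of up to 10 untied observations, normal approximation
#' with tie correction otherwise.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return two-sided p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need n >= 2 per group", call. = FALSE)
  }
  exact <- length(x) <= 10L && length(y) <= 10L && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value)
}

#' Spearman rank correlation
#'
#' Rho on ranks with the t-approximation p-value. A zero-variance input is
#' flagged: rho is returned as `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
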