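# longsurv: longitudinal mixed models, Kaplan-Meier / log-rank, Cox
# proportional hazards, and 2x2 association tests.

#' Linear mixed model with random subject intercepts
#'
#' Fits `value ~ fixed effects + (1 | subject)` by maximum likelihood
#' (default) or REML through `lme4::lmer`, the model used for longitudinal
#' change of a dysbiosis feature (Shannon, bacterial load, anaerobe or
#' pathogen abundance) over days of follow-up. Unbalanced panels are fine;
#' with zero between-subject variance the fixed effects collapse to
#' ordinary least squares.
#'
#' @param data Data frame in long format.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect column names (e.g. `"day"`
#'   and covariates).
#' @param subject Name of the subject-id column.
#' @param reml Use REML instead of ML (default `FALSE`).
#' @return A list of class `lmm_fit`: `fixed` (estimate, se, t), `sigma_b`
#'   (random-intercept SD), `sigma_e` (residual SD), `log_lik`, and the
#'   underlying `lme4` fit in `fit`.
#' @export
fit_lmm <- function(data, response, fixed, subject, reml = FALSE) {
  for (col in c(response, fixed, subject))
    if (!col %in% names(data)) stop_("column not found: ", col)
  if (length(unique(data[[subject]])) < 2L)
    stop_("need at least 2 subjects")
  form <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+ (1 |", subject, ")"))
  mm <- model.matrix(stats::reformulate(fixed), data)
  if (qr(mm)$rank < ncol(mm)) stop_("singular fixed-effect design")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = data, REML = reml)))
  sfit <- summary(fit)
  vc <- lme4::VarCorr(fit)
  structure(list(
    fixed = data.frame(term = rownames(sfit$coefficients),
                       estimate = sfit$coefficients[, "Estimate"],
                       se = sfit$coefficients[, "Std. Error"],
                       t = sfit$coefficients[, "t value"],
                       row.names = NULL),
    sigma_b = attr(vc[[subject]], "stddev")[[1L]],
    sigma_e = stats::sigma(fit),
    log_lik = as.numeric(stats::logLik(fit)),
    reml = reml,
    fit = fit), class = "lmm_fit")
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group with the usual log-rank
#' chi-square test across groups (omitted when there is a single group).
#'
#' @param records Data frame with columns `time` and `event` (0/1).
#' @param groups Optional grouping vector aligned with `records`.
#' @return List: `curves` (data frame group/time/n_risk/surv/lower/upper)
#'   and `logrank_p` (`NA` for a single group).
#' @export
kaplan_meier <- function(records, groups = NULL) {
  if (nrow(records) == 0L) stop_("no records")
  if (!all(records$event %in% c(0, 1))) stop_("`event` must be 0/1")
  if (is.null(groups)) groups <- rep("all", nrow(records))
  groups <- factor(groups)
  if (any(table(groups) == 0L) || nlevels(droplevels(groups)) != nlevels(groups))
    stop_("empty group")
  df <- data.frame(time = records$time, event = records$event, group = groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(sf$strata)) setNames(length(sf$time), paste0("group=", levels(groups)[1L]))
            else sf$strata
  curves <- data.frame(
    group = rep(sub("^group=", "", names(strata)), strata),
    time = sf$time, n_risk = sf$n.risk, surv = sf$surv,
    lower = sf$lower, upper = sf$upper, row.names = NULL)
  logrank_p <- NA_real_
  if (nlevels(groups) > 1L) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    logrank_p <- pchisq(sd_$chisq, df = nlevels(groups) - 1L, lower.tail = FALSE)
  }
  list(curves = curves, logrank_p = logrank_p)
}

#' Cox proportional hazards model
#'
#' Partial-likelihood Cox regression (Efron tie handling by default,
#' Breslow behind the flag) with Wald confidence intervals on the hazard
#' ratios. When the likelihood is monotone (complete separation, flagged by
#' an infinite-coefficient warning), the model is refitted with a small
#' ridge penalty and marked `penalized = TRUE`.
#'
#' @param records Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for the Wald CI (default 0.95).
#' @return A list of class `cox_fit`: `coefficients` (term, coef, HR,
#'   lower, upper, se, p), `log_lik`, `ties`, `penalized`, and the
#'   underlying `coxph` fit.
#' @export
fit_cox <- function(records, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  if (sum(records$event) < 1L) stop_("need at least one event")
  for (col in covariates) {
    if (!col %in% names(records)) stop_("column not found: ", col)
    v <- records[[col]]
    if (is.numeric(v) && sd(v) == 0) stop_("constant covariate: ", col)
  }
  form <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = records, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  penalized <- FALSE
  if (separation) {
    pform <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ survival::ridge(",
      paste(covariates, collapse = ", "), ", theta = 1)"))
    fit <- suppressWarnings(survival::coxph(pform, data = records, ties = ties))
    penalized <- TRUE
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  coefficients <- data.frame(
    term = names(cf), coef = unname(cf), HR = exp(unname(cf)),
    lower = exp(unname(cf) - z * se), upper = exp(unname(cf) + z * se),
    se = unname(se), p = 2 * pnorm(abs(unname(cf) / se), lower.tail = FALSE),
    row.names = NULL)
  structure(list(coefficients = coefficients,
                 log_lik = as.numeric(stats::logLik(fit)),
                 ties = ties, penalized = penalized, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties%s)\n", x$ties,
              if (x$penalized) ", ridge-penalized" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Odds ratio and Fisher exact test for a 2x2 table
#'
#' Point estimate is the sample cross-product odds ratio `(a d)/(b c)`,
#' with the Haldane-Anscombe 0.5 continuity correction applied to every
#' cell when any cell is zero. The confidence interval is the Woolf
#' log-odds interval. The two-sided p-value is the exact hypergeometric
#' (Fisher) test. Note the point estimate is deliberately the corrected
#' sample OR, not the conditional maximum-likelihood estimate some
#' environments report.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `odds_ratio`, `ci`, `p`.
#' @export
#' @examples
#' fisher_association(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
fisher_association <- function(counts, conf_level = 0.95) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop_("`counts` must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_("counts must be non-negative integers")
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d <- counts[2, 2]
  if (any(counts == 0)) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c_)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- fisher.test(counts)$p.value
  list(odds_ratio = or, ci = ci, p = p)
}

#' Low-Diversity persister contrast
#'
#' Derives the binary "persister" covariate — Low-Diversity cluster at both
#' the baseline and middle interval — and feeds it to an age-adjusted Cox
#' model among subjects with an available follow-up label.
#'
#' @param records One row per subject: `time`, `event`, `age`, plus
#'   `label_baseline` and `label_middle` cluster labels (`NA` middle label
#'   = no follow-up sample; those subjects are excluded).
#' @return A `cox_fit` for `persister + age`, plus the derived data in
#'   `$data`.
#' @export
persister_cox <- function(records) {
  keep <- !is.na(records$label_middle)
  df <- records[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop_("no subjects with follow-up labels")
  df$persister <- as.integer(df$label_baseline == "Low" & df$label_middle == "Low")
  fit <- fit_cox(df, c("persister", "age"))
  fit$data <- df
  fit
}
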