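#' Pearson or Spearman correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return Named list: `coefficient`, `p_value`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value)
}

#' Assign iLumA% quartiles
#'
#' Thresholds at the 25/50/75 sample percentiles; values tied with a
#' threshold fall into the lower quartile. Q1 holds the lowest iLumA%
#' (most admixed) cases, Q4 the highest (purest).
#'
#' @param values Numeric vector, length at least 4.
#' @return Factor with levels Q1-Q4, same length as `values`.
#' @export
assign_quartiles <- function(values) {
  if (length(values) < 4) stop("need at least 4 cases", call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("all values equal; quartiles are degenerate", call. = FALSE)
  }
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  idx <- 1L + (values > qs[1]) + (values > qs[2]) + (values > qs[3])
  factor(paste0("Q", idx), levels = paste0("Q", 1:4))
}

#' Compare the purest quartile with the most admixed
#'
#' Binary features use the chi-squared test on the Q1/Q4 2x2 table (no
#' continuity correction); continuous features use the two-sample Student
#' t test. Two-sided p-values.
#'
#' @param feature Per-case feature values.
#' @param quartiles Factor from [assign_quartiles()].
#' @param feature_type `"binary"` or `"continuous"`.
#' @param correct Apply Yates continuity correction to the chi-squared test.
#' @return Named list: `statistic`, `p_value`.
#' @export
q1_vs_q4_test <- function(feature, quartiles,
                          feature_type = c("binary", "continuous"),
                          correct = FALSE) {
  feature_type <- match.arg(feature_type)
  g1 <- feature[quartiles == "Q1"]
  g4 <- feature[quartiles == "Q4"]
  g1 <- g1[!is.na(g1)]; g4 <- g4[!is.na(g4)]
  if (!length(g1) || !length(g4)) stop("empty quartile group", call. = FALSE)
  if (feature_type == "binary") {
    tab <- rbind(Q1 = c(sum(g1 == 1), sum(g1 == 0)),
                 Q4 = c(sum(g4 == 1), sum(g4 == 0)))
    if (identical(mean(g1), mean(g4))) {
      return(list(statistic = 0, p_value = 1))
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  } else {
    if (stats::sd(g1) == 0 && stats::sd(g4) == 0) {
      stop("zero-variance continuous feature in both groups", call. = FALSE)
    }
    ht <- stats::t.test(g1, g4, var.equal = TRUE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Ordinal linear-trend test across quartiles
#'
#' Ordinary least squares of the per-case feature on the quartile coded
#' 1-4; reports the slope and its two-sided p-value.
#'
#' @param feature Per-case feature values.
#' @param quartiles Factor from [assign_quartiles()].
#' @return Named list: `slope`, `p_value`.
#' @export
trend_test <- function(feature, quartiles) {
  qnum <- as.integer(factor(quartiles, levels = paste0("Q", 1:4)))
  keep <- !is.na(feature) & !is.na(qnum)
  if (length(unique(qnum[keep])) < 2) {
    stop("need at least 2 distinct quartiles", call. = FALSE)
  }
  fit <- stats::lm(feature[keep] ~ qnum[keep])
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2) return(list(slope = 0, p_value = 1))
  list(slope = unname(sm[2, 1]), p_value = unname(sm[2, 4]))
}

#' ER-related gene expression score
#'
#' Per-case unweighted mean of the four Oncotype DX ER-group genes (ESR1,
#' PGR, BCL2, SCUBE2) on normalized log-scale expression.
#'
#' @param expression Genes x cases matrix (log scale) whose rownames
#'   include the four ER-group genes.
#' @param genes The four gene identifiers.
#' @return Named per-case score vector.
#' @export
er_gene_score <- function(expression,
                          genes = c("ESR1", "PGR", "BCL2", "SCUBE2")) {
  missing <- setdiff(genes, rownames(expression))
  if (length(missing)) {
    stop("missing ER-group gene row(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  colMeans(expression[genes, , drop = FALSE])
}

#' MATH score of mutant-allele heterogeneity
#'
#' Median absolute deviation (unscaled, constant = 1) of the mutant-allele
#' fractions divided by their median. Identical fractions give 0.
#'
#' @param vaf_list Numeric vector of mutant-allele fractions in (0, 1\];
#'   at least 3 values.
#' @return Nonnegative score.
#' @export
math_score <- function(vaf_list) {
  vaf_list <- vaf_list[!is.na(vaf_list)]
  if (length(vaf_list) < 3) stop("need at least 3 allele fractions", call. = FALSE)
  med <- stats::median(vaf_list)
  if (med == 0) stop("median allele fraction is 0; score undefined", call. = FALSE)
  stats::mad(vaf_list, constant = 1) / med
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates per group plus, for two or more groups, the
#' two-sided log-rank test.
#'
#' @param times Follow-up times (> 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group_labels Group per case.
#' @return Named list: `curves` (data.frame: group, time, n_risk, n_event,
#'   survival), `statistic`, `p_value` (NA for a single group).
#' @export
km_logrank <- function(times, events, group_labels) {
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (sum(events) == 0) stop("no events in any group", call. = FALSE)
  group_labels <- as.factor(group_labels)
  fit <- survival::survfit(survival::Surv(times, events) ~ group_labels)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group_labels)[1], length(fit$time))
  } else {
    rep(sub("^group_labels=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, survival = fit$surv,
                       stringsAsFactors = FALSE)
  stat <- NA_real_; p <- NA_real_
  if (nlevels(group_labels) >= 2) {
    lr <- survival::survdiff(survival::Surv(times, events) ~ group_labels)
    stat <- lr$chisq
    p <- stats::pchisq(lr$chisq, df = nlevels(group_labels) - 1,
                       lower.tail = FALSE)
  }
  list(curves = curves, statistic = stat, p_value = p)
}

#' Cox proportional-hazards comparison with follow-up time splitting
#'
#' Estimates the hazard ratio (Efron ties, Wald 95% CI) for `group`,
#' optionally adjusted for covariates, within one of three follow-up
#' strata: the entire follow-up; 0-3 years (events after 36 months
#' censored at 36); or beyond 3 years (landmark analysis restricted to
#' cases still at risk at 36 months, clock restarted at 36).
#'
#' @param times Follow-up times in months.
#' @param events Event indicators.
#' @param group Binary group (factor or 0/1); the hazard ratio is for the
#'   second level vs the first.
#' @param covariates Optional data.frame of adjustment covariates.
#' @param stratum `"entire"`, `"0-3y"` or `">3y"`.
#' @return One-row data.frame of class `survival_comparison`: `stratum`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `logrank_p`, `n`, `n_events`.
#' @export
cox_hr <- function(times, events, group, covariates = NULL,
                   stratum = c("entire", "0-3y", ">3y")) {
  stratum <- match.arg(stratum)
  group <- as.factor(group)
  keep <- rep(TRUE, length(times))
  t2 <- times; e2 <- events
  if (stratum == "0-3y") {
    e2 <- ifelse(times > 36, 0L, events)
    t2 <- pmin(times, 36)
  } else if (stratum == ">3y") {
    keep <- times > 36
    t2 <- times - 36
  }
  t2 <- t2[keep]; e2 <- e2[keep]; g2 <- droplevels(group[keep])
  if (sum(e2) < 1) stop("no events in the analyzed stratum", call. = FALSE)
  if (nlevels(g2) < 2) stop("only one group present in stratum", call. = FALSE)
  dat <- data.frame(.time = t2, .event = e2, .group = g2)
  form <- .time_formula(covariates, keep, dat)
  fit <- survival::coxph(form$formula, data = form$data, ties = "efron")
  co <- summary(fit)$coefficients
  i <- grep("^\\.group", rownames(co))[1]
  hr <- co[i, "exp(coef)"]
  se <- co[i, "se(coef)"]
  lr <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  logrank_p <- stats::pchisq(lr$chisq, df = nlevels(g2) - 1, lower.tail = FALSE)
  out <- data.frame(stratum = stratum, hazard_ratio = hr,
                    ci_low = exp(log(hr) - 1.96 * se),
                    ci_high = exp(log(hr) + 1.96 * se),
                    logrank_p = logrank_p, n = length(t2),
                    n_events = sum(e2), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("survival_comparison", "data.frame")
  out
}

.time_formula <- function(covariates, keep, dat) {
  if (!is.null(covariates)) {
    cov2 <- covariates[keep, , drop = FALSE]
    dat <- cbind(dat, cov2)
    rhs <- paste(c(".group", colnames(cov2)), collapse = " + ")
  } else {
    rhs <- ".group"
  }
  list(formula = stats::as.formula(
    paste("survival::Surv(.time, .event) ~", rhs)), data = dat)
}

#' Join scores, admixture and clinical records into a cohort table
#'
#' @param scores data.frame with `case_id`/`slide_id`, `iluma_pct`, `call`.
#' @param admixture An `admixture_profile` (or true admixture) data.frame.
#' @param clinical Clinical data.frame keyed by `case_id`.
#' @return data.frame of class `cohort_table` with a `quartile` column
#'   (Q1 = most admixed) added.
#' @export
cohort_table <- function(scores, admixture, clinical) {
  if (!"case_id" %in% names(scores)) {
    names(scores)[names(scores) == "slide_id"] <- "case_id"
  }
  out <- merge(scores, admixture, by = "case_id")
  out <- merge(out, as.data.frame(unclass(clinical)), by = "case_id")
  vaf <- attr(clinical, "vaf")
  if (!is.null(vaf)) {
    out$math <- vapply(out$case_id, function(id) math_score(vaf[[id]]),
                       numeric(1))
  }
  out$quartile <- assign_quartiles(out$iluma_pct)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Feature-by-quartile association table
#'
#' For each feature: per-quartile mean (continuous) or percentage
#' (binary), the Q1-vs-Q4 two-sided p-value (t or chi-squared) and the
#' ordinal linear-trend p-value.
#'
#' @param cohort A [cohort_table()].
#' @param features Named character vector mapping feature column names to
#'   `"binary"` or `"continuous"`.
#' @return data.frame, one row per feature.
#' @export
quartile_association <- function(cohort,
                                 features = c(age = "continuous",
                                              er_pos = "binary",
                                              pr_pos = "binary",
                                              her2_pos = "binary",
                                              node_pos = "binary",
                                              size_gt20 = "binary",
                                              stage_gt1 = "binary",
                                              grade3 = "binary",
                                              math = "continuous")) {
  features <- features[names(features) %in% names(cohort)]
  rows <- lapply(names(features), function(f) {
    v <- cohort[[f]]
    typ <- features[[f]]
    by_q <- tapply(v, cohort$quartile, function(x) mean(x, na.rm = TRUE))
    if (typ == "binary") by_q <- 100 * by_q
    # heavy ties can empty a quartile or degenerate a test; report NA then
    tst <- tryCatch(q1_vs_q4_test(v, cohort$quartile, typ),
                    error = function(e) list(p_value = NA_real_))
    tr <- tryCatch(trend_test(v, cohort$quartile),
                   error = function(e) list(p_value = NA_real_))
    data.frame(feature = f, type = typ,
               Q1 = by_q[["Q1"]], Q2 = by_q[["Q2"]],
               Q3 = by_q[["Q3"]], Q4 = by_q[["Q4"]],
               p_q1_vs_q4 = tst$p_value, p_trend = tr$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pure-vs-admixed survival table across follow-up strata
#'
#' Cox hazard ratios (admixed vs pure) with 95% CI and log-rank p for the
#' entire follow-up, the first 3 years, and beyond 3 years (landmark).
#'
#' @param cohort A [cohort_table()] with `survival_time`, `event`, `call`.
#' @param covariates Optional covariate column names for the adjusted
#'   models.
#' @return data.frame of `survival_comparison` rows.
#' @export
survival_table <- function(cohort, covariates = NULL) {
  grp <- factor(cohort$call, levels = c("pure", "admixed"))
  cov <- if (!is.null(covariates)) cohort[, covariates, drop = FALSE]
  rows <- lapply(c("entire", "0-3y", ">3y"), function(s) {
    tryCatch(cox_hr(cohort$survival_time, cohort$event, grp, cov, s),
             error = function(e) {
               data.frame(stratum = s, hazard_ratio = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          logrank_p = NA_real_, n = NA_integer_,
                          n_events = NA_integer_)
             })
  })
  do.call(rbind, rows)
}
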