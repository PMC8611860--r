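## Survival screening (median split, Kaplan-Meier, log-rank), cohort
## summarization, 2^-ddCt relative quantification, ANOVA + Dunnett.

#' Split subjects into high/low expression groups
#'
#' Subjects strictly above the cutpoint (default: the median) are `"high"`,
#' the rest `"low"` (ties go low). A constant vector cannot be split and is
#' an error.
#'
#' @param x numeric expression vector, length >= 2.
#' @param cutpoint split value; defaults to `median(x)`.
#' @return character vector of `"high"`/`"low"` labels along `x`.
#' @export
median_split <- function(x, cutpoint = stats::median(x)) {
  stop_if(length(x) < 2L || anyNA(x), "need >= 2 non-missing values")
  g <- ifelse(x > cutpoint, "high", "low")
  stop_if(length(unique(g)) < 2L, "cannot split: all subjects fall on one side of the cutpoint")
  g
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring;
#' censored subjects leave the risk set without producing a step.
#'
#' @param records data.frame with `time` (>= 0) and `event` (logical).
#' @return data.frame with `time` (ascending event times), `n_risk`,
#'   `n_event`, `surv`.
#' @export
km_estimate <- function(records) {
  stop_if(nrow(records) < 1L, "need at least one record")
  stop_if(any(records$time < 0), "negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic with 1 degree of
#' freedom.
#'
#' @param records data.frame with `time`, `event` and a two-level `group`.
#' @return list with `chi2` and `p_value` (two-sided).
#' @export
logrank_test <- function(records) {
  stop_if(length(unique(records$group)) != 2L, "need exactly two groups")
  stop_if(any(table(records$group) < 1L), "each group needs at least one subject")
  stop_if(sum(records$event) < 1L, "no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  list(chi2 = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cohort summary table
#'
#' Per clinical variable, the count and percentage of each category.
#' Percentages are `100 * count / total` rounded half away from zero to one
#' decimal, the convention of published clinicopathological tables.
#'
#' @param clinical data.frame with `subject_id` plus categorical columns,
#'   or a named list of named count vectors (category -> count).
#' @param total cohort size; defaults to the number of rows / the sum of
#'   counts per variable.
#' @return data.frame with `variable`, `category`, `count`, `percent`.
#' @export
cohort_summary <- function(clinical, total = NULL) {
  if (is.data.frame(clinical)) {
    vars <- setdiff(names(clinical), "subject_id")
    counts <- lapply(clinical[vars], function(v) table(v))
    names(counts) <- vars
    if (is.null(total)) total <- nrow(clinical)
  } else {
    counts <- lapply(clinical, function(v) {
      stop_if(any(v < 0), "negative counts")
      v
    })
    if (is.null(total)) total <- max(vapply(counts, sum, numeric(1)))
  }
  stop_if(total <= 0, "total must be positive")
  rows <- lapply(names(counts), function(v) {
    ct <- counts[[v]]
    data.frame(variable = v, category = names(ct), count = as.integer(ct),
               percent = round_half_up(100 * as.numeric(ct) / total, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Relative quantification of a target against a reference gene and a
#' calibrator sample: `fold = 2^-((Ct_target,s - Ct_ref,s) -
#' (Ct_target,c - Ct_ref,c))`.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample of
#'   interest for the target and the reference gene (e.g. beta-actin).
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator sample.
#' @return linear fold change(s).
#' @export
#' @examples
#' ddct_relative_expression(26, 20, 25, 20) # ddCt = 1 -> 0.5
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator, ct_ref_calibrator)
  stop_if(any(!is.finite(cts)), "all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) - (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Fits a one-way ANOVA and compares every group against the control with
#' Dunnett's single-step procedure (multivariate t adjustment on the
#' pooled error variance, via multcomp).
#'
#' @param values numeric response vector.
#' @param groups group labels along `values`; every group needs `n >= 2`.
#' @param control control group label.
#' @return list with `f_statistic`, `f_p_value` and `comparisons`
#'   (data.frame: `group`, `estimate`, `p_adjusted`).
#' @export
anova_dunnett <- function(values, groups, control) {
  groups <- as.character(groups)
  stop_if(!control %in% groups, "control label '%s' absent from groups", control)
  tab <- table(groups)
  stop_if(length(tab) < 2L, "need at least two groups")
  stop_if(any(tab < 2L), "every group needs at least 2 observations")
  g <- stats::relevel(factor(groups), ref = control)
  dat <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(glht_fit)
  comparisons <- data.frame(
    group = sub(" - .*$", "", names(sm$test$coefficients)),
    estimate = unname(sm$test$coefficients),
    p_adjusted = unname(as.numeric(sm$test$pvalues)),
    stringsAsFactors = FALSE)
  list(f_statistic = an[["F value"]][1], f_p_value = an[["Pr(>F)"]][1],
       comparisons = comparisons)
}
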