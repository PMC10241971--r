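new_prop_est <- function(x, n, low, high, level, method) {
  est <- x / n
  stopifnot(low >= 0, high <= 1, low <= est + 1e-12, high >= est - 1e-12)
  structure(list(x = as.integer(x), n = as.integer(n), estimate = est,
                 conf.low = low, conf.high = high, level = level,
                 method = method), class = "prop_est")
}

na_prop_est <- function(level) {
  structure(list(x = NA_integer_, n = NA_integer_, estimate = NA_real_,
                 conf.low = NA_real_, conf.high = NA_real_, level = level,
                 method = "not estimable"), class = "prop_est")
}

#' @export
print.prop_est <- function(x, digits = 2, ...) {
  cat(sprintf("%s: %.*f%% (%g%% CI, %.*f-%.*f) [%d/%d]\n", x$method,
              digits, 100 * x$estimate, 100 * x$level,
              digits, 100 * x$conf.low, digits, 100 * x$conf.high,
              x$x, x$n))
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles: the lower bound is the
#' alpha/2 quantile of Beta(x, n - x + 1) (0 when x = 0) and the upper
#' bound the 1 - alpha/2 quantile of Beta(x + 1, n - x) (1 when x = n).
#'
#' @param x number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level, default 0.95.
#' @return object of class `prop_est` with fields `x`, `n`, `estimate`,
#'   `conf.low`, `conf.high`, `level`.
#' @examples
#' clopper_pearson(21, 22)   # 95.5% (77.2-99.9)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, n >= 1, x >= 0, x <= n,
            level > 0, level < 1)
  alpha <- 1 - level
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  new_prop_est(x, n, low, high, level, "Clopper-Pearson exact")
}

#' Standard-logit confidence intervals for predictive values
#'
#' Delta-method intervals on the log-odds of PPV and NPV, combining the
#' binomial variability of sensitivity over the diseased stratum (n1 = tp +
#' fn) and of specificity over the nondiseased stratum (n0 = fp + tn).
#' With Se = tp/n1, Sp = tn/n0 and prevalence rho = n1/(n1+n0):
#'
#' \deqn{logit(PPV) = \ln\frac{\rho Se}{(1-\rho)(1-Sp)}, \quad
#'       Var = \frac{1-Se}{Se\,n_1} + \frac{Sp}{(1-Sp)\,n_0}}
#' \deqn{logit(NPV) = \ln\frac{(1-\rho) Sp}{\rho (1-Se)}, \quad
#'       Var = \frac{Se}{(1-Se)\,n_1} + \frac{1-Sp}{Sp\,n_0}}
#'
#' and the interval is the inverse logit of the estimate plus/minus z times
#' the standard error.  When rho is the sample prevalence the point
#' estimates reduce to tp/(tp+fp) and tn/(tn+fn).
#'
#' @param tp,fp,fn,tn 2x2 counts.
#' @param level confidence level, default 0.95 (z is the exact normal
#'   quantile).
#' @return list with `ppv` and `npv`, each a `prop_est`.
#' @examples
#' predictive_value_logit_ci(19, 351, 2, 4376)
#' @export
predictive_value_logit_ci <- function(tp, fp, fn, tn, level = 0.95) {
  n1 <- tp + fn
  n0 <- fp + tn
  stopifnot(tp + fp >= 1, tn + fn >= 1, n1 >= 1, n0 >= 1)
  se <- tp / n1
  sp <- tn / n0
  if (se <= 0 || se >= 1 || sp <= 0 || sp >= 1) {
    stop("degenerate table (sensitivity or specificity of 0 or 1): the ",
         "logit variance is infinite; use an exact interval instead")
  }
  rho <- n1 / (n1 + n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  inv_logit <- function(x) 1 / (1 + exp(-x))
  lp <- log(rho * se / ((1 - rho) * (1 - sp)))
  vp <- (1 - se) / (se * n1) + sp / ((1 - sp) * n0)
  ln <- log((1 - rho) * sp / (rho * (1 - se)))
  vn <- se / ((1 - se) * n1) + (1 - sp) / (sp * n0)
  ppv <- new_prop_est(tp, tp + fp, inv_logit(lp - z * sqrt(vp)),
                      inv_logit(lp + z * sqrt(vp)), level, "standard logit")
  npv <- new_prop_est(tn, tn + fn, inv_logit(ln - z * sqrt(vn)),
                      inv_logit(ln + z * sqrt(vn)), level, "standard logit")
  list(ppv = ppv, npv = npv)
}

#' Diagnostic accuracy measures with confidence intervals
#'
#' Sensitivity, specificity and prevalence with exact Clopper-Pearson
#' intervals; PPV and NPV with standard-logit intervals (see
#' [predictive_value_logit_ci()]).
#'
#' @param cm a `confusion_matrix`.
#' @param level confidence level, default 0.95.
#' @return object of class `accuracy_measures`: list with `sensitivity`,
#'   `specificity`, `prevalence`, `ppv`, `npv` (`prop_est` objects) and
#'   integers `n1`, `n0`, `n_analyzed`.
#' @examples
#' accuracy_measures(confusion_matrix(19, 351, 2, 4376))
#' @export
accuracy_measures <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n1 <- cm$tp + cm$fn
  n0 <- cm$fp + cm$tn
  if (n1 < 1 || n0 < 1) {
    stop("need at least one diseased (tp+fn) and one nondiseased (fp+tn) case")
  }
  # the logit predictive-value interval is degenerate when Se or Sp is 0 or
  # 1; sensitivity/specificity/prevalence keep their exact intervals and the
  # predictive values are reported as NA in that case
  pv <- tryCatch(predictive_value_logit_ci(cm$tp, cm$fp, cm$fn, cm$tn, level),
                 error = function(e) list(ppv = na_prop_est(level),
                                          npv = na_prop_est(level)))
  structure(list(sensitivity = clopper_pearson(cm$tp, n1, level),
                 specificity = clopper_pearson(cm$tn, n0, level),
                 prevalence = clopper_pearson(n1, n1 + n0, level),
                 ppv = pv$ppv, npv = pv$npv,
                 n1 = n1, n0 = n0, n_analyzed = cm$n_conclusive),
            class = "accuracy_measures")
}

#' @export
print.accuracy_measures <- function(x, ...) {
  cat("diagnostic accuracy (n analyzed = ", x$n_analyzed,
      ", diseased n1 = ", x$n1, ", nondiseased n0 = ", x$n0, ")\n", sep = "")
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "prevalence")) {
    cat(format(nm, width = 12))
    print(x[[nm]])
  }
  invisible(x)
}

#' Management-plan accuracy
#'
#' The percentage of histopathology-confirmed melanomas that were managed
#' correctly, with an exact Clopper-Pearson interval.  `INCONCLUSIVE`
#' labels (1-month checkups) drop out of the denominator.
#'
#' @param labels character vector of management labels (see
#'   [classify_management()]).
#' @param level confidence level, default 0.95.
#' @return a `prop_est`.
#' @examples
#' management_accuracy(c(rep("CORRECT", 21), "INCORRECT"))
#' @export
management_accuracy <- function(labels, level = 0.95) {
  bad <- setdiff(labels, c("CORRECT", "INCORRECT", "INCONCLUSIVE"))
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  x <- sum(labels == "CORRECT")
  n <- x + sum(labels == "INCORRECT")
  if (n == 0L) {
    stop("no conclusive management labels (all were INCONCLUSIVE or none given)")
  }
  clopper_pearson(x, n, level)
}

#' Test yield
#'
#' Conclusive analyzable cases as a fraction of all cases minus invalid
#' cases and minus invalid-inconclusive results (valid-inconclusive tests
#' remain in the denominator).
#'
#' @param n_total all cases retrieved.
#' @param n_invalid cases rejected for missing/invalid data before matching.
#' @param n_invalid_inconclusive cases with unusable images.
#' @param n_analyzed conclusive cases entering the 2x2 table.
#' @return fraction in `[0, 1]`.
#' @examples
#' test_yield(5389, 172, 91, 4748)   # 0.926
#' @export
test_yield <- function(n_total, n_invalid, n_invalid_inconclusive, n_analyzed) {
  denom <- n_total - n_invalid - n_invalid_inconclusive
  if (denom <= 0) stop("non-positive yield denominator")
  n_analyzed / denom
}

#' Buderer sample size for a diagnostic accuracy study
#'
#' Minimum number of cases so that the binomial confidence interval for
#' sensitivity (and specificity) attains a maximum half-width `W`, the
#' binomial requirement being inflated by the inverse of prevalence (for
#' sensitivity) or of one minus prevalence (for specificity):
#'
#' \deqn{n_{Se} = \lceil z^2 Se(1-Se) / (W^2 \rho) \rceil, \quad
#'       n_{Sp} = \lceil z^2 Sp(1-Sp) / (W^2 (1-\rho)) \rceil}
#'
#' The required size is the larger of the two.
#'
#' @param se,sp assumed sensitivity and specificity, in (0, 1).
#' @param prevalence assumed disease prevalence, in (0, 1).
#' @param width maximum CI half-width `W` as a fraction (e.g. 0.10 for ten
#'   percentage points).
#' @param level confidence level, default 0.95.
#' @param z normal quantile; defaults to the exact quantile for `level`,
#'   override with 1.96 to match hand calculations.
#' @return list with `n_required`, `driver` (`"SENSITIVITY"` or
#'   `"SPECIFICITY"`), `n_se`, `n_sp`.
#' @examples
#' buderer_sample_size(0.83, 0.92, 0.0185, 0.10, z = 1.96)  # 2930 cases
#' @export
buderer_sample_size <- function(se, sp, prevalence, width, level = 0.95,
                                z = NULL) {
  stopifnot(se > 0, se < 1, sp > 0, sp < 1, width > 0)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be strictly inside (0, 1)")
  }
  if (is.null(z)) z <- stats::qnorm(1 - (1 - level) / 2)
  n_se <- ceiling(z^2 * se * (1 - se) / (width^2 * prevalence))
  n_sp <- ceiling(z^2 * sp * (1 - sp) / (width^2 * (1 - prevalence)))
  list(n_required = max(n_se, n_sp),
       driver = if (n_se >= n_sp) "SENSITIVITY" else "SPECIFICITY",
       n_se = n_se, n_sp = n_sp)
}
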