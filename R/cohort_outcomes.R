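#' Classify myeloid cells into C5aR1hi / CD86hi / other
#'
#' Precedence: a cell expressing the complement receptor C5AR1 is `C5aR1hi`;
#' otherwise a cell with high CD86 and no expression of C5AR1, CD163 or MRC1
#' is `CD86hi`; every other cell is `other`. "High" CD86 defaults to the top
#' 25% of CD86-expressing cells (gene-level threshold); mode `"detected"`
#' requires only CD86 > 0.
#'
#' @param values cell-by-gene expression matrix containing the four genes.
#' @param patients optional per-cell patient ids; when given, per-patient
#'   class counts are returned too.
#' @param genes named character vector locating the marker genes.
#' @param high_mode `"top25_expressing"` or `"detected"`.
#' @return list with `cell_class` (character per cell) and `counts`
#'   (patient-level data.frame with `c5ar1_hi`, `cd86_hi`, `other`), the
#'   latter `NULL` when `patients` is missing.
#' @export
classify_myeloid <- function(values, patients = NULL,
                             genes = c(c5ar1 = "C5AR1", cd86 = "CD86",
                                       cd163 = "CD163", mrc1 = "MRC1"),
                             high_mode = c("top25_expressing", "detected")) {
  high_mode <- match.arg(high_mode)
  missing <- setdiff(genes, colnames(values))
  if (length(missing))
    stop("required gene(s) missing: ", paste(missing, collapse = ", "))
  c5 <- as.numeric(values[, genes[["c5ar1"]]])
  cd86 <- as.numeric(values[, genes[["cd86"]]])
  cd163 <- as.numeric(values[, genes[["cd163"]]])
  mrc1 <- as.numeric(values[, genes[["mrc1"]]])
  cd86_high <- if (high_mode == "detected") cd86 > 0 else {
    expressing <- cd86[cd86 > 0]
    if (length(expressing) == 0) rep(FALSE, length(cd86)) else
      cd86 >= stats::quantile(expressing, 0.75, type = 7, names = FALSE) &
        cd86 > 0
  }
  cls <- ifelse(c5 > 0, "C5aR1hi",
                ifelse(cd86_high & cd163 == 0 & mrc1 == 0, "CD86hi", "other"))
  counts <- NULL
  if (!is.null(patients)) {
    tab <- table(patient = patients, class = factor(
      cls, levels = c("C5aR1hi", "CD86hi", "other")))
    counts <- data.frame(patient_id = rownames(tab),
                         c5ar1_hi = as.integer(tab[, "C5aR1hi"]),
                         cd86_hi = as.integer(tab[, "CD86hi"]),
                         other = as.integer(tab[, "other"]),
                         stringsAsFactors = FALSE)
  }
  list(cell_class = cls, counts = counts)
}

#' Pseudocounted C5aR1hi/CD86hi ratio
#'
#' @param c5ar1_hi,cd86_hi nonnegative class counts (vectorized).
#' @param pseudocount added to numerator and denominator (default 1, so a
#'   zero denominator stays finite).
#' @return numeric ratio(s).
#' @export
ratio_statistic <- function(c5ar1_hi, cd86_hi, pseudocount = 1) {
  if (any(c5ar1_hi < 0) || any(cd86_hi < 0)) stop("counts must be >= 0")
  (c5ar1_hi + pseudocount) / (cd86_hi + pseudocount)
}

#' Upper-quartile stratification of a cohort ratio
#'
#' Patients at or above the 75th percentile (linear-interpolation quantile)
#' of the ratio form the `high` group; ties at the cutoff go to `high`.
#' A cohort with all ratios equal degenerates to everyone `high` and is
#' flagged.
#'
#' @param ratios numeric vector (>= 4 patients).
#' @return factor with levels `high`, `rest`; attributes `cutoff`,
#'   `degenerate`.
#' @export
stratify_quartile <- function(ratios) {
  if (length(ratios) < 4) stop("at least 4 patients are required")
  cutoff <- stats::quantile(ratios, 0.75, type = 7, names = FALSE)
  grp <- factor(ifelse(ratios >= cutoff, "high", "rest"),
                levels = c("high", "rest"))
  attr(grp, "cutoff") <- cutoff
  attr(grp, "degenerate") <- length(unique(ratios)) == 1
  if (attr(grp, "degenerate"))
    warning("all ratios equal; every patient stratified 'high'")
  grp
}

#' ROC AUC with Mann-Whitney p-value
#'
#' AUC is the Mann-Whitney U statistic divided by `n1 * n2` (ties counted
#' one half); the two-sided p-value uses the tie-corrected normal
#' approximation of the Mann-Whitney test.
#'
#' @param score numeric predictor (higher predicts the positive class).
#' @param outcome logical or two-level factor; `TRUE` (or the second level)
#'   is the positive class.
#' @return list with `auc`, `p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(score, outcome) {
  if (is.factor(outcome) || is.character(outcome)) {
    f <- factor(outcome)
    if (nlevels(f) != 2) stop("outcome must have exactly two classes")
    outcome <- f == levels(f)[2]
  }
  n1 <- sum(outcome)
  n2 <- sum(!outcome)
  if (n1 == 0 || n2 == 0) stop("both outcome classes must be present")
  r <- rank(score, ties.method = "average")
  u <- sum(r[outcome]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  n <- n1 + n2
  ties <- table(score)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (u - n1 * n2 / 2) / sqrt(max(sigma2, .Machine$double.eps))
  list(auc = auc, p = 2 * stats::pnorm(-abs(z)), n_pos = n1, n_neg = n2)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank statistic (observed minus expected events over the event times,
#' hypergeometric variance), referred to a 1-df chi-square.
#'
#' @param time,event survival times (> 0) and 0/1 event indicators.
#' @param group two-level grouping.
#' @return list with `fit` (a `survfit` object), `chisq`, `p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (sum(event) < 1) stop("at least one event is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  list(fit = fit, chisq = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Breslow
#' tie handling; hazard ratio with a Wald 95% confidence interval from the
#' observed information. Monotone-likelihood (perfect separation) fits are
#' detected and flagged.
#'
#' @param time,event survival data (>= 2 events).
#' @param covariate numeric, non-constant.
#' @param conf_level confidence level for the interval.
#' @return list with `beta`, `se`, `hr`, `ci` (length-2), `p`, `flagged`.
#' @export
cox_univariate <- function(time, event, covariate, conf_level = 0.95) {
  if (sum(event) < 2) stop("at least two events are required")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  flagged <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se)
  if (flagged)
    warning("monotone likelihood suspected (perfect separation?)")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(beta = beta, se = se, hr = exp(beta),
       ci = exp(c(beta - zq * se, beta + zq * se)),
       p = unname(summary(fit)$coefficients[, "Pr(>|z|)"]),
       flagged = flagged)
}
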