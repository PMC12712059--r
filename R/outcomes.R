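# Survival stratification and phenotype-covariate association. The
# maximally selected log-rank cutpoint scan is implemented here; standard
# estimators delegate to survival:: and stats::.

#' Kaplan-Meier product-limit estimate
#'
#' @param time nonnegative event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame of class `"km_estimate"` with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`; starts at time 0 with
#'   survival 1 and is a non-increasing right-continuous step function.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record", call. = FALSE)
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    survival = c(1, fit$surv))
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", max(x$n_risk), "subjects,",
      sum(x$n_event), "events\n")
  print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Log-rank test between groups
#'
#' Standard unweighted log-rank chi-square with g - 1 degrees of freedom.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 groups, >= 1 event overall).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (sum(event) < 1L) stop("need at least 1 event", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

# standardized two-group log-rank statistic (O - E)/sqrt(V) for the
# "low" group, from the hypergeometric mean/variance at each distinct
# event time; used by the cutpoint scan
logrank_z <- function(time, event, in_low) {
  dt <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_low)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_low)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o - e) / sqrt(v)
}

#' Optimal survival cutpoint (maximally selected log-rank statistic)
#'
#' Candidate cutpoints are the midpoints of consecutive distinct values
#' of `x` lying strictly inside the (`minprop`, 1 - `minprop`) quantile
#' window. For each candidate the standardized two-group log-rank
#' statistic between the resulting low (x <= cut) and high groups is
#' computed; the cutpoint maximising its absolute value is returned
#' (ties: smaller cutpoint). The high-score group is the reference for
#' downstream contrasts.
#'
#' @param time,event survival data.
#' @param x continuous variable to dichotomise.
#' @param minprop minimum proportion of samples on each side (default
#'   0.1).
#' @param variable name recorded on the result.
#' @return object of class `"cutpoint_result"` with `cutpoint`,
#'   `statistic` (absolute standardized log-rank), `z` (signed, low
#'   group), `group` (factor high/low, high = reference level),
#'   `minprop`, `n_candidates`.
#' @export
optimal_cutpoint <- function(time, event, x, minprop = 0.1, variable = "x") {
  stopifnot(length(time) == length(x))
  q <- stats::quantile(x, c(minprop, 1 - minprop), names = FALSE)
  v <- sort(unique(x))
  if (length(v) < 2L) stop("no admissible cutpoint candidates: constant variable",
                           call. = FALSE)
  mids <- (v[-1] + v[-length(v)]) / 2
  mids <- mids[mids > q[1] & mids < q[2]]
  if (length(mids) == 0L) stop("no admissible cutpoint candidates inside the minprop window",
                               call. = FALSE)
  zs <- vapply(mids, function(m) logrank_z(time, event, x <= m), numeric(1))
  best <- which.max(abs(zs))  # ties: which.max takes the first = smaller cutpoint
  grp <- factor(ifelse(x <= mids[best], "low", "high"), levels = c("high", "low"))
  structure(list(variable = variable, cutpoint = mids[best],
                 statistic = abs(zs[best]), z = zs[best], group = grp,
                 minprop = minprop, n_candidates = length(mids),
                 time = time, event = event),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Optimal cutpoint for %s: %.4g (|standardized log-rank| = %.3f, %d candidates, minprop %.2f)\n",
              x$variable, x$cutpoint, x$statistic, x$n_candidates, x$minprop))
  print(table(x$group))
  invisible(x)
}

#' @export
plot.cutpoint_result <- function(x, ...) {
  fit <- survival::survfit(survival::Surv(x$time, x$event) ~ x$group)
  graphics::plot(fit, col = c(1, 2), xlab = "time", ylab = "survival",
                 main = paste("KM by", x$variable, "cutpoint"), ...)
  graphics::legend("topright", legend = levels(x$group), col = c(1, 2), lty = 1)
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling and Wald confidence
#' intervals. Non-convergence or apparent separation is flagged on the
#' result rather than raised.
#'
#' @param time,event survival data.
#' @param covariates data.frame of covariates (numeric or factor).
#' @param conf_level Wald CI level.
#' @return data.frame with `term`, `coef`, `hr`, `ci_low`, `ci_high`,
#'   `p_value`; attributes `converged` and `flagged`.
#' @export
cox_fit <- function(time, event, covariates, conf_level = 0.95) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const)) stop("constant covariate(s): ",
                       paste(names(covariates)[const], collapse = ", "), call. = FALSE)
  if (sum(event) < ncol(covariates) + 1L) {
    stop("need more events than covariates", call. = FALSE)
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit, conf.int = conf_level)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(term = names(beta), coef = unname(beta),
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * se),
                    ci_high = exp(unname(beta) + z * se),
                    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    row.names = NULL)
  if (any(abs(beta) > 15)) flagged <- TRUE
  attr(out, "converged") <- is.null(fit$info) || fit$iter < fit$control$iter.max
  attr(out, "flagged") <- flagged
  out
}

#' Chi-square association test
#'
#' Pearson chi-square on a contingency table; Yates continuity
#' correction is applied for 2x2 tables only.
#'
#' @param tab 2-dimensional table or matrix of counts.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_association <- function(tab) {
  tab <- as.matrix(tab)
  if (length(dim(tab)) != 2L) stop("need a 2-dimensional table", call. = FALSE)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) stop("zero expected count", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Classical one-way ANOVA
#'
#' @param values numeric response.
#' @param group group labels (>= 2 groups with >= 2 values each).
#' @return list with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L)) stop("need >= 2 values per group", call. = FALSE)
  wss <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  if (wss == 0) stop("zero within-group variance in all groups", call. = FALSE)
  res <- stats::oneway.test(values ~ group, var.equal = TRUE)
  list(statistic = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p_value = res$p.value)
}

#' Pairwise Wilcoxon rank-sum tests with BH adjustment
#'
#' Rank-sum test per group pair: exact enumeration when both sides have
#' n <= 8 and there are no ties, normal approximation with tie
#' correction otherwise. P values are Benjamini-Hochberg adjusted across
#' the family of comparisons.
#'
#' @param values numeric response.
#' @param group group labels.
#' @param pairs optional list of length-2 character vectors naming the
#'   comparisons (default: all pairs).
#' @param paired paired test (requires equal group sizes in order).
#' @return data.frame with `term`, `statistic` (W), `p_value`,
#'   `p_adjusted`.
#' @export
wilcoxon_bh <- function(values, group, pairs = NULL, paired = FALSE) {
  group <- as.character(group)
  levels <- unique(group)
  if (is.null(pairs)) {
    pairs <- utils::combn(levels, 2L, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    a <- values[group == pr[1]]
    b <- values[group == pr[2]]
    if (length(a) < 2L || length(b) < 2L) stop("empty or singleton group: ",
                                               paste(pr, collapse = " vs "), call. = FALSE)
    use_exact <- length(a) <= 8L && length(b) <= 8L &&
      !anyDuplicated(c(a, b)) && !paired
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = use_exact, paired = paired,
                         correct = !use_exact))
    data.frame(term = paste(pr[1], "vs", pr[2]),
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' One-vs-rest logistic regression of phenotype on clinical covariates
#'
#' One binary logistic model per phenotype (this phenotype vs all
#' others) on the categorical covariates, with fixed reference levels
#' (European ancestry, age <40, stage I, LumA). Odds ratios with Wald
#' confidence intervals; apparent separation flags the affected model
#' instead of raising.
#'
#' @param annotation clinical data.frame with the covariate columns.
#' @param labels phenotype label per row of `annotation`.
#' @param covariates covariate column names to include (present columns
#'   only are used).
#' @param reference named list of reference levels.
#' @param conf_level Wald CI level.
#' @return data.frame with `phenotype`, `term`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `flagged`. Reference-level rows are absent.
#' @export
logistic_ovr <- function(annotation, labels,
                         covariates = c("ancestry", "age_group", "stage", "pam50"),
                         reference = list(ancestry = "European", age_group = "<40",
                                          stage = "I", pam50 = "LumA"),
                         conf_level = 0.95) {
  covariates <- intersect(covariates, names(annotation))
  if (length(covariates) == 0L) stop("no covariate columns found", call. = FALSE)
  dat <- annotation[, covariates, drop = FALSE]
  for (col in covariates) {
    f <- factor(dat[[col]])
    ref <- reference[[col]]
    if (!is.null(ref) && ref %in% levels(f)) f <- stats::relevel(f, ref)
    dat[[col]] <- f
  }
  keep <- stats::complete.cases(dat) & !is.na(labels)
  dat <- dat[keep, , drop = FALSE]
  labs <- labels[keep]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- lapply(unique(labs), function(ph) {
    y <- as.integer(labs == ph)
    flagged <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = cbind(data.frame(y = y), dat), family = stats::binomial()),
      warning = function(w) { flagged <<- TRUE; invokeRestart("muffleWarning") })
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    ok <- names(beta) != "(Intercept)"
    if (!fit$converged || any(abs(beta[ok]) > 15)) flagged <- TRUE
    data.frame(phenotype = ph, term = names(beta)[ok],
               or = exp(unname(beta[ok])),
               ci_low = exp(unname(beta[ok]) - z * se[ok]),
               ci_high = exp(unname(beta[ok]) + z * se[ok]),
               p_value = 2 * stats::pnorm(-abs(unname(beta[ok] / se[ok]))),
               flagged = flagged, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Stratified balanced subsampling
#'
#' Subsamples without replacement so every stratum is reduced to the
#' size of the smallest stratum; a simple balanced-design stand-in for
#' cardinality matching. Deterministic given `seed`.
#'
#' @param annotation data.frame with a `sample_id` column.
#' @param strata_keys column names defining the strata.
#' @param seed integer seed.
#' @return character vector of retained sample ids.
#' @export
stratified_balance <- function(annotation, strata_keys, seed = 1L) {
  key <- interaction(annotation[, strata_keys, drop = FALSE], drop = TRUE)
  sizes <- table(key)
  if (any(sizes == 0L)) stop("empty stratum", call. = FALSE)
  m <- min(sizes)
  with_seed(seed, {
    unlist(lapply(levels(key), function(lv) {
      ids <- annotation$sample_id[key == lv]
      if (length(ids) == m) ids else sample(ids, m)
    }), use.names = FALSE)
  })
}
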