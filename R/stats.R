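#' Average manual sTIL scores over tumor blocks
#'
#' Manual scoring uses slides from up to two tumor blocks when available;
#' the patient-level score is the arithmetic mean of the non-missing block
#' scores, or the single score when only one block exists. No score at all
#' yields `NA`.
#'
#' @param block_scores Data frame / tibble (or numeric matrix) with one row
#'   per patient and one column per block, percent units.
#' @return Numeric vector of combined percentages, `NA` where no block was
#'   scored.
#' @examples
#' combine_block_scores(data.frame(b1 = c(20, 15, NA), b2 = c(30, NA, NA)))
#' @export
combine_block_scores <- function(block_scores) {
  m <- as.matrix(as.data.frame(block_scores))
  if (!is.numeric(m)) stop("block scores must be numeric", call. = FALSE)
  out <- rowMeans(m, na.rm = TRUE)
  out[!rowSums(is.finite(m))] <- NA_real_
  unname(out)
}

#' Dichotomize a biomarker at a cutpoint
#'
#' Manual sTIL status uses the guideline rule "high when strictly greater
#' than 10 percent"; automated sTIL density uses "high when greater than or
#' equal to the selected cutpoint". The boundary rule is recorded on the
#' output because the two conventions differ at the cutpoint itself.
#'
#' @param values Numeric biomarker values.
#' @param cutpoint Cut value.
#' @param rule `"strictly_greater"` (manual) or `"geq"` (density).
#' @return Factor with levels `low`, `high` (NA preserved); attributes
#'   `cutpoint`, `rule`.
#' @export
dichotomize <- function(values, cutpoint,
                        rule = c("strictly_greater", "geq")) {
  rule <- match.arg(rule)
  high <- if (rule == "strictly_greater") values > cutpoint else
    values >= cutpoint
  out <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  attr(out, "cutpoint") <- cutpoint
  attr(out, "rule") <- rule
  out
}

#' Derive the standard clinical covariate codings
#'
#' Adds the dichotomous / grouped codings used in the survival models:
#' age at 50 years, tumor size at 2 cm, nodal status 0 / 1-3 / >=4, tumor
#' type with ductal as reference.
#'
#' @param cohort Tibble with columns `age_years`, `tumor_size_cm`,
#'   `n_positive_nodes`, `tumor_type`.
#' @return The cohort with factor columns `age_group` (`<50`, `>=50`),
#'   `size_group` (`<=2cm`, `>2cm`), `nodal_group` (`0`, `1-3`, `>=4`),
#'   `type_group` (`ductal`, `lobular`, `other`).
#' @export
code_covariates <- function(cohort) {
  dplyr::mutate(
    tibble::as_tibble(cohort),
    age_group = factor(ifelse(.data$age_years >= 50, ">=50", "<50"),
                       levels = c("<50", ">=50")),
    size_group = factor(ifelse(.data$tumor_size_cm > 2, ">2cm", "<=2cm"),
                        levels = c("<=2cm", ">2cm")),
    nodal_group = factor(
      dplyr::case_when(.data$n_positive_nodes == 0 ~ "0",
                       .data$n_positive_nodes <= 3 ~ "1-3",
                       TRUE ~ ">=4"),
      levels = c("0", "1-3", ">=4")),
    type_group = factor(as.character(.data$tumor_type),
                        levels = c("ductal", "lobular", "other"))
  )
}

# ---- Kaplan-Meier ----------------------------------------------------------

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator with Greenwood standard errors and log-scale
#' confidence intervals (via [survival::survfit()]). Tied event times are
#' handled by simultaneous decrement of the risk set.
#'
#' @param times Follow-up times (days).
#' @param events Event indicators, 0 = censored, 1 = event.
#' @param conf_level Confidence level for the pointwise CIs.
#' @return A `stil_km` object; `tidy()` gives the step table, `glance()`
#'   the median survival and its CI.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(events %in% c(0, 1)), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.int = conf_level)
  structure(list(fit = fit, n = length(times), conf_level = conf_level),
            class = "stil_km")
}

#' @export
print.stil_km <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @rdname km_estimate
#' @param x A `stil_km` object.
#' @param ... Unused.
#' @export
tidy.stil_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble::tibble(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                 n_censor = s$n.censor, estimate = s$surv,
                 std_error = s$std.err, conf_low = s$lower,
                 conf_high = s$upper)
}

#' @rdname km_estimate
#' @export
glance.stil_km <- function(x, ...) {
  tab <- summary(x$fit)$table
  tibble::tibble(n = unname(tab["records"]),
                 events = unname(tab["events"]),
                 median = unname(tab["median"]),
                 median_conf_low = unname(tab["0.95LCL"]),
                 median_conf_high = unname(tab["0.95UCL"]))
}

# ---- log-rank --------------------------------------------------------------

#' Two-sample log-rank test with a signed standardized statistic
#'
#' Standard log-rank test: at each distinct event time the observed events
#' in group 2 are compared with their hypergeometric expectation given the
#' risk sets; the signed statistic is
#' `z = (O2 - E2) / sqrt(V)` and the two-sided p-value comes from
#' `z^2 ~ chi-square(1)`. The signed form is what the maximally selected
#' rank statistic scans over candidate cutpoints.
#'
#' @param times Follow-up times.
#' @param events Event indicators 0/1.
#' @param groups Two-level grouping (factor, character, or logical).
#' @return A tibble with `statistic` (signed z for the second group level),
#'   `chisq`, `p_value`, `n1`, `n2`, `observed2`, `expected2`.
#' @export
logrank_stat <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L || any(tabulate(g, 2L) == 0L)) {
    stop("log-rank test requires exactly 2 non-empty groups", call. = FALSE)
  }
  stopifnot(length(times) == length(events), length(times) == length(g),
            all(events %in% c(0, 1)))
  in2 <- g == levels(g)[2]
  o2 <- 0; e2 <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n2 <- sum(at_risk & in2)
    d <- sum(events == 1 & times == t)
    d2 <- sum(events == 1 & times == t & in2)
    o2 <- o2 + d2
    e2 <- e2 + d * n2 / n
    if (n > 1) {
      v <- v + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
    }
  }
  z <- if (v > 0) (o2 - e2) / sqrt(v) else 0
  tibble::tibble(statistic = z, chisq = z^2,
                 p_value = stats::pchisq(z^2, df = 1, lower.tail = FALSE),
                 n1 = sum(!in2), n2 = sum(in2),
                 observed2 = o2, expected2 = e2)
}

# ---- Cox proportional hazards ---------------------------------------------

#' Cox proportional-hazards fit with biomarker scaling
#'
#' Wraps [survival::coxph()] (Efron tie handling) and applies the reporting
#' scale used for the sTIL biomarkers: manual percentages are entered as
#' value/10 and automated densities as value/300, so hazard ratios read as
#' the effect of a 10-percentage-point or 300 cells/mm^2 increment.
#' Only complete cases enter the fit.
#'
#' @param data Tibble containing all referenced columns.
#' @param time_col,event_col Column names of the endpoint.
#' @param terms Character vector of covariate column names.
#' @param scaling Named numeric vector: divisor applied to each named term
#'   (e.g. `c(stil_density = 300, manual_stil_pct = 10)`).
#' @param conf_level Confidence level for the Wald intervals.
#' @param on_monotone `"error"` (default) aborts on a monotone partial
#'   likelihood (some coefficient diverging, e.g. perfect separation);
#'   `"warn"` keeps the fit, leaving the diverging term's interval
#'   unbounded -- useful for sparse nuisance factor levels in adjusted
#'   models where the biomarker term remains well behaved.
#' @return A `stil_cox` object; `tidy()` gives one row per model term with
#'   `HR`, `conf_low`, `conf_high`, `p_value`; `glance()` the model-level
#'   summary.
#' @export
cox_fit <- function(data, time_col, event_col, terms,
                    scaling = c(stil_density = 300, manual_stil_pct = 10),
                    conf_level = 0.95,
                    on_monotone = c("error", "warn")) {
  on_monotone <- match.arg(on_monotone)
  data <- tibble::as_tibble(data)
  stopifnot(all(c(time_col, event_col, terms) %in% names(data)))
  used <- data[, c(time_col, event_col, terms)]
  cc <- stats::complete.cases(used)
  used <- used[cc, , drop = FALSE]
  if (sum(used[[event_col]]) < 1) {
    stop("Cox fit needs at least one event among complete cases",
         call. = FALSE)
  }
  for (nm in intersect(names(scaling), terms)) {
    if (is.numeric(used[[nm]])) used[[nm]] <- used[[nm]] / scaling[[nm]]
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = used, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        if (on_monotone == "error") {
          stop("Cox partial likelihood did not converge (monotone ",
               "likelihood?): ", conditionMessage(w), call. = FALSE)
        }
      }
      invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, n_used = nrow(used),
                 n_dropped = sum(!cc), scaling = scaling,
                 conf_level = conf_level),
            class = "stil_cox")
}

#' @export
print.stil_cox <- function(x, ...) {
  cat(sprintf("<Cox PH fit> n = %d (%d dropped as incomplete)\n",
              x$n_used, x$n_dropped))
  print(tidy.stil_cox(x))
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `stil_cox` object.
#' @param ... Unused.
#' @export
tidy.stil_cox <- function(x, ...) {
  s <- summary(x$fit, conf.int = x$conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    HR = co[, "exp(coef)"],
    std_error = co[, "se(coef)"],
    conf_low = ci[, 3],
    conf_high = ci[, 4],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @rdname cox_fit
#' @export
glance.stil_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$n_used, n_dropped = x$n_dropped,
                 events = s$nevent,
                 logLik = as.numeric(stats::logLik(x$fit)),
                 lr_statistic = unname(s$logtest["test"]),
                 lr_p_value = unname(s$logtest["pvalue"]))
}

# ---- maximally selected rank statistics -----------------------------------

#' Cutpoint selection by maximally selected rank statistics
#'
#' Scans every candidate cutpoint `mu` whose low-group proportion lies
#' inside the quantile window and computes the signed standardized log-rank
#' statistic for the split `biomarker >= mu` versus `< mu`; the selected
#' cutpoint maximizes the absolute statistic. Because the maximum over many
#' correlated tests inflates the naive p-value, the adjusted p-value uses
#' the improved Bonferroni-type bound of Lausen, Sauerbrei and Schumacher:
#' with ordered candidate low-group sizes `m_1 < ... < m_k` out of `n`,
#' correlations between neighbouring statistics enter through
#' `t_i = sqrt(1 - m_i (n - m_{i+1}) / ((n - m_i) m_{i+1}))` and
#' `p_adj = 2 (1 - Phi(b)) + sum_i exp(-b^2/2) (t_i - (b^2/4 - 1) t_i^3 / 6) / pi`
#' evaluated at the observed maximum `b`. The bound is approximate (and
#' conservative for small `b`); an exact permutation p-value is available
#' with `p_method = "permutation"`.
#'
#' @param times Follow-up times.
#' @param events Event indicators 0/1.
#' @param biomarker Numeric biomarker (e.g. sTIL density, cells/mm^2).
#' @param quantile_window Candidate window as `c(eps, 1 - eps)` quantiles of
#'   the biomarker; default `c(0.1, 0.9)`.
#' @param p_method `"lausen"` (default, closed-form bound) or
#'   `"permutation"`.
#' @param n_perm Permutation count for `p_method = "permutation"`.
#' @param seed Seed for the permutation path.
#' @return A `stil_cutpoint` object; fields `cutpoint`, `statistic`
#'   (signed z at the maximum), `p_adjusted`, `p_method`, `window`
#'   (biomarker values at the window bounds), and `scan` (tibble of every
#'   candidate with its statistic). `tidy()` returns the scan table,
#'   `glance()` the selection summary.
#' @export
maxstat_cutpoint <- function(times, events, biomarker,
                             quantile_window = c(0.1, 0.9),
                             p_method = c("lausen", "permutation"),
                             n_perm = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  stopifnot(length(times) == length(events),
            length(times) == length(biomarker),
            all(events %in% c(0, 1)),
            length(quantile_window) == 2L,
            quantile_window[1] < quantile_window[2])
  ok <- is.finite(biomarker) & is.finite(times)
  times <- times[ok]; events <- events[ok]; biomarker <- biomarker[ok]
  n <- length(biomarker)
  lo <- stats::quantile(biomarker, quantile_window[1], names = FALSE)
  hi <- stats::quantile(biomarker, quantile_window[2], names = FALSE)
  cand <- sort(unique(biomarker))
  cand <- cand[cand > lo & cand <= hi]
  # each candidate mu splits {>= mu} vs {< mu}; need both groups non-empty
  cand <- cand[vapply(cand, function(mu) {
    any(biomarker >= mu) && any(biomarker < mu)
  }, logical(1))]
  if (length(cand) < 1L) {
    stop("need at least 2 distinct biomarker values inside the quantile ",
         "window to form a candidate cutpoint", call. = FALSE)
  }
  zs <- maxstat_scan(times, events, biomarker, cand)
  best <- which.max(abs(zs))
  b <- abs(zs[best])
  m_low <- vapply(cand, function(mu) sum(biomarker < mu), numeric(1))
  p_adj <- switch(p_method,
    lausen = p_lausen94(b, n, sort(unique(m_low))),
    permutation = {
      if (!is.null(seed)) set.seed(seed)
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        zp <- max(abs(maxstat_scan(times, events, sample(biomarker), cand)))
        if (zp >= b) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_perm + 1)
    })
  structure(list(
    cutpoint = cand[best],
    statistic = zs[best],
    max_abs_statistic = b,
    p_adjusted = p_adj,
    p_method = p_method,
    p_note = "approximate upper bound" ,
    window = c(low = lo, high = hi),
    quantile_window = quantile_window,
    n = n,
    scan = tibble::tibble(cutpoint = cand, statistic = zs,
                          n_low = as.integer(m_low))
  ), class = "stil_cutpoint")
}

# Signed standardized log-rank statistic for every candidate split
# {biomarker >= mu} vs {< mu} in one pass. Ordering subjects by decreasing
# biomarker makes each high group a prefix, so the per-event-time group-2
# risk and event counts for all candidates are row-wise cumulative sums of
# one E x n incidence matrix; the statistic then falls out of column sums.
# Agrees exactly with logrank_stat() (tested).
maxstat_scan <- function(times, events, biomarker, cand) {
  ord <- order(biomarker, decreasing = TRUE)
  tb <- times[ord]
  eb <- events[ord]
  ut <- sort(unique(times[events == 1]))
  if (length(ut) == 0L) return(rep(0, length(cand)))
  risk <- outer(ut, tb, "<=") * 1          # E x n, subject at risk at ut[e]
  evt <- outer(ut, tb, "==") * rep(eb, each = length(ut))
  n_t <- rowSums(risk)
  d_t <- rowSums(evt)
  N2 <- t(apply(risk, 1, cumsum))          # high group = first m columns
  D2 <- t(apply(evt, 1, cumsum))
  U <- colSums(D2 - d_t * N2 / n_t)
  vfac <- d_t * (n_t - d_t) / pmax(n_t - 1, 1) / n_t^2
  V <- colSums(vfac * N2 * (n_t - N2))
  z <- ifelse(V > 0, U / sqrt(V), 0)
  m_high <- vapply(cand, function(mu) sum(biomarker >= mu), integer(1))
  z[m_high]
}

# Improved Bonferroni-type bound for the maximum of absolute standardized
# log-rank statistics over ordered candidate splits (Lausen/Sauerbrei/
# Schumacher-style approximation). m: ordered distinct low-group sizes.
p_lausen94 <- function(b, n, m) {
  if (b <= 0) return(1)
  if (length(m) < 2L) {
    return(min(1, 2 * stats::pnorm(-b)))
  }
  m1 <- m[-length(m)]
  m2 <- m[-1]
  t <- sqrt(pmax(0, 1 - m1 * (n - m2) / ((n - m1) * m2)))
  D <- sum(exp(-b^2 / 2) * (t - (b^2 / 4 - 1) * t^3 / 6) / pi)
  min(1, max(0, 2 * (1 - stats::pnorm(b)) + D))
}

#' @export
print.stil_cutpoint <- function(x, ...) {
  cat(sprintf(
    "<maxstat cutpoint> %.6g (|z| = %.3f, adjusted p = %.4g [%s, %s])\n",
    x$cutpoint, x$max_abs_statistic, x$p_adjusted, x$p_method, x$p_note))
  invisible(x)
}

#' @rdname maxstat_cutpoint
#' @param x A `stil_cutpoint` object.
#' @param ... Unused.
#' @export
tidy.stil_cutpoint <- function(x, ...) x$scan

#' @rdname maxstat_cutpoint
#' @export
glance.stil_cutpoint <- function(x, ...) {
  tibble::tibble(cutpoint = x$cutpoint, statistic = x$statistic,
                 max_abs_statistic = x$max_abs_statistic,
                 p_adjusted = x$p_adjusted, p_method = x$p_method,
                 window_low = unname(x$window["low"]),
                 window_high = unname(x$window["high"]), n = x$n)
}

# ---- Spearman --------------------------------------------------------------

#' Pairwise Spearman rank correlations between readers
#'
#' Rank correlation with average ranks for ties; two-sided p-values via the
#' t approximation `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. A constant vector has no rank ordering, so its correlations are
#' reported as missing.
#'
#' @param count_matrix Numeric matrix or data frame, readers in columns and
#'   fields of view in rows (at least 3 complete rows per pair).
#' @return A list with `correlation` and `p_value` matrices (unit diagonal,
#'   symmetric) and a tidy tibble `pairs`.
#' @export
pairwise_spearman <- function(count_matrix) {
  m <- as.matrix(as.data.frame(count_matrix))
  k <- ncol(m)
  stopifnot(k >= 2L)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("reader", seq_len(k))
  corr <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pval <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(corr) <- 1
  diag(pval) <- 0
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(m[, c(i, j)])
      n <- sum(ok)
      if (n < 3L) {
        stop("need >= 3 paired observations for readers ", nm[i], " and ",
             nm[j], call. = FALSE)
      }
      xi <- m[ok, i]; xj <- m[ok, j]
      if (length(unique(xi)) < 2L || length(unique(xj)) < 2L) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(rank(xi), rank(xj))
        p <- if (abs(r) >= 1) 0 else {
          tstat <- r * sqrt((n - 2) / (1 - r^2))
          2 * stats::pt(-abs(tstat), df = n - 2)
        }
      }
      corr[i, j] <- corr[j, i] <- r
      pval[i, j] <- pval[j, i] <- p
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reader1 = nm[i], reader2 = nm[j], n = n, estimate = r, p_value = p)
    }
  }
  list(correlation = corr, p_value = pval,
       pairs = dplyr::bind_rows(rows))
}

# ---- concordance -----------------------------------------------------------

#' Concordance of automated vs manual sTIL classification
#'
#' Treats the manual high/low status as the reference:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) for the automated
#' call. Discrepant cases are listed, and those whose continuous scores lie
#' within configurable bands of both cutpoints are flagged as expected
#' borderline disagreement.
#'
#' @param manual_groups Reference factor/character vector (`high` =
#'   positive).
#' @param auto_groups Automated factor/character vector, same length.
#' @param ids Optional case identifiers (default index).
#' @param manual_scores,auto_scores Optional continuous scores for the
#'   borderline flags.
#' @param manual_cutpoint,auto_cutpoint Cutpoints the groups were derived
#'   from.
#' @param manual_band,auto_band Half-widths of the "near the cutpoint"
#'   bands (percent resp. cells/mm^2).
#' @return A `stil_concordance` list: `sensitivity`, `specificity`,
#'   `tp`, `fp`, `tn`, `fn`, `discrepant` (tibble with `near_both_cutpoints`
#'   flag when scores were supplied).
#' @export
concordance_report <- function(manual_groups, auto_groups, ids = NULL,
                               manual_scores = NULL, auto_scores = NULL,
                               manual_cutpoint = 10, auto_cutpoint = NULL,
                               manual_band = 10, auto_band = 200) {
  manual <- as.character(manual_groups)
  auto <- as.character(auto_groups)
  if (length(manual) != length(auto)) {
    stop("manual and automated group vectors differ in length",
         call. = FALSE)
  }
  stopifnot(all(manual %in% c("low", "high")), all(auto %in% c("low", "high")))
  if (is.null(ids)) ids <- seq_along(manual)
  tp <- sum(manual == "high" & auto == "high")
  fn <- sum(manual == "high" & auto == "low")
  tn <- sum(manual == "low" & auto == "low")
  fp <- sum(manual == "low" & auto == "high")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  disc_idx <- which(manual != auto)
  disc <- tibble::tibble(id = ids[disc_idx],
                         manual = manual[disc_idx],
                         auto = auto[disc_idx])
  if (!is.null(manual_scores) && !is.null(auto_scores) &&
      !is.null(auto_cutpoint)) {
    disc$manual_score <- manual_scores[disc_idx]
    disc$auto_score <- auto_scores[disc_idx]
    disc$near_both_cutpoints <-
      abs(disc$manual_score - manual_cutpoint) <= manual_band &
      abs(disc$auto_score - auto_cutpoint) <= auto_band
  }
  structure(list(sensitivity = sens, specificity = spec,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 discrepant = disc),
            class = "stil_concordance")
}

#' @export
print.stil_concordance <- function(x, ...) {
  cat(sprintf(
    "<concordance> sensitivity %.3f, specificity %.3f (TP %d, FP %d, TN %d, FN %d); %d discrepant\n",
    x$sensitivity, x$specificity, x$tp, x$fp, x$tn, x$fn,
    nrow(x$discrepant)))
  invisible(x)
}

#' @rdname concordance_report
#' @param x A `stil_concordance` object.
#' @param ... Unused.
#' @export
glance.stil_concordance <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                 tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 n_discrepant = nrow(x$discrepant))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
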