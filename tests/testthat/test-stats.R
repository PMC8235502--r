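test_that("block scores average available blocks and flag missing", {
  expect_equal(combine_block_scores(data.frame(b1 = 20, b2 = 30)), 25)
  expect_equal(combine_block_scores(data.frame(b1 = 15, b2 = NA)), 15)
  expect_true(is.na(combine_block_scores(data.frame(b1 = NA_real_,
                                                    b2 = NA_real_))))
  expect_equal(combine_block_scores(cbind(c(20, 15, NA), c(30, NA, NA))),
               c(25, 15, NA))
})

test_that("dichotomization respects the boundary rule", {
  manual <- dichotomize(c(9, 10, 10.5, 60), 10, "strictly_greater")
  expect_equal(as.character(manual), c("low", "low", "high", "high"))
  density <- dichotomize(c(469.9, 470, 471), 470, "geq")
  expect_equal(as.character(density), c("low", "high", "high"))
  expect_equal(attr(density, "rule"), "geq")
  empty <- dichotomize(numeric(), 10, "geq")
  expect_length(empty, 0)
})

test_that("covariate codings match the standard groupings", {
  coh <- code_covariates(tibble::tibble(
    age_years = c(49, 50, 80), tumor_size_cm = c(2, 2.1, 1),
    n_positive_nodes = c(0, 3, 4),
    tumor_type = c("ductal", "lobular", "other")))
  expect_equal(as.character(coh$age_group), c("<50", ">=50", ">=50"))
  expect_equal(as.character(coh$size_group), c("<=2cm", ">2cm", "<=2cm"))
  expect_equal(as.character(coh$nodal_group), c("0", "1-3", ">=4"))
  expect_equal(levels(coh$type_group), c("ductal", "lobular", "other"))
})

test_that("Kaplan-Meier matches the product-limit hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(tidy(km)$estimate, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  km2 <- km_estimate(c(5, 8, 2), c(0, 0, 0))
  expect_true(all(tidy(km2)$estimate == 1))
})

test_that("Kaplan-Meier equals the risk-set oracle with ties", {
  times <- c(3, 3, 5, 5, 5, 8, 9, 9, 12, 14)
  events <- c(1, 0, 1, 1, 0, 1, 0, 1, 1, 0)
  km <- tidy(km_estimate(times, events))
  orc <- oracle_km(times, events)
  got <- km[km$n_event > 0, ]
  expect_equal(got$time, orc$time)
  expect_equal(got$estimate, orc$surv)
  # larger random fixtures (<= 50 subjects)
  for (seed in 1:3) {
    set.seed(seed)
    t2 <- sample(1:20, 50, replace = TRUE)
    e2 <- rbinom(50, 1, 0.6)
    km2 <- tidy(km_estimate(t2, e2))
    orc2 <- oracle_km(t2, e2)
    expect_equal(km2$estimate[km2$n_event > 0], orc2$surv)
  }
})

test_that("log-rank agrees with survival::survdiff and is antisymmetric", {
  set.seed(5)
  times <- c(2, 4, 4, 6, 7, 9, 11, 13)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  groups <- c("a", "a", "a", "a", "b", "b", "b", "b")
  got <- logrank_stat(times, events, groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  expect_equal(got$chisq, sd$chisq, tolerance = 1e-12)
  expect_equal(got$p_value, stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
  # swapping labels flips the sign, keeps p
  flip <- logrank_stat(times, events, rev(sort(groups)))
  swapped <- logrank_stat(times, events,
                          ifelse(groups == "a", "b", "a"))
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p_value, got$p_value)
  # identical survival by construction: permuting labels of one pooled
  # sample where both groups share all times
  t0 <- rep(c(1, 2, 3, 4), 2)
  e0 <- rep(1, 8)
  g0 <- rep(c("a", "b"), each = 4)
  expect_equal(logrank_stat(t0, e0, g0)$statistic, 0)
  expect_error(logrank_stat(1:3, c(1, 1, 1), c("a", "a", "a")), "2 non-empty")
})

test_that("log-rank matches survdiff on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed + 40)
    n <- 30
    times <- rexp(n, 0.1) + sample(0:3, n, TRUE)  # induces some ties? no
    times <- round(times)
    events <- rbinom(n, 1, 0.7)
    groups <- sample(c("x", "y"), n, TRUE)
    if (length(unique(groups)) < 2 || sum(events) == 0) next
    got <- logrank_stat(times, events, groups)
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    expect_equal(got$chisq, sd$chisq, tolerance = 1e-10)
  }
})

test_that("Cox coefficient matches a brute-force partial-likelihood search", {
  # 12-subject fixture, single binary covariate
  times <- c(4, 7, 9, 12, 15, 18, 20, 24, 28, 30, 33, 40)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 0, 0, 1)
  df <- tibble::tibble(t = times, e = events, x = x)
  fit <- cox_fit(df, "t", "e", "x", scaling = c())
  beta_oracle <- oracle_cox_beta(times, events, x)
  expect_equal(tidy(fit)$estimate, beta_oracle, tolerance = 1e-4)
  # with ties, against the Efron oracle
  times2 <- c(4, 4, 9, 9, 9, 18, 20, 24, 28, 30, 33, 40)
  fit2 <- cox_fit(tibble::tibble(t = times2, e = events, x = x),
                  "t", "e", "x", scaling = c())
  beta2 <- oracle_cox_beta(times2, events, x)
  expect_equal(tidy(fit2)$estimate, beta2, tolerance = 1e-4)
})

test_that("a constant-zero covariate gives HR 1 and p near 1", {
  set.seed(9)
  df <- tibble::tibble(t = rexp(40, 0.1), e = rbinom(40, 1, 0.8),
                       x = rep(0, 40))
  # constant covariate: coxph drops it to NA coefficient; a zero-variance
  # covariate carries no information, equivalent to HR = 1
  fit <- suppressWarnings(cox_fit(df, "t", "e", "x", scaling = c()))
  td <- tidy(fit)
  expect_true(is.na(td$HR) || abs(td$HR - 1) < 1e-6)
})

test_that("biomarker scaling enters as value/divisor", {
  set.seed(10)
  n <- 200
  density <- rlnorm(n, log(400), 0.7)
  t <- rexp(n, 0.001 * exp(log(0.8) * density / 300))
  e <- as.integer(t < 3000)
  t <- pmin(t, 3000)
  df <- tibble::tibble(os_time = t, os_event = e, stil_density = density)
  fit <- cox_fit(df, "os_time", "os_event", "stil_density")
  raw <- survival::coxph(survival::Surv(t, e) ~ I(density / 300),
                         ties = "efron")
  expect_equal(tidy(fit)$estimate, unname(coef(raw)), tolerance = 1e-8)
})

test_that("Cox refuses unusable inputs with clear messages", {
  df <- tibble::tibble(t = c(5, 6), e = c(0, 0), x = c(1, 2))
  expect_error(cox_fit(df, "t", "e", "x"), "at least one event")
  # monotone likelihood: perfectly separating covariate
  sep <- tibble::tibble(t = c(1, 2, 3, 4, 10, 11, 12, 13),
                        e = c(1, 1, 1, 1, 1, 1, 1, 1),
                        x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(cox_fit(sep, "t", "e", "x", scaling = c()), "converge")
})

test_that("maxstat scan equals the plain log-rank at each candidate", {
  set.seed(13)
  n <- 60
  bio <- rlnorm(n, log(400), 0.6)
  t <- rexp(n, 0.01)
  e <- rbinom(n, 1, 0.7)
  cut <- maxstat_cutpoint(t, e, bio)
  scan <- tidy(cut)
  for (k in sample(nrow(scan), 5)) {
    mu <- scan$cutpoint[k]
    z <- logrank_stat(t, e, factor(bio >= mu,
                                   levels = c(FALSE, TRUE)))$statistic
    expect_equal(scan$statistic[k], z, tolerance = 1e-10)
  }
  expect_true(cut$cutpoint >= cut$window["low"] &
                cut$cutpoint <= cut$window["high"])
  expect_equal(cut$max_abs_statistic, max(abs(scan$statistic)))
})

test_that("two distinct biomarker values reduce maxstat to one log-rank", {
  times <- c(2, 4, 5, 7, 9, 12, 15, 18, 20, 22)
  events <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  bio <- rep(c(100, 900), 5)
  cut <- maxstat_cutpoint(times, events, bio,
                          quantile_window = c(0.01, 0.99))
  expect_equal(cut$cutpoint, 900)
  plain <- logrank_stat(times, events,
                        factor(bio >= 900, levels = c(FALSE, TRUE)))
  expect_equal(cut$statistic, plain$statistic)
  expect_error(maxstat_cutpoint(times, events, rep(1, 10)), "distinct")
})

test_that("maxstat adjusted p is within [0,1] and above the naive p", {
  set.seed(14)
  n <- 80
  bio <- rlnorm(n, log(400), 0.6)
  t <- rexp(n, 0.01)
  e <- rbinom(n, 1, 0.8)
  cut <- maxstat_cutpoint(t, e, bio)
  naive <- 2 * pnorm(-cut$max_abs_statistic)
  expect_gte(cut$p_adjusted, naive)
  expect_lte(cut$p_adjusted, 1)
  # permutation p agrees in order of magnitude with the bound
  cutp <- maxstat_cutpoint(t, e, bio, p_method = "permutation",
                           n_perm = 200, seed = 99)
  expect_gte(cutp$p_adjusted, naive)
})

test_that("Spearman matches exhaustive rank computation, ties included", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 10, 11, 11)
  y <- c(2, 1, 4, 4, 6, 5, 9, 7, 7, 12, 10, 13)
  res <- pairwise_spearman(cbind(a = x, b = y))
  expect_equal(res$correlation["a", "b"], oracle_spearman(x, y))
  expect_equal(res$correlation["a", "b"],
               cor(x, y, method = "spearman"))
  # identical and reversed vectors
  expect_equal(pairwise_spearman(cbind(x, x))$correlation[1, 2], 1)
  expect_equal(pairwise_spearman(cbind(x = 1:6,
                                       y = 6:1))$correlation[1, 2], -1)
  # constant reader is reported missing, not an error
  resc <- pairwise_spearman(cbind(a = x, b = rep(3, 12)))
  expect_true(is.na(resc$correlation["a", "b"]))
  expect_error(pairwise_spearman(cbind(a = 1:2, b = 2:1)), ">= 3")
})

test_that("three-reader matrices give symmetric unit-diagonal output", {
  set.seed(15)
  base <- rpois(12, 40)
  m <- cbind(r1 = base + rpois(12, 4), r2 = base + rpois(12, 4),
             r3 = base + rpois(12, 6))
  res <- pairwise_spearman(m)
  expect_equal(res$correlation, t(res$correlation))
  expect_equal(diag(res$correlation), c(r1 = 1, r2 = 1, r3 = 1))
  expect_true(all(res$pairs$p_value >= 0 & res$pairs$p_value <= 1))
  expect_equal(nrow(res$pairs), 3)
})

test_that("concordance arithmetic reproduces the 2x2 construction", {
  manual <- c(rep("high", 121 + 28), rep("low", 91 + 22))
  auto <- c(rep("high", 121), rep("low", 28), rep("low", 91),
            rep("high", 22))
  rep_ <- concordance_report(manual, auto)
  expect_equal(rep_$tp, 121); expect_equal(rep_$fn, 28)
  expect_equal(rep_$tn, 91); expect_equal(rep_$fp, 22)
  expect_equal(round(rep_$sensitivity, 3), 0.812)
  expect_equal(round(rep_$specificity, 3), 0.805)
  expect_equal(nrow(rep_$discrepant), 50)
  # perfect agreement
  perfect <- concordance_report(manual, manual)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(nrow(perfect$discrepant), 0)
  # all-negative reference: sensitivity undefined
  neg <- concordance_report(rep("low", 5), rep("low", 5))
  expect_true(is.na(neg$sensitivity))
  expect_error(concordance_report(c("low", "high"), "low"), "length")
})

test_that("borderline discrepancies are flagged near both cutpoints", {
  manual <- c("high", "high", "low")
  auto <- c("low", "low", "high")
  rep_ <- concordance_report(
    manual, auto, ids = c("A", "B", "C"),
    manual_scores = c(12, 45, 9), auto_scores = c(400, 100, 520),
    manual_cutpoint = 10, auto_cutpoint = 470,
    manual_band = 10, auto_band = 200)
  disc <- rep_$discrepant
  expect_equal(disc$near_both_cutpoints, c(TRUE, FALSE, TRUE))
})
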