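# Evaluation statistics, each checked against an independent oracle:
# brute-force pair counting (AUC), hand-computed product limits (KM),
# manual partial-likelihood derivatives (Cox), and the survival package.

test_that("stratified split has exact sizes and keeps label rates", {
  labels <- rep(c(0, 1), c(1100, 605))          # n = 1705
  sp <- stratified_split(labels, seed = 2)
  expect_identical(lengths(sp[c("train", "val", "test")]),
                   c(train = 1278L, val = 213L, test = 214L))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_identical(sort(as.integer(c(sp$train, sp$val, sp$test))), 1:1705)
  # label rates per split within 2 percentage points of overall
  rate <- function(idx) mean(labels[as.integer(idx)])
  for (part in sp[c("train", "val", "test")])
    expect_lt(abs(rate(part) - mean(labels)), 0.02)
})

test_that("small balanced cohorts keep both classes wherever arithmetic allows", {
  labels <- rep(c(0, 1), each = 4)
  for (seed in 1:12) {
    sp <- stratified_split(labels, seed = seed)
    expect_identical(lengths(sp[c("train", "val", "test")]),
                     c(train = 6L, val = 1L, test = 1L))
    expect_setequal(unique(labels[as.integer(sp$train)]), c(0, 1))
  }
})

test_that("degenerate ratios and bad strata are handled", {
  labels <- rep(c(0, 1), each = 10)
  sp <- stratified_split(labels, ratios = c(1, 0, 0), seed = 1)
  expect_length(sp$train, 20L)
  expect_length(sp$val, 0L)
  expect_error(stratified_split(labels, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(stratified_split(c(0, 0, 0, 1, 1)), ">= 3")
})

test_that("AUC matches brute-force pair counting on random instances", {
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)                    # ties likely
    expect_equal(roc_auc(s, y, conf = FALSE)$auc, brute(s, y), tolerance = 1e-12)
  }
})

test_that("AUC endpoints and CI behave", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(roc_auc(c(rnorm(10), rnorm(10) + 100), y, conf = FALSE)$auc, 1)
  expect_equal(roc_auc(rep(0.3, 20), y, conf = FALSE)$auc, 0.5)
  set.seed(3)
  r <- roc_auc(runif(40), rbinom(40, 1, 0.5), n_boot = 500, seed = 9)
  expect_lte(r$ci[1], r$auc); expect_gte(r$ci[2], r$auc)
  set.seed(3)
  r2 <- roc_auc(runif(40), rbinom(40, 1, 0.5), n_boot = 500, seed = 9)
  expect_identical(r$ci, r2$ci)                  # bootstrap is seeded
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("F2 follows the formula and its conventions", {
  expect_equal(f2_score(c(1, 1, 0, 0) * 0.9, c(1, 1, 0, 0)), 1)
  # P = 0.5, R = 1: F2 = 5 * 0.5 / (4 * 0.5 + 1) = 0.8333...
  expect_equal(f2_score(c(0.9, 0.9), c(1, 0)), 5 * 0.5 * 1 / (4 * 0.5 + 1),
               tolerance = 1e-12)
  expect_equal(f2_score(rep(0.1, 6), c(1, 1, 0, 0, 0, 0)), 0)
})

test_that("classifier metrics stay within [0, 1] with ordered CI", {
  set.seed(4)
  y <- rbinom(60, 1, 0.4)
  s <- runif(60)
  cm <- classifier_metrics(s, y, seed = 2)
  for (v in c(cm$auc, cm$sensitivity, cm$specificity, cm$precision, cm$f2))
    expect_true(v >= 0 && v <= 1)
  expect_lt(cm$auc_ci[1], cm$auc_ci[2])
})

test_that("risk stratification is a rank-invariant median split", {
  s <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  g <- stratify_risk(s)
  expect_identical(as.integer(table(g)), c(4L, 4L))
  expect_identical(g, stratify_risk(qlogis(s)))      # monotone transform
  expect_warning(g2 <- stratify_risk(rep(0.5, 6)), "low-risk")
  expect_true(all(g2 == "low"))
})

test_that("KM matches the hand-computed product limit on six records", {
  rec <- survival_records(1:6, c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  km <- kaplan_meier(rec)
  expect_equal(km$time, c(1, 3, 4, 6))
  expect_equal(km$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(km_surv_at(km, 0), 1)
  expect_equal(km_surv_at(km, 3.5), 0.625)
})

test_that("KM degenerate cases: no events, and no censoring = 1 - ECDF", {
  none <- survival_records(1:5, 1:5, rep(0, 5))
  expect_identical(nrow(kaplan_meier(none)), 0L)
  expect_equal(km_surv_at(kaplan_meier(none), c(1, 10)), c(1, 1))
  set.seed(8)
  t <- sample(1:100, 30)
  all_ev <- survival_records(1:30, t, rep(1, 30))
  km <- kaplan_meier(all_ev)
  ecdf_t <- ecdf(t)
  expect_equal(km$surv, 1 - ecdf_t(km$time), tolerance = 1e-12)
})

test_that("KM agrees with survival::survfit on censored data", {
  set.seed(9)
  rec <- survival_records(1:40, rexp(40, 0.1), rbinom(40, 1, 0.7))
  km <- kaplan_meier(rec)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = rec)
  ours <- km_surv_at(km, sf$time)
  expect_equal(ours, sf$surv, tolerance = 1e-10)
})

test_that("log-rank is zero for identical groups and errors on empty ones", {
  rec1 <- survival_records(1:6, c(2, 4, 6, 8, 10, 12), c(1, 1, 0, 1, 0, 1))
  dup <- rbind(rec1, rec1)
  lr <- log_rank(rep(c("a", "b"), each = 6), dup)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(log_rank(rep("a", 12), dup), "two groups")
})

test_that("log-rank agrees with survival::survdiff and detects HR 3", {
  set.seed(10)
  rec <- survival_records(1:80, c(rexp(40, 0.03), rexp(40, 0.09)),
                          rep(1, 80))
  grp <- rep(c(0, 1), each = 40)
  lr <- log_rank(grp, rec)
  sd_ <- survival::survdiff(survival::Surv(time_months, event) ~ grp, data = rec)
  expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-8)
  # power at HR 3, n = 300: p < 0.01 in >= 95% of replicates
  hits <- 0L
  with_seed(77, {
    for (r in 1:100) {
      tt <- c(rexp(150, 0.02), rexp(150, 0.06))
      cens <- pmin(tt, 84)
      ev <- as.integer(tt <= 84)
      reci <- survival_records(1:300, cens, ev)
      if (log_rank(rep(0:1, each = 150), reci)$p < 0.01) hits <- hits + 1L
    }
  })
  expect_gte(hits, 95L)
})

test_that("Cox score and information match the manual four-record oracle", {
  # records (time, event, x): (1,1,1), (2,1,0), (3,1,1), (4,1,0), beta = 0:
  # U = 1/2 - 1/3 + 1/2 + 0 = 2/3;  I = 1/4 + 2/9 + 1/4 + 0 = 13/18;
  # one Newton step from 0: beta = U / I = 12/13.
  x <- c(1, 0, 1, 0); time <- 1:4; event <- rep(1, 4)
  si <- cox_score_info(0, x, time, event)
  expect_equal(si$score, 2 / 3, tolerance = 1e-12)
  expect_equal(si$info, 13 / 18, tolerance = 1e-12)
  expect_equal(si$score / si$info, 12 / 13, tolerance = 1e-12)
})

test_that("Cox fit agrees with survival::coxph (Breslow) and errors sanely", {
  set.seed(11)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.02 * exp(log(2.5) * x))
  rec <- survival_records(1:n, round(pmin(tt, 80), 1), as.integer(tt <= 80))
  fit <- cox_hr(x, rec)
  oracle <- survival::coxph(survival::Surv(time_months, event) ~ x, data = rec,
                            ties = "breslow")
  expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-7)
  expect_equal(fit$se, sqrt(unname(oracle$var[1, 1])), tolerance = 1e-6)
  bad <- rec; bad$event[x == 1] <- 0
  expect_error(cox_hr(x, bad), "no events in group 1")
})

test_that("Cox recovers a true HR of 2 (n = 1000) and covers the null", {
  with_seed(123, {
    n <- 1000
    x <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.02 * exp(log(2) * x))
    rec <- survival_records(1:n, pmin(tt, 120), as.integer(tt <= 120))
    fit <- cox_hr(x, rec)
    expect_gt(fit$hr, 1.7); expect_lt(fit$hr, 2.4)
  })
  # null coverage: CI contains 1 in >= 90% of replicates
  hits <- 0L
  with_seed(321, {
    for (r in 1:50) {
      n <- 150
      x <- rbinom(n, 1, 0.5)
      tt <- rexp(n, 0.03)
      rec <- survival_records(1:n, pmin(tt, 100), as.integer(tt <= 100))
      f <- tryCatch(cox_hr(x, rec), error = function(e) NULL)
      if (!is.null(f) && f$ci[1] <= 1 && f$ci[2] >= 1) hits <- hits + 1L
    }
  })
  expect_gte(hits, 45L)
})
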