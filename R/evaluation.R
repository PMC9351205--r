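# Classification and survival-analysis statistics: stratified splitting,
# rank-based AUC with a stratified bootstrap CI, F-beta, median risk
# stratification, Kaplan-Meier, two-group log-rank, and Cox proportional
# hazards for a single binary covariate (Newton-Raphson, Breslow ties).
# All implemented from their definitions; the `survival` package serves
# only as an independent oracle in the test suite.

#' Survival record constructor
#' @param id identifiers.
#' @param time_months follow-up times, finite and >= 0.
#' @param event 0/1 event indicators (1 = death).
#' @return data.frame with columns id, time_months, event.
#' @export
survival_records <- function(id, time_months, event) {
  stopifnot(length(id) == length(time_months), length(id) == length(event))
  if (any(!is.finite(time_months)) || any(time_months < 0))
    stop("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  data.frame(id = id, time_months = as.numeric(time_months),
             event = as.integer(event), stringsAsFactors = FALSE)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each label stratum under the seed and allocates
#' `floor(r1*n)` / `floor(r2*n)` / remainder ids to train/val/test, keeping
#' per-stratum label proportions within one count of the overall rate
#' (largest-remainder apportionment).
#'
#' @param labels vector of stratum labels (one per subject); names (or
#'   `ids`) identify subjects.
#' @param ratios length-3 numeric summing to 1 (default 75/12.5/12.5).
#' @param seed shuffle seed.
#' @param ids optional subject ids (default: names of `labels`, else 1..n).
#' @return a `split_assignment`: `train`, `val`, `test` id vectors,
#'   `ratios`, `seed`.
#' @export
stratified_split <- function(labels, ratios = c(0.75, 0.125, 0.125), seed = 1L,
                             ids = NULL) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  if (length(ratios) != 3) stop("ratios must have length 3")
  n <- length(labels)
  if (is.null(ids)) ids <- if (!is.null(names(labels))) names(labels) else seq_len(n)
  strata <- split(seq_len(n), labels)
  if (any(vapply(strata, length, integer(1)) < 3))
    stop("every stratum needs >= 3 members")
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)

  # largest-remainder apportionment of the exact global counts to strata
  apportion <- function(sizes, total) {
    if (total == 0) return(rep(0L, length(sizes)))
    quota <- sizes * total / sum(sizes)
    base <- floor(quota)
    rem <- total - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    as.integer(base)
  }
  sizes <- vapply(strata, length, integer(1))
  tr_s <- apportion(sizes, n_train)
  va_s <- apportion(sizes - tr_s, n_val)

  train <- val <- test <- character(0)
  with_seed(seed, {
    for (k in seq_along(strata)) {
      sh <- sample(strata[[k]])
      t1 <- tr_s[k]; t2 <- va_s[k]
      train <- c(train, ids[sh[seq_len(t1)]])
      if (t2 > 0) val <- c(val, ids[sh[t1 + seq_len(t2)]])
      if (length(sh) > t1 + t2) test <- c(test, ids[sh[(t1 + t2 + 1):length(sh)]])
    }
  })
  structure(list(train = train, val = val, test = test,
                 ratios = ratios, seed = seed),
            class = "split_assignment")
}

#' Rank-based AUC with a stratified bootstrap confidence interval
#'
#' Midrank AUC (ties get half credit), equal to the probability that a
#' random positive outranks a random negative.  The 95% CI is a percentile
#' interval over `n_boot` label-stratified bootstrap replicates (the CI
#' method is the package's choice; distribution-free and reproducible).
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @param conf compute the bootstrap CI?
#' @param n_boot bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list: `auc`, `ci` (length 2, when `conf`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf = TRUE, n_boot = 2000L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0)
    stop("AUC needs both classes present")
  auc_of <- function(p, n) {
    r <- rank(c(scores[p], scores[n]), ties.method = "average")
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(n))
  }
  auc <- auc_of(pos, neg)
  out <- list(auc = auc, n_pos = length(pos), n_neg = length(neg))
  if (conf) {
    reps <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        p <- sample(pos, replace = TRUE)
        n <- sample(neg, replace = TRUE)
        auc_of(p, n)
      }, numeric(1))
    })
    out$ci <- unname(quantile(reps, c(0.025, 0.975)))
  }
  out
}

#' F-beta score with beta = 2
#'
#' `(1 + b^2) P R / (b^2 P + R)`; recall weighted four times precision.
#' Returns 0 when precision and recall are both undefined/zero.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @param threshold scores > threshold predict positive.
#' @return F2 in \[0, 1\].
#' @export
f2_score <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  labels <- as.integer(labels)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p == 0 && r == 0) return(0)
  if (4 * p + r == 0) return(0)
  5 * p * r / (4 * p + r)
}

#' Threshold classification metrics
#'
#' AUC (with bootstrap CI), sensitivity, specificity, precision and F2 at
#' an operating threshold (0.5 by default; precision is 0 when nothing is
#' predicted positive).
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @param threshold operating point.
#' @param seed bootstrap seed for the AUC CI.
#' @return a `classifier_metrics` list.
#' @export
classifier_metrics <- function(scores, labels, threshold = 0.5, seed = 1L) {
  labels <- as.integer(labels)
  a <- roc_auc(scores, labels, conf = TRUE, seed = seed)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  structure(list(auc = a$auc, auc_ci = a$ci,
                 sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
                 specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
                 precision = if (tp + fp == 0) 0 else tp / (tp + fp),
                 f2 = f2_score(scores, labels, threshold),
                 threshold = threshold),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); sens %.3f spec %.3f prec %.3f F2 %.3f @ thr %.2f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$sensitivity, x$specificity,
              x$precision, x$f2, x$threshold))
  invisible(x)
}

#' Median-split risk stratification
#'
#' Scores above the median are high-risk; ties (including the median
#' itself) go to low-risk.  Rank-invariant: any monotone transform of the
#' scores yields the same grouping.
#'
#' @param scores numeric risk scores.
#' @return factor with levels `low`, `high` and a `sizes` attribute.
#' @export
stratify_risk <- function(scores) {
  med <- median(scores)
  grp <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  if (all(grp == "low"))
    warning("all scores at or below the median: every patient is low-risk")
  attr(grp, "sizes") <- table(grp)
  grp
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t)` starts at 1 and drops only at event times by factor
#' `(1 - d_i / n_i)`.
#'
#' @param records data.frame with `time_months` and `event` (see
#'   [survival_records]).
#' @return data.frame (one row per distinct event time): `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
kaplan_meier <- function(records) {
  stopifnot(all(c("time_months", "event") %in% names(records)))
  t_ev <- sort(unique(records$time_months[records$event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = integer(0),
                    n_event = integer(0), surv = numeric(0))
  for (tt in t_ev) {
    n_risk <- sum(records$time_months >= tt)
    d <- sum(records$time_months == tt & records$event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = tt, n_risk = n_risk, n_event = d, surv = s))
  }
  out
}

#' Evaluate a KM estimate at arbitrary times
#' @param km data.frame from [kaplan_meier].
#' @param times evaluation times.
#' @return survival probabilities.
#' @export
km_surv_at <- function(km, times) {
  vapply(times, function(tt) {
    rows <- km$time <= tt
    if (!any(rows)) 1 else km$surv[max(which(rows))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard chi-square statistic with 1 df from the observed-minus-expected
#' events in group 2 across the pooled event times.
#'
#' @param groups two-level factor/vector, one entry per record.
#' @param records data.frame with `time_months`, `event`.
#' @return list: `chisq`, `p`, `observed`, `expected` (per group).
#' @export
log_rank <- function(groups, records) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("log-rank needs exactly two groups")
  if (any(table(g) == 0)) stop("one group is empty")
  t_ev <- sort(unique(records$time_months[records$event == 1]))
  O <- c(0, 0); E <- c(0, 0); V <- 0
  for (tt in t_ev) {
    at_risk <- records$time_months >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(records$time_months == tt & records$event == 1)
    d1 <- sum(records$time_months == tt & records$event == 1 & g == levels(g)[1])
    O <- O + c(d1, d - d1)
    E <- E + c(d * n1 / n, d * (n - n1) / n)
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O[1] - E[1])^2 / V else 0
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Cox partial-likelihood score and information for a binary covariate
#'
#' Breslow handling of tied event times.  Exposed so the Newton-Raphson
#' iteration can be verified against hand-computed derivatives.
#'
#' @param beta log hazard ratio at which to evaluate.
#' @param x 0/1 covariate vector.
#' @param time,event survival data.
#' @return list: `score` (U), `info` (I), `loglik`.
#' @export
cox_score_info <- function(beta, x, time, event) {
  t_ev <- sort(unique(time[event == 1]))
  U <- 0; I <- 0; ll <- 0
  for (tt in t_ev) {
    risk <- time >= tt
    ev <- time == tt & event == 1
    d <- sum(ev)
    s0 <- sum(exp(beta * x[risk]))
    s1 <- sum(x[risk] * exp(beta * x[risk]))
    xbar <- s1 / s0
    U <- U + sum(x[ev]) - d * xbar
    I <- I + d * (s1 / s0) * (1 - s1 / s0)   # binary x: E[x^2] = E[x]
    ll <- ll + beta * sum(x[ev]) - d * log(s0)
  }
  list(score = U, info = I, loglik = ll)
}

#' Cox proportional-hazards fit for a binary group indicator
#'
#' Newton-Raphson maximization of the Breslow partial likelihood; Wald 95%
#' CI and p-value.
#'
#' @param group_indicator 0/1 (or two-level) group membership; the hazard
#'   ratio is group 1 vs group 0.
#' @param records data.frame with `time_months`, `event`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return a `cox_fit`: `hr`, `ci`, `p`, `beta`, `se`, `n_events`.
#' @export
cox_hr <- function(group_indicator, records, max_iter = 25L, tol = 1e-9) {
  x <- if (is.factor(group_indicator)) as.integer(group_indicator) - 1L
       else as.integer(group_indicator)
  if (!all(x %in% 0:1)) stop("group indicator must be binary")
  time <- records$time_months; event <- records$event
  for (gv in 0:1) {
    if (sum(event[x == gv]) == 0)
      stop(sprintf("no events in group %d: hazard ratio is not identifiable", gv))
  }
  beta <- 0
  for (it in seq_len(max_iter)) {
    si <- cox_score_info(beta, x, time, event)
    if (si$info <= 0) stop("singular information in Cox fit")
    delta <- si$score / si$info
    beta <- beta + delta
    if (abs(delta) < tol) break
  }
  se <- 1 / sqrt(cox_score_info(beta, x, time, event)$info)
  z <- beta / se
  structure(list(hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
                 p = 2 * pnorm(-abs(z)),
                 beta = beta, se = se, n_events = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH: HR %.2f (95%% CI %.2f-%.2f), p = %.2g, %d events\n",
              x$hr, x$ci[1], x$ci[2], x$p, x$n_events))
  invisible(x)
}
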