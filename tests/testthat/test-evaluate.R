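test_that("AUROC matches all-pairs concordance", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "one class")
  withr::with_seed(101, {
    for (rep in 1:25) {
      n <- sample(10:200, 1)
      s <- round(runif(n), 2)  # rounding forces ties
      y <- rbinom(n, 1, 0.3)
      if (length(unique(y)) < 2) next
      expect_equal(roc_auc(s, y), bf_auroc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("AUPRC is 1 for perfect ranking and ~prevalence for noise", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  withr::with_seed(7, {
    s <- runif(20000); y <- rbinom(20000, 1, 0.12)
    expect_equal(pr_auc(s, y), mean(y), tolerance = 0.02)
  })
})

test_that("threshold selection equals exhaustive grid search", {
  pol <- select_threshold(runif(10), rbinom(10, 1, 0.5), "fixed")
  expect_equal(pol$threshold, 0.5)
  pol2 <- select_threshold(c(0.2, 0.3, 0.7, 0.9), c(0, 0, 1, 1),
                           "youden_max")
  expect_equal(pol2$threshold, 0.5)  # smallest maximizing candidate
  withr::with_seed(33, {
    for (policy in c("youden_max", "f1_max")) {
      for (rep in 1:10) {
        s <- round(runif(60), 2)
        y <- rbinom(60, 1, 0.3)
        if (length(unique(y)) < 2) next
        pol <- select_threshold(s, y, policy)
        grid <- seq(0, 1, length.out = 1001)
        vals <- vapply(grid, function(th) {
          cm <- confusion_at(s, y, th)
          if (policy == "youden_max") cm$youden else cm$f1
        }, numeric(1))
        expect_equal(pol$value, max(vals), tolerance = 1e-9)
      }
    }
  })
})

test_that("confusion metrics follow their closed forms", {
  cm <- confusion_at(c(0.9, 0.8, 0.6, 0.4), c(1, 1, 0, 0), 0.5)
  expect_equal(cm[c("tp", "fp", "fn", "tn")], list(tp = 2, fp = 1, fn = 0,
                                                   tn = 1))
  expect_equal(cm$precision, 2 / 3)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$f1, 0.8)
  cm0 <- confusion_at(c(0.2, 0.8), c(0, 1), 0)
  expect_equal(cm0$sensitivity, 1)
  expect_equal(cm0$specificity, 0)
  # sensitivity 1, specificity 0.25 -> G-mean 0.5
  expect_equal(confusion_at(c(0.9, 0.8, 0.6, 0.7, 0.55, 0.2),
                            c(1, 1, 0, 0, 0, 0), 0.5)$g_mean,
               sqrt(1 * 0.25))
})

test_that("Harrell's c matches the all-pairs oracle", {
  # perfect rank-inverse scores
  expect_equal(harrell_c(c(3, 2, 1), c(5, 10, 15), c(1, 1, 1)), 1)
  withr::with_seed(59, {
    n <- 50
    s <- round(runif(n), 2)
    tm <- sample(1:400, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    ev[1] <- 1
    expect_equal(harrell_c(s, tm, ev), bf_harrell(s, tm, ev),
                 tolerance = 1e-12)
    # no censoring, distinct times: c equals AUROC-style concordance of
    # scores with the reversed time ranking
    tm2 <- sample(seq_len(n))
    expect_equal(harrell_c(s, tm2, rep(1, n)),
                 bf_harrell(s, tm2, rep(1, n)), tolerance = 1e-12)
  })
  expect_error(harrell_c(c(1, 2), c(5, 9), c(0, 0)), "comparable")
})

test_that("bootstrap CIs behave and default to 1,000 replicates", {
  ci <- bootstrap_ci(function(i) 0.42, n = 30, seed = 2)
  expect_equal(ci$lower, 0.42)
  expect_equal(ci$upper, 0.42)
  expect_equal(ci$replicates, 1000L)
  # deterministic given the seed
  withr::with_seed(11, { s <- runif(80); y <- rbinom(80, 1, 0.3) })
  f <- function(i) roc_auc(s[i], y[i])
  c1 <- bootstrap_ci(f, 80, B = 200, seed = 5)
  c2 <- bootstrap_ci(f, 80, B = 200, seed = 5)
  expect_identical(c1, c2)
  # CI width shrinks with n
  withr::with_seed(12, {
    mk <- function(n) {
      y <- rbinom(n, 1, 0.3); s <- y + rnorm(n)
      bootstrap_ci(function(i) roc_auc(s[i], y[i]), n, B = 200, seed = 3)
    }
    ci_small <- mk(200); ci_big <- mk(2000)
  })
  expect_lt(ci_big$upper - ci_big$lower, ci_small$upper - ci_small$lower)
  # degenerate resamples are skipped and counted ...
  y1 <- c(1, rep(0, 5)); s1 <- seq(0.9, 0.4, length.out = 6)
  cd <- bootstrap_ci(function(i) roc_auc(s1[i], y1[i]), 6, B = 100, seed = 1)
  expect_gt(cd$degenerate, 0)
  expect_equal(cd$replicates + cd$degenerate, 100L)
  # ... but refused when dominant
  expect_error(bootstrap_ci(function(i) stop("metric undefined"), 6,
                            B = 100, seed = 1), "degenerate")
})

test_that("Kaplan-Meier and log-rank match textbook computations", {
  km <- km_curve(c(5, 10, 15), c(1, 1, 1), rep("all", 3))
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # survival is monotone from 1 and ends at the empirical fraction when
  # there is no censoring
  withr::with_seed(4, {
    tm <- sample(1:50, 30, replace = TRUE)
    gr <- rep(c("a", "b"), 15)
    km2 <- km_curve(tm, rep(1, 30), gr)
  })
  for (g in c("a", "b")) {
    sv <- km2$curve$survival[km2$curve$group == g]
    expect_true(all(diff(sv) <= 1e-12))
    expect_equal(sv[length(sv)], 0)
  }
  # identical groups: chi-square 0
  lr0 <- logrank_test(rep(c(2, 4, 6), 2), rep(1, 6), rep(c("x", "y"), 3))
  expect_lt(lr0$chi2, 1e-12)
  # toy two-group data against the first-principles statistic
  tm <- c(2, 4, 6, 8); ev <- c(1, 1, 1, 0); gr <- c("A", "A", "B", "B")
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$chi2, bf_logrank(tm, ev, gr), tolerance = 1e-9)
  expect_equal(lr$p, pchisq(lr$chi2, 1, lower.tail = FALSE))
  withr::with_seed(6, {
    tm <- sample(1:100, 40, replace = TRUE)
    ev <- rbinom(40, 1, 0.7)
    gr <- rep(c("A", "B"), 20)
    ev[1:2] <- 1
    lr2 <- logrank_test(tm, ev, gr)
    expect_equal(lr2$chi2, bf_logrank(tm, ev, gr), tolerance = 1e-8)
  })
  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "b", "c")), "exactly 2")
})

test_that("decision curves follow the net-benefit formula", {
  # TP = 2, FP = 1 at p_t = 0.2 with n = 10
  s <- c(0.9, 0.8, 0.3, rep(0.05, 7))
  y <- c(1, 1, 0, 1, rep(0, 6))
  dc <- decision_curve(s, y, grid = 0.2)
  expect_equal(dc$net_benefit, 0.2 - 0.1 * 0.25, tolerance = 1e-12)
  prev <- mean(y)
  expect_equal(dc$treat_all, prev - (1 - prev) * 0.2 / 0.8,
               tolerance = 1e-12)
  expect_equal(dc$treat_none, 0)
  expect_equal(nrow(decision_curve(s, y, grid = c(0.2, 1))), 1L)
})

test_that("evaluate_model assembles point estimates with their CIs", {
  withr::with_seed(15, {
    y <- rbinom(300, 1, 0.15)
    s <- plogis(qlogis(0.15) + 2 * y + rnorm(300))
    tm <- ifelse(y == 1, sample(1:365, 300, TRUE), 400)
  })
  rep <- evaluate_model(s, y, threshold = 0.5, times = tm, events = y,
                        B = 50, seed = 1)
  expect_s3_class(rep, "eval_report")
  expect_setequal(rep$metric, c("auroc", "auprc", "youden", "f1", "recall",
                                "precision", "g_mean", "harrell_c"))
  expect_true(all(rep$lower <= rep$estimate + 1e-9))
  expect_true(all(rep$upper >= rep$estimate - 1e-9))
  expect_equal(rep$estimate[rep$metric == "auroc"], roc_auc(s, y))
})
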