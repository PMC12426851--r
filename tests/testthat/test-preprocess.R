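test_that("the 24 intervals tile the 720-day window exactly", {
  b <- interval_bounds()
  expect_equal(nrow(b), 24L)
  expect_equal(unname(b[1, "from"]), -719L)
  expect_equal(b[24, ], c(from = -29L, to = 0L))
  widths <- b[, "to"] - b[, "from"] + 1L
  expect_true(all(widths == 30L))
  # no gaps or overlaps
  expect_equal(b[-1, "from"], b[-24, "to"] + 1L)
})

test_that("windowing keeps [-719, 0] and flags empty patients", {
  visits <- data.frame(patient_id = c(1, 1, 1, 1, 2),
                       day = c(-800, -720, -719, 0, -750),
                       feature = "lab_a", value = 1)
  timelines <- data.frame(patient_id = 1:2)
  expect_message(w <- build_window(visits, timelines), "no observation")
  expect_equal(sort(w$day), c(-719, 0))
  expect_false(2 %in% w$patient_id)
  # empty visit table yields an all-missing sequence downstream
  sc <- summarize_sequence(w[0, ], tiny_schema(), patient_ids = 1:3)
  expect_equal(dim(sc$values), c(3L, 24L, 6L))
  expect_false(any(sc$mask))
})

test_that("monthly summaries take means, modes and smallest-code ties", {
  sch <- tiny_schema()
  visits <- data.frame(
    patient_id = 1,
    day = c(-700, -695, -10, -5, -2, -1, 0),
    feature = c("lab_a", "lab_a", "grade", "grade", "grade", "flag_a",
                "flag_a"),
    value = c(2, 4, 1, 1, 2, 1, 0))
  sc <- summarize_sequence(visits, sch, patient_ids = 1)
  expect_equal(unname(sc$values[1, 1, "lab_a"]), 3.0)     # mean of {2, 4}
  expect_equal(unname(sc$values[1, 24, "grade"]), 1)      # mode of {1, 1, 2}
  expect_equal(unname(sc$values[1, 24, "flag_a"]), 0)     # tie {0, 1} -> smallest
  expect_true(sc$mask[1, 1, "lab_a"])
  expect_false(sc$mask[1, 2, "lab_a"])
  # schema-kind violation is named
  bad <- data.frame(patient_id = 7, day = -3, feature = "grade", value = 9)
  expect_error(summarize_sequence(bad, sch), "patient 7")
})

test_that("interval summaries match brute-force grouping on random visits", {
  sch <- tiny_schema()
  withr::with_seed(42, {
    for (rep in 1:60) {
      nv <- sample(5:40, 1)
      visits <- data.frame(
        patient_id = sample(1:3, nv, replace = TRUE),
        day = sample(-730:0, nv, replace = TRUE),
        feature = sample(sch$name, nv, replace = TRUE),
        value = sample(0:1, nv, replace = TRUE))
      visits$value[visits$feature == "grade"] <-
        sample(1:3, sum(visits$feature == "grade"), replace = TRUE)
      visits$value[startsWith(visits$feature, "lab")] <-
        round(rnorm(sum(startsWith(visits$feature, "lab"))), 3)
      sc <- summarize_sequence(build_window(visits), sch,
                               patient_ids = 1:3)
      oracle <- bf_summarize(visits, sch)
      expect_equal(sum(sc$mask), nrow(oracle))
      for (r in seq_len(nrow(oracle))) {
        expect_equal(
          unname(sc$values[oracle$patient_id[r], oracle$interval[r],
                           oracle$feature[r]]),
          oracle$cell[r], tolerance = 1e-12)
      }
    }
  })
})

test_that("training statistics come from the training split only", {
  pr <- tiny_prepped(n = 200, seed = 8)
  # perturb test-set cells; stats must not change
  sc2 <- pr$sc
  ti <- pr$split$test
  sc2$values[ti, , ] <- sc2$values[ti, , ] * 10 + 3
  st2 <- fit_train_statistics(sc2,
    sc2$patient_ids[c(pr$split$train, pr$split$validation)])
  expect_equal(as.data.frame(unclass(st2)), as.data.frame(unclass(pr$stats)))
  # simple pooled mean example
  sch <- tiny_schema()
  v <- data.frame(patient_id = c(1, 2), day = c(-3, -4), feature = "lab_a",
                  value = c(1, 3))
  sc <- summarize_sequence(v, sch, patient_ids = 1:2)
  st <- fit_train_statistics(sc, 1:2)
  expect_equal(st$mean[st$feature == "lab_a"], 2)
  expect_equal(st$min[st$feature == "lab_a"], 1)
  expect_equal(st$max[st$feature == "lab_a"], 3)
})

test_that("scaling clips to the training range and fills by policy", {
  sch <- tiny_schema()
  v <- data.frame(patient_id = c(1, 1, 2, 2),
                  day = c(-700, -10, -700, -10),
                  feature = "lab_a", value = c(0, 1, 0.5, 2))
  sc <- summarize_sequence(v, sch, patient_ids = 1:2)
  st <- fit_train_statistics(sc, 1L)   # train range [0, 1]
  scd <- scale_and_impute(sc, st, "sentinel")
  expect_equal(unname(scd$values[2, 1, "lab_a"]), 0.5)
  expect_equal(unname(scd$values[2, 24, "lab_a"]), 1.0)  # 2 clipped to train max
  expect_equal(unname(scd$values[1, 2, "lab_a"]), -1)    # missing cell
  mm <- scale_and_impute(sc, st, "train_mean_mode")
  expect_equal(unname(mm$values[1, 2, "lab_a"]), 0.5)    # scaled train mean
  # sentinel separation: no observed cell can equal -1
  pr <- tiny_prepped(n = 150, seed = 4)
  expect_true(all(pr$scd$values[pr$sc$mask] >= 0))
  expect_true(all(pr$scd$values[!pr$sc$mask] == -1))
})

test_that("labels follow the 1-year rule without excluding anyone", {
  tl <- data.frame(patient_id = 1:4,
                   event_day = c(100L, 400L, NA, 365L),
                   censor_day = c(100L, 400L, 200L, 365L))
  expect_equal(make_label(tl), c(1L, 0L, 0L, 1L))
  tl$event_day[1] <- -5L
  expect_error(make_label(tl), "precedes AF")
})

test_that("stratified splits respect the 60/40 and 20% protocol", {
  labels <- rep(c(0, 1), c(90, 10))
  sp <- split_cohort(labels, seed = 1)
  expect_equal(length(sp$test), 40L)
  expect_equal(sum(labels[sp$test]), 4L)
  expect_equal(length(sp$validation), 12L)
  expect_equal(length(intersect(sp$test, c(sp$train, sp$validation))), 0L)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:100)
  # determinism
  sp2 <- split_cohort(labels, seed = 1)
  expect_identical(sp$assignment, sp2$assignment)
  expect_false(identical(sp$assignment,
                         split_cohort(labels, seed = 2)$assignment))
  expect_warning(split_cohort(rep(c(0, 1), c(30, 3)), seed = 1),
                 "best-effort")
})

test_that("down-sampling reaches 4:1 and keeps every positive", {
  labels <- rep(c(1, 0), c(50, 500))
  sp <- list(train = 1:550, seed = 3)
  class(sp) <- "split_assignment"
  idx <- downsample_train(sp, labels, ratio = 4)
  expect_equal(sum(labels[idx] == 1), 50L)
  expect_equal(sum(labels[idx] == 0), 200L)
  # not enough negatives: keep all
  labels2 <- rep(c(1, 0), c(50, 100))
  sp2 <- list(train = 1:150, seed = 3); class(sp2) <- "split_assignment"
  expect_equal(length(downsample_train(sp2, labels2, 4)), 150L)
  # deterministic given the seed
  expect_identical(downsample_train(sp, labels, 4),
                   downsample_train(sp, labels, 4))
  sp0 <- list(train = which(labels == 0), seed = 1)
  class(sp0) <- "split_assignment"
  expect_error(downsample_train(sp0, labels, 4), "no positive")
})
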