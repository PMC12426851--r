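#' Flatten sequences for nonsequential learners
#'
#' `"last_interval"` keeps the 40 values of interval 24 (the month containing
#' the first AF event); `"flattened_sequence"` lays out all 24 x 40 = 960
#' values time-major, so the last 40 entries equal the last-interval vector.
#'
#' @param sc A scaled `summarized_cohort` (after [scale_and_impute()]) or an
#'   n x T x m array.
#' @param mode `"last_interval"` or `"flattened_sequence"`.
#' @return An n x 40 or n x 960 numeric matrix.
#' @export
extract_features <- function(sc, mode = c("last_interval",
                                          "flattened_sequence")) {
  mode <- match.arg(mode)
  values <- if (inherits(sc, "summarized_cohort")) sc$values else sc
  d <- dim(values)
  n <- d[1]; Tn <- d[2]; m <- d[3]
  if (mode == "last_interval") {
    out <- values[, Tn, , drop = TRUE]
    out <- matrix(out, n, m)
    colnames(out) <- dimnames(values)[[3]]
    out
  } else {
    a <- aperm(values, c(1, 3, 2))  # n x m x T; column j = f + (t-1)*m
    out <- matrix(a, n, m * Tn)
    fn <- dimnames(values)[[3]] %||% paste0("f", seq_len(m))
    colnames(out) <- paste0(rep(fn, Tn), "_t", rep(seq_len(Tn), each = m))
    out
  }
}

#' Specify one benchmark run
#'
#' @param model One of `"logistic"`, `"svm"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"pooled_gru"`, `"foresiin"`.
#' @param input_mode Input representation for nonsequential models;
#'   sequential models always consume the full sequence tensor.
#' @param policy Missing-data policy (see [scale_and_impute()]).
#' @param seed Seed for model fitting.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(model = c("logistic", "svm", "random_forest",
                                     "gradient_boosting", "pooled_gru",
                                     "foresiin"),
                           input_mode = c("last_interval",
                                          "flattened_sequence"),
                           policy = c("sentinel", "train_mean_mode"),
                           seed = 1L) {
  model <- match.arg(model)
  structure(list(model = model,
                 input_mode = if (model %in% c("pooled_gru", "foresiin"))
                   "sequence" else match.arg(input_mode),
                 policy = match.arg(policy), seed = as.integer(seed)),
            class = "benchmark_spec")
}

# Fit one nonsequential learner over a tiny hyperparameter grid selected on
# validation AUPRC; returns the winning predictor function. Grids are
# deliberately small and documented in the methods vignette.
fit_flat_model <- function(model, xtr, ytr, xval, yval, seed) {
  fit_one <- function(hp) {
    switch(model,
      logistic = {
        df <- data.frame(y = ytr, xtr)
        fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
        function(x) suppressWarnings(
          predict(fit, newdata = data.frame(x), type = "response"))
      },
      svm = {
        if (!requireNamespace("e1071", quietly = TRUE))
          stop("package e1071 is required for the SVM benchmark")
        fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "radial",
                          cost = hp, probability = TRUE)
        function(x) attr(predict(fit, x, probability = TRUE),
                         "probabilities")[, "1"]
      },
      random_forest = {
        if (!requireNamespace("ranger", quietly = TRUE))
          stop("package ranger is required for the RF benchmark")
        fit <- ranger::ranger(x = xtr, y = factor(ytr, levels = 0:1),
                              probability = TRUE, num.trees = 500,
                              mtry = max(1, min(ncol(xtr), hp)),
                              seed = seed)
        function(x) predict(fit, data = x)$predictions[, "1"]
      },
      gradient_boosting = {
        if (!requireNamespace("xgboost", quietly = TRUE))
          stop("package xgboost is required for the XGB benchmark")
        fit <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = hp,
                        eta = 0.1, nthread = 1),
          data = xgboost::xgb.DMatrix(xtr, label = ytr), nrounds = 150)
        function(x) predict(fit, xgboost::xgb.DMatrix(x))
      })
  }
  grid <- switch(model,
    logistic = list(NA),
    svm = list(0.5, 2),
    random_forest = list(floor(sqrt(ncol(xtr))), max(2, ncol(xtr) %/% 5)),
    gradient_boosting = list(2, 4))
  best <- NULL; best_ap <- -Inf
  for (hp in grid) {
    pred <- with_seed(seed, fit_one(hp))
    ap <- if (length(grid) > 1) pr_auc(pred(xval), yval) else 0
    if (ap > best_ap) { best_ap <- ap; best <- pred }
  }
  best
}

#' Run the benchmark comparison table
#'
#' Trains each spec on the down-sampled training set, selects its decision
#' threshold on the validation set, and evaluates on the independent test
#' set with the full metric suite — the model x input-type x imputation
#' comparison matrix. The CHA2DS2-VASc and ATRIA comparators, computed from
#' the baseline table and used directly as ranking statistics, join the
#' table when `baseline` is supplied.
#'
#' @param sc Unscaled `summarized_cohort` from [summarize_sequence()].
#' @param labels 0/1 labels for all patients (cohort order).
#' @param split A `split_assignment`.
#' @param specs List of [benchmark_spec()]s.
#' @param baseline Optional baseline table for the clinical scores.
#' @param times,events Optional survival data (cohort order) for c-index.
#' @param ratio Down-sampling ratio (default 4).
#' @param threshold_policy Policy for [select_threshold()].
#' @param B Bootstrap replicates for the CIs (default 1000).
#' @param model_config_overrides Named list merged into the default
#'   [model_config()] of the sequential rows.
#' @return A `benchmark_table` data.frame: one row per spec and comparator,
#'   with AUPRC, AUROC, Youden, F1, c-index and their CIs.
#' @export
run_benchmarks <- function(sc, labels, split, specs, baseline = NULL,
                           times = NULL, events = NULL, ratio = 4,
                           threshold_policy = "youden_max", B = 1000L,
                           model_config_overrides = list()) {
  stats_cache <- list()
  ds_idx <- downsample_train(split, labels, ratio)
  te <- split$test; va <- split$validation
  rows <- list()

  scaled_for <- function(policy) {
    if (is.null(stats_cache[[policy]])) {
      st <- fit_train_statistics(sc, sc$patient_ids[c(split$train, va)])
      stats_cache[[policy]] <<- scale_and_impute(sc, st, policy)
    }
    stats_cache[[policy]]
  }

  eval_scores <- function(name, mode, policy, val_scores, test_scores) {
    pol <- select_threshold(val_scores, labels[va], threshold_policy)
    rep <- evaluate_model(test_scores, labels[te], pol$threshold,
                          times = if (is.null(times)) NULL else times[te],
                          events = if (is.null(events)) NULL else events[te],
                          B = B, seed = 1L)
    wide <- setNames(rep$estimate, rep$metric)
    ci <- function(mname)
      sprintf("(%.3f-%.3f)", rep$lower[rep$metric == mname],
              rep$upper[rep$metric == mname])
    data.frame(model = name, input_mode = mode, policy = policy,
               threshold = pol$threshold,
               auprc = wide[["auprc"]], auprc_ci = ci("auprc"),
               auroc = wide[["auroc"]], auroc_ci = ci("auroc"),
               youden = wide[["youden"]], youden_ci = ci("youden"),
               f1 = wide[["f1"]], f1_ci = ci("f1"),
               c_index = if ("harrell_c" %in% rep$metric)
                 wide[["harrell_c"]] else NA_real_,
               c_index_ci = if ("harrell_c" %in% rep$metric)
                 ci("harrell_c") else NA_character_)
  }

  for (spec in specs) {
    scd <- scaled_for(spec$policy)
    row <- tryCatch({
      if (spec$model %in% c("pooled_gru", "foresiin")) {
        variant <- if (spec$model == "foresiin") "independent" else "pooled_gru"
        cfg <- do.call(model_config,
                       modifyList(list(variant = variant, seed = spec$seed),
                                  model_config_overrides))
        par0 <- init_params(cfg, dim(scd$values)[3])
        fit <- train_model(par0, scd$values[ds_idx, , , drop = FALSE],
                           labels[ds_idx],
                           scd$values[va, , , drop = FALSE], labels[va], cfg)
        val_s <- forward(fit$params, scd$values[va, , , drop = FALSE])$score
        te_s <- forward(fit$params, scd$values[te, , , drop = FALSE])$score
        eval_scores(spec$model, "sequence", spec$policy, val_s, te_s)
      } else {
        X <- extract_features(scd, spec$input_mode)
        pred <- fit_flat_model(spec$model, X[ds_idx, , drop = FALSE],
                               labels[ds_idx], X[va, , drop = FALSE],
                               labels[va], spec$seed)
        eval_scores(spec$model, spec$input_mode, spec$policy,
                    pred(X[va, , drop = FALSE]), pred(X[te, , drop = FALSE]))
      }
    }, error = function(e) {
      warning("benchmark row failed (", spec$model, "): ",
              conditionMessage(e))
      data.frame(model = spec$model, input_mode = spec$input_mode,
                 policy = spec$policy, threshold = NA_real_,
                 auprc = NA_real_, auprc_ci = NA_character_,
                 auroc = NA_real_, auroc_ci = NA_character_,
                 youden = NA_real_, youden_ci = NA_character_,
                 f1 = NA_real_, f1_ci = NA_character_,
                 c_index = NA_real_, c_index_ci = NA_character_)
    })
    rows[[length(rows) + 1L]] <- row
  }

  if (!is.null(baseline)) {
    for (scorer in c("cha2ds2_vasc", "atria")) {
      s <- if (scorer == "cha2ds2_vasc") cha2ds2_vasc(baseline)
           else atria_score(baseline)
      # integer scores in [0, max] rescaled to [0, 1] to act as risk scores
      s <- s / max(s, 1)
      rows[[length(rows) + 1L]] <-
        eval_scores(scorer, "baseline", "none", s[va], s[te])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("benchmark_table", "data.frame"))
}
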