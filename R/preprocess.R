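#' Interval bounds for the 24-month feature window
#'
#' Fixed 30-day intervals counted back from the first AF event (day 0):
#' interval `t` covers days `[-719 + 30(t-1), -719 + 30t - 1]`, so interval
#' 24 is `[-29, 0]` and contains the AF day. Together the 24 intervals tile
#' `[-719, 0]` with no gaps or overlaps.
#'
#' @return A 24 x 2 integer matrix with columns `from`, `to` (inclusive).
#' @export
interval_bounds <- function() {
  t <- 1:24
  cbind(from = -719L + 30L * (t - 1L), to = -719L + 30L * t - 1L)
}

#' Restrict visits to the 2-year feature window
#'
#' Keeps observations with day in `[-719, 0]`; day 0 (the first AF encounter)
#' belongs to the final interval. Patients with no visit in the window are
#' retained downstream as all-missing sequences (no patient is excluded).
#'
#' @param visits Long visit table (`patient_id`, `day`, `feature`, `value`).
#' @param timelines Timeline table; used only to report patients whose
#'   windows are empty.
#' @return The windowed subset of `visits`.
#' @export
build_window <- function(visits, timelines = NULL) {
  visits <- data.table::as.data.table(visits)
  out <- visits[visits$day >= -719L & visits$day <= 0L, ]
  if (!is.null(timelines)) {
    empty <- setdiff(timelines$patient_id, unique(out$patient_id))
    if (length(empty))
      message(length(empty),
              " patient(s) have no observation in the feature window; ",
              "they are kept as all-missing sequences")
  }
  out
}

#' Summarize windowed visits into 24 x m monthly sequences
#'
#' Each (patient, interval, feature) cell becomes the mean of the observed
#' values for numeric features, or the mode for binary/categorical features
#' (ties broken toward the smallest category code). Cells with no observation
#' are missing (`mask = FALSE`).
#'
#' @param visits Windowed visit table from [build_window()].
#' @param schema The [feature_schema()].
#' @param patient_ids Patients to include (defaults to those in `visits`);
#'   pass the full cohort ids so visit-free patients get all-missing rows.
#' @return A `summarized_cohort`: list with `values` (n x 24 x m array),
#'   `mask` (same shape, `TRUE` = observed), `patient_ids`, `feature_names`,
#'   `interval_bounds`, `schema`.
#' @export
summarize_sequence <- function(visits, schema, patient_ids = NULL) {
  visits <- data.table::as.data.table(visits)
  if (is.null(patient_ids)) patient_ids <- sort(unique(visits$patient_id))
  n <- length(patient_ids); m <- nrow(schema); Tn <- 24L
  values <- array(NA_real_, c(n, Tn, m),
                  dimnames = list(NULL, NULL, schema$name))
  mask <- array(FALSE, c(n, Tn, m),
                dimnames = list(NULL, NULL, schema$name))
  if (nrow(visits)) {
    bad <- setdiff(unique(visits$feature), schema$name)
    if (length(bad))
      stop("validation error: unknown feature(s) ", paste(bad, collapse = ", "))
    v <- visits[visits$day >= -719L & visits$day <= 0L, ]
    check_schema_values(v, schema)
    v$interval <- (v$day + 719L) %/% 30L + 1L
    kind <- setNames(schema$kind, schema$name)
    v$is_num <- kind[v$feature] == "numeric"
    agg_num <- v[v$is_num == TRUE,
                 list(cell = mean(value)),
                 by = c("patient_id", "interval", "feature")]
    # vectorized mode with smallest-code ties: count, order by count desc /
    # code asc, keep the first row per cell
    cnt <- v[v$is_num == FALSE, list(n_obs = .N),
             by = c("patient_id", "interval", "feature", "value")]
    data.table::setorder(cnt, patient_id, interval, feature, -n_obs, value)
    agg_cat <- unique(cnt, by = c("patient_id", "interval", "feature"))
    agg_cat <- agg_cat[, list(patient_id, interval, feature, cell = value)]
    agg <- rbind(agg_num, agg_cat)
    pi <- match(agg$patient_id, patient_ids)
    fi <- match(agg$feature, schema$name)
    keep <- !is.na(pi)
    idx <- cbind(pi[keep], agg$interval[keep], fi[keep])
    values[idx] <- agg$cell[keep]
    mask[idx] <- TRUE
  }
  structure(list(values = values, mask = mask,
                 patient_ids = patient_ids,
                 feature_names = schema$name,
                 interval_bounds = interval_bounds(),
                 schema = schema),
            class = "summarized_cohort")
}

# Deterministic, order-independent mode: smallest code wins ties.
mode_smallest <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

check_schema_values <- function(v, schema) {
  for (j in which(schema$kind != "numeric")) {
    row <- schema[j, ]
    codes <- if (row$kind == "binary") c(0, 1) else seq_along(row$probs[[1]])
    vv <- v[v$feature == row$name, ]
    ok <- vv$value %in% codes
    if (!all(ok)) {
      first <- vv[which(!ok)[1], ]
      stop(sprintf(
        "validation error: feature '%s' of patient %s on day %d has value %s outside its schema codes",
        row$name, first$patient_id, first$day, format(first$value)))
    }
  }
  invisible(TRUE)
}

#' @export
print.summarized_cohort <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<summarized_cohort> %d patients x %d intervals x %d features; %.1f%% cells observed\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Fit per-feature training statistics
#'
#' Pools all observed cells of training-split patients and records, per
#' feature, the mean (numeric), mode (binary/categorical, smallest-code
#' ties), the observed min/max, and the maximum observed category code.
#' Validation and test patients never contribute.
#'
#' @param sc A `summarized_cohort`.
#' @param train_ids Patient ids of the training split (including its
#'   validation subset, which is carved from the training set).
#' @return An object of class `train_stats`.
#' @export
fit_train_statistics <- function(sc, train_ids) {
  ti <- match(train_ids, sc$patient_ids)
  if (anyNA(ti)) stop("train_ids not found in cohort")
  m <- length(sc$feature_names)
  stats <- data.frame(feature = sc$feature_names,
                      kind = sc$schema$kind,
                      mean = NA_real_, mode = NA_real_,
                      min = NA_real_, max = NA_real_,
                      max_code = NA_real_)
  unseen <- character(0)
  for (j in seq_len(m)) {
    cells <- sc$values[ti, , j][sc$mask[ti, , j]]
    if (!length(cells)) { unseen <- c(unseen, sc$feature_names[j]); next }
    stats$min[j] <- min(cells); stats$max[j] <- max(cells)
    if (stats$kind[j] == "numeric") stats$mean[j] <- mean(cells)
    else { stats$mode[j] <- mode_smallest(cells); stats$max_code[j] <- max(cells) }
  }
  if (length(unseen))
    message("feature(s) never observed in training (imputed as 0 after scaling): ",
            paste(unseen, collapse = ", "))
  structure(stats, class = c("train_stats", "data.frame"))
}

#' Scale observed cells and fill missing ones
#'
#' Numeric cells are min-max scaled to `[0, 1]` using the training min/max
#' (values outside the training range are clipped; degenerate features with
#' `min == max` map to 0.5). Binary/categorical codes are divided by the
#' maximum training code. Missing cells are then set according to the policy:
#' the scaled training mean/mode (`"train_mean_mode"`), or the sentinel `-1`
#' (`"sentinel"`), which lies strictly outside the scaled observed range so
#' the model can tell absence from any observed value. The mask is unchanged.
#'
#' @param sc A `summarized_cohort`.
#' @param stats A `train_stats` from [fit_train_statistics()].
#' @param policy `"sentinel"` (default, imputation-free) or
#'   `"train_mean_mode"`.
#' @return A `summarized_cohort` with scaled, filled `values`.
#' @export
scale_and_impute <- function(sc, stats,
                             policy = c("sentinel", "train_mean_mode")) {
  policy <- match.arg(policy)
  values <- sc$values
  for (j in seq_along(sc$feature_names)) {
    obs <- sc$mask[, , j]
    x <- values[, , j]
    if (stats$kind[j] == "numeric") {
      rng <- stats$max[j] - stats$min[j]
      if (is.na(rng)) x[obs] <- 0            # never seen in training
      else if (rng == 0) x[obs] <- 0.5
      else x[obs] <- pmin(1, pmax(0, (x[obs] - stats$min[j]) / rng))
      fill <- if (is.na(rng)) 0
      else if (rng == 0) 0.5
      else min(1, max(0, (stats$mean[j] - stats$min[j]) / rng))
    } else {
      mc <- max(stats$max_code[j], 1, na.rm = TRUE)
      x[obs] <- x[obs] / mc
      fill <- if (is.na(stats$mode[j])) 0 else stats$mode[j] / mc
    }
    x[!obs] <- if (policy == "sentinel") -1 else fill
    values[, , j] <- x
  }
  out <- sc
  out$values <- values
  out$policy <- policy
  out$stats <- stats
  out
}

#' Binary one-year stroke label from a timeline
#'
#' 1 if the patient's first TIA/ischemic stroke occurs within 365 days of the
#' first AF event, 0 otherwise — including patients censored (death, loss to
#' follow-up) before day 365 without an event, so no patient is excluded.
#'
#' @param timelines Timeline table with `event_day` (NA if no event) and
#'   `censor_day`.
#' @return Integer vector of 0/1 labels aligned with `timelines` rows.
#' @export
make_label <- function(timelines) {
  ev <- timelines$event_day
  if (any(!is.na(ev) & ev <= 0))
    stop("timeline error: event_day must be positive (event precedes AF)")
  as.integer(!is.na(ev) & ev <= 365)
}

#' Stratified train/validation/test split
#'
#' Patients are split 60/40 into training and test within each label stratum
#' (fractions exact to one patient per stratum), then 20% of the training
#' set, again stratified, is set aside as the validation set used for early
#' stopping and threshold selection.
#'
#' @param labels 0/1 label vector.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @param test_frac Test fraction (default 0.4).
#' @param val_frac Validation fraction of the training set (default 0.2).
#' @return A `split_assignment`: list with integer index vectors `train`
#'   (excluding validation), `validation`, `test`, plus `assignment`
#'   (character vector over patients) and the seed.
#' @export
split_cohort <- function(labels, seed, test_frac = 0.4, val_frac = 0.2) {
  stopifnot(all(labels %in% c(0, 1)))
  if (min(table(factor(labels, levels = 0:1))) < 2)
    stop("need at least 2 patients per class to stratify")
  if (any(table(labels) < 5))
    warning("a class has fewer than 5 patients; stratification is best-effort")
  n <- length(labels)
  assignment <- character(n)
  with_seed(stage_seed(seed, 3L), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n_test <- round(length(idx) * test_frac)
      test <- idx[seq_len(n_test)]
      tr <- idx[-seq_len(n_test)]
      n_val <- round(length(tr) * val_frac)
      val <- tr[seq_len(n_val)]
      assignment[test] <- "test"
      assignment[val] <- "validation"
      assignment[setdiff(tr, val)] <- "train"
    }
  })
  structure(list(train = which(assignment == "train"),
                 validation = which(assignment == "validation"),
                 test = which(assignment == "test"),
                 assignment = assignment, seed = seed),
            class = "split_assignment")
}

#' Down-sample training negatives to a fixed class ratio
#'
#' Keeps every training positive and samples negatives without replacement to
#' exactly `ratio` times the positive count (or all negatives if fewer),
#' addressing class imbalance as in the study protocol's 4:1 setting. The
#' validation and test sets are untouched.
#'
#' @param split A `split_assignment`.
#' @param labels Full label vector.
#' @param ratio Negatives per positive (default 4).
#' @param seed Seed for the negative subsample.
#' @return Integer vector of retained training indices.
#' @export
downsample_train <- function(split, labels, ratio = 4, seed = split$seed) {
  pos <- split$train[labels[split$train] == 1]
  neg <- split$train[labels[split$train] == 0]
  if (!length(pos)) stop("no positive patients in the training set")
  k <- min(length(neg), round(ratio * length(pos)))
  keep_neg <- with_seed(stage_seed(seed, 4L), sample(neg, k))
  sort(c(pos, keep_neg))
}
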