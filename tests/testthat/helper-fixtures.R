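# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the implementation path (and the libraries it delegates to).

tiny_schema <- function() {
  rows <- data.frame(
    name = c("lab_a", "lab_b", "lab_c", "flag_a", "flag_b", "grade"),
    kind = c("numeric", "numeric", "numeric", "binary", "binary",
             "categorical"),
    units = "",
    mean = c(10, 100, 1, NA, NA, NA),
    sd = c(2, 20, 0.3, NA, NA, NA),
    p = c(NA, NA, NA, 0.3, 0.1, NA),
    missing_rate = c(0.5, 0.7, 0.6, 0.5, 0.6, 0.7))
  rows$probs <- vector("list", 6)
  rows$probs[[6]] <- c(0.5, 0.3, 0.2)
  feature_schema(rows)
}

tiny_cohort <- function(n = 300, seed = 5,
                        effects = c(lab_a = 1.2, flag_a = 0.8),
                        prevalence = 0.2, ...) {
  cfg <- sim_config(n_patients = n, target_prevalence = prevalence,
                    planted_effects = effects, seed = seed, ...)
  generate_cohort(cfg, tiny_schema())
}

# Fully scaled & split miniature pipeline on the tiny schema; returns the
# pieces most tests need.
tiny_prepped <- function(n = 300, seed = 5, policy = "sentinel", ...) {
  co <- tiny_cohort(n, seed, ...)
  labels <- make_label(co$timelines)
  sc <- summarize_sequence(build_window(co$visits), tiny_schema(),
                           co$timelines$patient_id)
  split <- split_cohort(labels, seed = seed)
  stats <- fit_train_statistics(sc,
    sc$patient_ids[c(split$train, split$validation)])
  scd <- scale_and_impute(sc, stats, policy)
  list(cohort = co, labels = labels, sc = sc, scd = scd, split = split,
       stats = stats)
}

# ---- oracles ---------------------------------------------------------------

# all-pairs concordance AUROC (ties count one half)
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# all-pairs Harrell c with the standard comparability rules: patient i with
# an observed event is comparable with every j surviving past time_i,
# including j censored exactly at time_i; two events at the same time are
# not comparable; score ties count one half
bf_harrell <- function(scores, times, events) {
  conc <- 0; comp <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] == 1 &&
        (times[i] < times[j] ||
           (times[i] == times[j] && events[j] == 0))) {
      comp <- comp + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# brute-force monthly grouping: returns a data.frame(patient, interval,
# feature, cell) built with plain loops over a long visit table
bf_summarize <- function(visits, schema) {
  out <- list()
  for (pid in unique(visits$patient_id)) {
    for (f in unique(visits$feature[visits$patient_id == pid])) {
      kind <- schema$kind[schema$name == f]
      vv <- visits[visits$patient_id == pid & visits$feature == f &
                     visits$day >= -719 & visits$day <= 0, ]
      if (!nrow(vv)) next
      itv <- (vv$day + 719) %/% 30 + 1
      for (t in unique(itv)) {
        vals <- vv$value[itv == t]
        cell <- if (kind == "numeric") mean(vals) else {
          tab <- table(vals)
          as.numeric(names(tab)[tab == max(tab)][1])  # names sorted ascending
        }
        out[[length(out) + 1]] <- data.frame(patient_id = pid, interval = t,
                                             feature = f, cell = cell)
      }
    }
  }
  do.call(rbind, out)
}

# textbook two-group log-rank statistic from first principles
bf_logrank <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  ev_times <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ev_times) {
    at1 <- sum(times >= t & g == 1); at2 <- sum(times >= t & g == 2)
    d1 <- sum(times == t & events == 1 & g == 1)
    d2 <- sum(times == t & events == 1 & g == 2)
    d <- d1 + d2; atr <- at1 + at2
    O1 <- O1 + d1
    E1 <- E1 + d * at1 / atr
    if (atr > 1)
      V <- V + d * (at1 / atr) * (at2 / atr) * (atr - d) / (atr - 1)
  }
  (O1 - E1)^2 / V
}

rand_risk_output <- function(params, n, seed) {
  withr::with_seed(seed, {
    x <- array(runif(n * 24 * params$m, -1, 1), c(n, 24, params$m))
    list(x = x, out = forward(params, x))
  })
}
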