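#' Calibrate the outcome intercept to a target prevalence
#'
#' Bisects the outcome logit intercept until the mean simulated event
#' probability matches `config$target_prevalence` to within 0.002. The
#' patient-level standardized latents are simulated once from the config seed
#' and held fixed across bisection steps, so the search is deterministic.
#'
#' @param config A [sim_config()].
#' @param schema A [feature_schema()].
#' @param tol Convergence tolerance on the mean probability (default 0.002).
#' @param max_iter Maximum bisection iterations before a calibration error.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_prevalence <- function(config, schema, tol = 0.002, max_iter = 100L) {
  stopifnot(inherits(config, "sim_config"), inherits(schema, "feature_schema"))
  check_planted(config, schema)
  n <- max(config$n_patients, 100000L)  # large draw keeps the target tight
  risk <- with_seed(stage_seed(config$seed, 2L),
                    latent_risk_scores(n, config, schema))
  target <- config$target_prevalence
  f <- function(b0) mean(plogis(b0 + risk)) - target
  lo <- -30; hi <- 30
  mid <- 0; v <- f(mid)
  for (it in seq_len(max_iter)) {
    # bisect to the interval's resolution limit; tol only gates acceptance
    if (v > 0) hi <- mid else lo <- mid
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) <= tol && (hi - lo) < 1e-9) break
  }
  if (abs(v) > tol)
    stop("calibration error: intercept search did not converge in ",
         max_iter, " iterations")
  mid
}

check_planted <- function(config, schema) {
  bad <- setdiff(names(config$planted_effects), schema$name)
  if (length(bad))
    stop("configuration error: planted feature(s) not in schema: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Standardized patient-level latents for the planted features only, combined
# into the (intercept-free) outcome logit contribution of each patient.
latent_risk_scores <- function(n, config, schema) {
  eff <- config$planted_effects
  if (!length(eff)) return(numeric(n))
  risk <- numeric(n)
  for (nm in names(eff)) {
    row <- schema[schema$name == nm, ]
    s <- switch(row$kind,
      numeric = rnorm(n),
      binary = {
        p <- row$p
        (rbinom(n, 1, p) - p) / sqrt(p * (1 - p))
      },
      categorical = {
        pr <- row$probs[[1]]
        k <- sample.int(length(pr), n, replace = TRUE, prob = pr)
        (k - sum(seq_along(pr) * pr)) / sd(seq_along(pr))
      })
    risk <- risk + eff[[nm]] * s
  }
  risk
}

#' Generate a synthetic AF cohort with planted ground truth
#'
#' Simulates irregular visit records over the two years before each patient's
#' first AF event (day 0), a binary stroke-within-one-year outcome drawn from
#' a logistic model on the planted features' standardized patient-level
#' latents, event/censoring timelines, and a baseline table for the clinical
#' comparator scores.
#'
#' Numeric features have a between-patient latent (mean, SD from the schema)
#' plus within-patient visit noise; binary and categorical features are
#' patient-constant. Visit counts per month are Poisson; every patient gets a
#' visit on day 0 (the index AF encounter). Each feature is recorded at a
#' visit with a probability chosen so the summarized month-cell missingness
#' matches the schema's `missing_rate` (months without visits are missing for
#' every feature, which floors the achievable rate at `exp(-visit_rate)`).
#'
#' @param config A [sim_config()].
#' @param schema A [feature_schema()].
#' @return A list of class `synthetic_cohort` with elements
#'   `visits` (long data.table: patient_id, day, feature, value),
#'   `timelines` (data.table: patient_id, first_af_day, event_day, censor_day),
#'   `baseline` (data.frame for [cha2ds2_vasc()] / [atria_score()]),
#'   and `truth` (planted weights, intercept, per-patient latent risk,
#'   realized prevalence, seed).
#' @export
generate_cohort <- function(config, schema = default_schema()) {
  stopifnot(inherits(config, "sim_config"), inherits(schema, "feature_schema"))
  check_planted(config, schema)
  b0 <- config$intercept %||% calibrate_prevalence(config, schema)
  n <- config$n_patients
  m <- nrow(schema)

  with_seed(stage_seed(config$seed, 1L), {
    # --- patient-level latents ------------------------------------------
    lat_std <- matrix(0, n, m, dimnames = list(NULL, schema$name))
    for (j in seq_len(m)) {
      row <- schema[j, ]
      lat_std[, j] <- switch(row$kind,
        numeric = rnorm(n),
        binary = rbinom(n, 1, row$p),
        categorical = sample.int(length(row$probs[[1]]), n, replace = TRUE,
                                 prob = row$probs[[1]]))
    }

    # outcome logit on standardized planted latents
    risk <- numeric(n)
    for (nm in names(config$planted_effects)) {
      row <- schema[schema$name == nm, ]
      s <- switch(row$kind,
        numeric = lat_std[, nm],
        binary = (lat_std[, nm] - row$p) / sqrt(row$p * (1 - row$p)),
        categorical = {
          pr <- row$probs[[1]]
          (lat_std[, nm] - sum(seq_along(pr) * pr)) / sd(seq_along(pr))
        })
      risk <- risk + config$planted_effects[[nm]] * s
    }
    y <- rbinom(n, 1, plogis(b0 + risk))

    # --- timelines ------------------------------------------------------
    event_day <- rep(NA_integer_, n)
    event_day[y == 1] <- sample.int(365L, sum(y == 1), replace = TRUE)
    censor_day <- integer(n)
    censor_day[y == 1] <- event_day[y == 1]
    n0 <- sum(y == 0)
    censor_day[y == 0] <- config$censor_min +
      rgeom(n0, 1 / config$censor_geom_mean)
    timelines <- data.table::data.table(
      patient_id = seq_len(n), first_af_day = 0L,
      event_day = event_day, censor_day = as.integer(censor_day))

    # --- visit process --------------------------------------------------
    # months 1..24 cover days [-719, 0]; month 25 covers [-730, -720] (outside
    # the feature window, exercising the windowing step downstream).
    visit_mult <- if (config$mar_missing) exp(0.3 * scale(risk)[, 1]) else rep(1, n)
    counts <- matrix(rpois(n * 25L, config$visit_rate * visit_mult), n, 25L)
    counts[, 25L] <- rpois(n, config$visit_rate * 11 / 30)  # 11-day stub month
    pid <- rep(rep(seq_len(n), 25L), times = as.vector(counts))
    mon <- rep(rep(seq_len(25L), each = n), times = as.vector(counts))
    day <- ifelse(mon <= 24L,
                  -719L + (24L - mon) * 30L + (sample.int(30L, length(mon),
                                                          replace = TRUE) - 1L),
                  -730L + (sample.int(11L, length(mon), replace = TRUE) - 1L))
    # month 1 = earliest; keep ordering irrelevant downstream. Add the index
    # AF visit on day 0 for every patient.
    pid <- c(pid, seq_len(n)); day <- c(day, rep(0L, n))
    nv <- length(pid)

    # --- feature recording and values ----------------------------------
    # Per-visit miss probability q_j calibrated so the summarized month-cell
    # missingness matches the schema rate: 23 plain Poisson months give
    # e^{-lambda(1-q)} each, and the index month (whose day-0 visit is
    # guaranteed) gives q * e^{-lambda(1-q)}; features with rates below the
    # visit-process floor get q = 0.
    lambda <- config$visit_rate
    month_miss <- function(q) exp(-lambda * (1 - q)) * (23 + q) / 24
    q <- vapply(schema$missing_rate, function(rho) {
      if (rho >= 1) return(1)
      if (rho <= month_miss(0)) return(0)
      stats::uniroot(function(q) month_miss(q) - rho, c(0, 1),
                     tol = 1e-10)$root
    }, numeric(1))
    vis_list <- vector("list", m)
    for (j in seq_len(m)) {
      rec <- runif(nv) >= q[j]
      if (!any(rec)) next
      row <- schema[j, ]
      base <- lat_std[pid[rec], j]
      val <- if (row$kind == "numeric")
        row$mean + row$sd * base + rnorm(sum(rec), 0, config$noise_frac * row$sd)
      else base
      vis_list[[j]] <- data.table::data.table(
        patient_id = pid[rec], day = day[rec],
        feature = row$name, value = as.numeric(val))
    }
    visits <- data.table::rbindlist(vis_list)
    data.table::setkey(visits, patient_id, day)

    # --- baseline table for comparator scores ---------------------------
    # flags reuse the cohort's binary features when the schema has them
    # (so the comparator scores share e.g. the prior-stroke signal) and
    # fall back to independent draws otherwise
    flag <- function(nm, p) {
      if (nm %in% schema$name && schema$kind[schema$name == nm] == "binary")
        lat_std[, nm] == 1 else runif(n) < p
    }
    creat <- if ("creatinine" %in% schema$name[schema$kind == "numeric"])
      pmax(0.4, lat_std[, "creatinine"] *
             schema$sd[schema$name == "creatinine"] +
             schema$mean[schema$name == "creatinine"])
    else pmax(0.4, rnorm(n, 1.2, 0.45))
    baseline <- data.frame(
      patient_id = seq_len(n),
      age = pmax(30, round(rnorm(n, 74, 10))),
      sex = ifelse(runif(n) < 0.57, "male", "female"),
      race_black = runif(n) < 0.02,
      creatinine = creat,
      heart_failure = flag("heart_failure", 0.065),
      hypertension = flag("hypertension", 0.40),
      diabetes = flag("diabetes", 0.30),
      prior_stroke_tia = flag("history_tia_is", 0.056),
      vascular_disease = flag("vascular_disease", 0.22),
      proteinuria = runif(n) < 0.10,
      esrd = runif(n) < 0.03,
      lvedd = pmax(2, rnorm(n, 4.8, 0.7)),
      ivsd = pmax(0.4, rnorm(n, 1.0, 0.2)),
      pwd = pmax(0.4, rnorm(n, 1.0, 0.18)),
      bsa = pmax(1.2, rnorm(n, 1.73, 0.2)))

    truth <- list(
      weights = setNames(numeric(m), schema$name),
      intercept = b0,
      latent_risk = risk,
      realized_prevalence = mean(y),
      seed = config$seed)
    truth$weights[names(config$planted_effects)] <- config$planted_effects

    structure(list(visits = visits, timelines = timelines,
                   baseline = baseline, truth = truth,
                   schema = schema, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d visit observations\n",
              nrow(x$timelines), nrow(x$visits)))
  cat(sprintf("  realized 1-year stroke prevalence: %.3f\n",
              x$truth$realized_prevalence))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Visits and timelines go to CSV (long format), the baseline table to CSV,
#' and the planted truth to JSON, all re-readable by [read_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$visits, file.path(dir, "visits.csv"))
  data.table::fwrite(cohort$timelines, file.path(dir, "timelines.csv"))
  data.table::fwrite(cohort$baseline, file.path(dir, "baseline.csv"))
  jsonlite::write_json(
    list(weights = as.list(cohort$truth$weights),
         intercept = cohort$truth$intercept,
         realized_prevalence = cohort$truth$realized_prevalence,
         seed = cohort$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `visits.csv` and `timelines.csv`
#'   (and optionally `baseline.csv`, `truth.json`).
#' @return A list with `visits`, `timelines`, and when present `baseline`
#'   and `truth`.
#' @export
read_cohort <- function(dir) {
  vf <- file.path(dir, "visits.csv")
  tf <- file.path(dir, "timelines.csv")
  if (!file.exists(vf) || !file.exists(tf))
    stop("missing cohort files in ", dir,
         " (expected visits.csv and timelines.csv; run cmd_simulate first)")
  out <- list(visits = data.table::fread(vf),
              timelines = data.table::fread(tf))
  bf <- file.path(dir, "baseline.csv")
  if (file.exists(bf)) out$baseline <- as.data.frame(data.table::fread(bf))
  jf <- file.path(dir, "truth.json")
  if (file.exists(jf)) out$truth <- jsonlite::read_json(jf, simplifyVector = TRUE)
  out
}
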