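#' Group-level feature impact analysis
#'
#' Splits patients (normally the independent test set) into group t0 (no
#' stroke within 1 year) and group t1 (stroke within 1 year) and averages
#' each feature's additive effect `e_j` on the logit within each group. The
#' difference t1 - t0 measures how much a feature separates the two groups:
#' positive contributions push the risk score up. Because the decomposition
#' is exact, the group-mean logit difference equals the sum of the
#' per-feature differences (the shared bias cancels).
#'
#' @param output A `risk_output` carrying per-feature `effects`.
#' @param labels 0/1 one-year stroke labels aligned with the output rows.
#' @return A `feature_impact_report` data.frame with columns `feature`,
#'   `t0`, `t1`, `t1_minus_t0`, `rank` (1 = largest `|t1 - t0|`, ties broken
#'   by feature index).
#' @export
group_impact <- function(output, labels) {
  if (is.null(output$effects))
    stop("output carries no per-feature effects (use the independent variant)")
  eff <- output$effects
  stopifnot(nrow(eff) == length(labels))
  for (g in c(0, 1)) if (!any(labels == g))
    stop("group t", g, " is empty")
  t0 <- colMeans(eff[labels == 0, , drop = FALSE])
  t1 <- colMeans(eff[labels == 1, , drop = FALSE])
  d <- t1 - t0
  feats <- colnames(eff) %||% paste0("f", seq_len(ncol(eff)))
  ord <- order(-abs(d), seq_along(d))
  rep <- data.frame(feature = feats, t0 = unname(t0), t1 = unname(t1),
                    t1_minus_t0 = unname(d), rank = NA_integer_)
  rep$rank[ord] <- seq_along(ord)
  structure(rep, class = c("feature_impact_report", "data.frame"))
}

#' Top-k features by absolute impact difference
#'
#' @param report A `feature_impact_report` from [group_impact()].
#' @param k Number of features to return (default 20, the figure layout used
#'   for impact rankings); must be positive and at most the feature count.
#' @return The top-k rows ordered by descending `|t1 - t0|`.
#' @export
rank_features <- function(report, k = 20L) {
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(report))
  out <- report[order(report$rank), ][seq_len(k), ]
  rownames(out) <- NULL
  out
}

#' Write an impact report to CSV
#'
#' @param report A `feature_impact_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_impact_report <- function(report, path) {
  data.table::fwrite(report[order(report$rank), ], path)
  invisible(path)
}
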