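#' Dose-only baseline: affine map from standardised dose to scores
#'
#' Sanity baseline that ignores the images entirely: for each clinical
#' metric an ordinary least-squares fit of the score on
#' `log10(fraction * full_counts / weight_kg)` over the training cohort.
#' The image-based network should beat it on metrics that depend on image
#' content rather than dose alone.
#'
#' @param cohort Training `qc_cohort`.
#' @return A `dose_baseline` object (per-metric intercept and slope).
#' @export
dose_baseline_fit <- function(cohort) {
  df <- cohort_scores(cohort)
  x <- log10(df$fraction * df$full_counts / df$weight_kg)
  coefs <- lapply(c("gqr", "pr", "dc"), function(m) {
    stats::coef(stats::lm(df[[m]] ~ x))
  })
  names(coefs) <- c("gqr", "pr", "dc")
  structure(list(coefs = coefs), class = "dose_baseline")
}

#' Predict scores from the dose-only baseline
#'
#' @param object A [dose_baseline_fit()] model.
#' @param cohort A `qc_cohort` to score.
#' @param ... Unused.
#' @return Data frame as from [evaluate_on_cohort()] (one row per patient,
#'   fraction and metric), with predictions clipped to \[0, 3\].
#' @export
predict.dose_baseline <- function(object, cohort, ...) {
  df <- cohort_scores(cohort)
  x <- log10(df$fraction * df$full_counts / df$weight_kg)
  rows <- lapply(c("gqr", "pr", "dc"), function(m) {
    cf <- object$coefs[[m]]
    data.frame(patient_id = df$patient_id, fraction = df$fraction,
               metric = m,
               predicted = pmin(pmax(cf[1] + cf[2] * x, 0), 3),
               true = df[[m]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
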