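# Agreement metrics between predicted and clinician scores.

#' Aggregate patch predictions into one image-level score
#'
#' The per-image score is the mean of its patch predictions, clipped to the
#' clinical \[0, 3\] range (the rectified head is unbounded above during
#' training; clipping is applied only at evaluation time).
#'
#' @param patch_predictions Non-empty numeric vector of patch-level
#'   predictions.
#' @return A single score in \[0, 3\].
#' @export
aggregate_patient_score <- function(patch_predictions) {
  if (length(patch_predictions) == 0L) {
    stop("no patch predictions to aggregate", call. = FALSE)
  }
  min(max(mean(patch_predictions), 0), 3)
}

check_pairs <- function(predicted, true) {
  if (length(predicted) == 0L) stop("no score pairs", call. = FALSE)
  if (length(predicted) != length(true)) {
    stop("`predicted` and `true` must have equal length", call. = FALSE)
  }
}

#' Mean absolute error of predicted scores
#'
#' Computed on the unrounded predictions.
#'
#' @param predicted Numeric vector of predicted scores.
#' @param true Numeric vector of clinician scores (0.5 grid in \[0, 3\]).
#' @return Mean of `|predicted - true|`.
#' @export
mae <- function(predicted, true) {
  check_pairs(predicted, true)
  mean(abs(predicted - true))
}

#' Percentage exact agreement
#'
#' Predictions are first rounded to the clinical 0.5 grid (half-up), since
#' clinician scores live on that grid and a continuous regression output
#' would otherwise never agree exactly.
#'
#' @inheritParams mae
#' @return Percentage (0-100) of pairs with rounded prediction equal to the
#'   true score.
#' @export
exact_agreement <- function(predicted, true) {
  check_pairs(predicted, true)
  100 * mean(abs(round_to_half(predicted) - true) < 1e-9)
}

#' Percentage close agreement
#'
#' As [exact_agreement()] but counting rounded predictions within 0.5 of
#' the true score (the inter-session scoring uncertainty band). Always at
#' least the exact agreement.
#'
#' @inheritParams mae
#' @return Percentage (0-100) of pairs within +/- 0.5 after rounding.
#' @export
close_agreement <- function(predicted, true) {
  check_pairs(predicted, true)
  100 * mean(abs(round_to_half(predicted) - true) <= 0.5 + 1e-9)
}

#' Spearman rank correlation
#'
#' Standard rank correlation with average ranks on ties. When either
#' variable has zero variance the coefficient is undefined and `NA` is
#' returned with a warning (never a silent 0).
#'
#' @param x,y Numeric vectors of length >= 2.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
spearman <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y)) {
    stop("need >= 2 pairs of equal length", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("Spearman correlation undefined: zero variance", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Evaluate a clinical model on a test cohort
#'
#' Extracts a patch set from every (patient, fraction) volume, predicts the
#' three clinical metrics per patch, and aggregates to one predicted score
#' per reconstructed image via [aggregate_patient_score()].
#'
#' @param model A trained clinical `qc_model`.
#' @param cohort Test `qc_cohort`.
#' @param per_plane,size,n_candidates Patch extraction settings.
#' @param seed Integer seed for the patch draws.
#' @return Data frame with one row per (patient, fraction, metric):
#'   `patient_id`, `fraction`, `metric`, `predicted`, `true`.
#' @export
evaluate_on_cohort <- function(model, cohort, per_plane = 8L, size = 32L,
                               n_candidates = 400L, seed = 1L) {
  rows <- list()
  k <- 0L
  for (p in cohort) {
    for (fr in p$fractions) {
      k <- k + 1L
      ps <- extract_patches(fr$volume, n_candidates, size, per_plane,
                            seed = derive_seed(seed, 31L, k),
                            patient_id = p$patient_id,
                            fraction = fr$fraction)
      pred <- predict.qc_model(model, ps)
      for (m in c("gqr", "pr", "dc")) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p$patient_id, fraction = fr$fraction, metric = m,
          predicted = aggregate_patient_score(pred[, m]),
          true = fr$scores[[m]]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement report per clinical metric
#'
#' Computes MAE, percentage exact and close agreement, and the Spearman
#' rank correlation per clinical metric and pooled across metrics.
#'
#' @param predictions Data frame as returned by [evaluate_on_cohort()]
#'   (columns `metric`, `predicted`, `true`).
#' @return An `eval_report` data frame with one row per metric plus a
#'   `pooled` row: `metric`, `n`, `mae`, `exact_pct`, `close_pct`,
#'   `spearman`.
#' @export
eval_report <- function(predictions) {
  one <- function(df, label) {
    rho <- tryCatch(suppressWarnings(spearman(df$predicted, df$true)),
                    error = function(e) NA_real_)
    data.frame(metric = label, n = nrow(df),
               mae = mae(df$predicted, df$true),
               exact_pct = exact_agreement(df$predicted, df$true),
               close_pct = close_agreement(df$predicted, df$true),
               spearman = rho)
  }
  out <- do.call(rbind, c(
    lapply(c("gqr", "pr", "dc"), function(m) {
      one(predictions[predictions$metric == m, , drop = FALSE], m)
    }),
    list(one(predictions, "pooled"))
  ))
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}
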