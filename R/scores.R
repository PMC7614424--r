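#' Clinician score model parameters
#'
#' Generative model for the three clinician-scored quality metrics — global
#' quality rating (GQR), pattern recognition (PR) and diagnostic confidence
#' (DC). Each expected score is linear in `log10(dose_per_kg)` where
#' `dose_per_kg = fraction * full_counts / weight_kg` (the injected dose
#' standardised by patient weight); rater noise is added, and the result is
#' quantised to the clinical 0.5-step grid and clipped to \[0, 3\].
#'
#' Default slopes and noise standard deviations are chosen so that all three
#' metrics correlate positively with the count fraction and GQR has the
#' highest slope-to-noise ratio, i.e. the strongest dose association; the
#' noise level (~0.35 score units) makes repeated scorings of the same image
#' differ by at least 0.5 roughly half the time, emulating inter-session
#' scoring variability.
#'
#' @param slope,intercept,noise_sd Named numeric vectors with entries
#'   `gqr`, `pr`, `dc`. Slopes must be positive.
#' @param step Quantisation step of the clinical scale (0.5).
#' @return An object of class `score_model_params`.
#' @export
score_model_params <- function(slope = c(gqr = 1.2, pr = 1.05, dc = 0.95),
                               intercept = c(gqr = -2.64, pr = -2.07,
                                             dc = -1.68),
                               noise_sd = c(gqr = 0.30, pr = 0.38, dc = 0.42),
                               step = 0.5) {
  metrics <- c("gqr", "pr", "dc")
  for (nm in c("slope", "intercept", "noise_sd")) {
    v <- get(nm)
    if (!all(metrics %in% names(v))) {
      stop(sprintf("`%s` must be named with gqr, pr, dc", nm), call. = FALSE)
    }
  }
  if (any(slope[metrics] <= 0)) {
    stop("score-model slopes must be positive", call. = FALSE)
  }
  if (any(noise_sd[metrics] < 0)) {
    stop("rater-noise SDs must be nonnegative", call. = FALSE)
  }
  structure(
    list(slope = slope[metrics], intercept = intercept[metrics],
         noise_sd = noise_sd[metrics], step = step),
    class = "score_model_params"
  )
}

#' Round to the clinical 0.5-step grid
#'
#' Values exactly halfway between two grid points round half-up
#' (e.g. 1.25 -> 1.5).
#'
#' @param x Numeric vector.
#' @param step Grid step (default 0.5).
#' @return `x` rounded to the nearest multiple of `step`.
#' @export
round_to_half <- function(x, step = 0.5) {
  floor(x / step + 0.5) * step
}

#' Draw clinician-like scores for one reconstruction
#'
#' For each metric the latent score is
#' `slope * log10(dose_per_kg) + intercept + noise` with
#' `dose_per_kg = fraction * full_counts / weight_kg`, then quantised to the
#' 0.5 grid (half-up) and clipped to \[0, 3\]. The expected score is
#' monotone non-decreasing in the count fraction.
#'
#' @param fraction Count fraction in (0, 1].
#' @param weight_kg Patient weight (kg, positive).
#' @param params A [score_model_params()] object.
#' @param seed Integer seed for the rater noise.
#' @param full_counts Expected total counts of the full acquisition.
#' @return Named numeric vector `c(gqr=, pr=, dc=)` on the 0.5 grid.
#' @export
assign_scores <- function(fraction, weight_kg, params = score_model_params(),
                          seed, full_counts = 5e6) {
  stopifnot_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(weight_kg, "weight_kg", positive = TRUE)
  dose_per_kg <- fraction * full_counts / weight_kg
  latent <- params$slope * log10(dose_per_kg) + params$intercept
  noise <- with_seed(seed, rnorm(3L, 0, params$noise_sd))
  raw <- latent + noise
  sc <- pmin(pmax(round_to_half(raw, params$step), 0), 3)
  names(sc) <- c("gqr", "pr", "dc")
  sc
}
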