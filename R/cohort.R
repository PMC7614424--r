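# Synthetic patient cohort: phantom + per-fraction degraded volumes + scores.

#' The seven simulated count fractions and their quality categories
#'
#' @return Named numeric vector of fractions; names give the quality
#'   category (`low` = 0.5% and 1%, `medium` = 5% and 10%, `high` = 25%,
#'   50% and 100% of counts).
#' @export
dose_fractions <- function() {
  c(low = 0.005, low = 0.01, medium = 0.05, medium = 0.10,
    high = 0.25, high = 0.50, high = 1.0)
}

# Pick `k` fractions for one patient: k = 3 draws one per quality category
# (mirroring the clinical reading protocol), k = 7 uses all levels,
# otherwise a uniform draw without replacement. Caller manages the RNG.
pick_fractions <- function(k) {
  fr <- dose_fractions()
  if (k == 7L) return(unname(fr))
  if (k == 3L) {
    picked <- vapply(c("low", "medium", "high"), function(cat) {
      pool <- unname(fr[names(fr) == cat])
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, numeric(1))
    return(sort(unname(picked)))
  }
  if (k < 1L || k > 7L) stop("fractions_per_patient must be in 1..7",
                             call. = FALSE)
  sort(sample(unname(fr), k))
}

#' Generate a synthetic scored patient cohort
#'
#' Builds `n_patients` brain phantoms with jittered anatomy, simulates each
#' at `fractions_per_patient` count fractions with count-dependent noise and
#' resolution loss, normalises each reconstruction to \[0, 1\], and attaches
#' clinician-like scores from the score model. Patient weights are drawn
#' from Normal(75, 10) kg truncated to \[45, 120\]; full-acquisition counts
#' are drawn uniformly in `full_counts_range`. Fully deterministic given
#' `seed`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param fractions_per_patient 3 (default; one fraction per quality
#'   category), 7 (all levels), or any count in 1..7.
#' @param seed Master seed.
#' @param shape Volume grid shape, each component >= 32.
#' @param score_params A [score_model_params()] object.
#' @param full_counts_range Range for the per-patient full-count total.
#' @param anatomy Base [anatomy_params()]; per-patient anatomy jitters
#'   radii and uptakes around it (and enables mild voxel texture).
#' @param id_prefix Prefix for patient identifiers.
#' @return A `qc_cohort`: list of patient records, each with `patient_id`,
#'   `weight_kg`, `full_counts`, `seed`, the ground-truth `activity`, and
#'   `fractions` (list of `fraction`, normalised `volume`, `scores`).
#' @export
make_cohort <- function(n_patients, fractions_per_patient = 3L, seed = 1L,
                        shape = c(96, 96, 64),
                        score_params = score_model_params(),
                        full_counts_range = c(4e6, 6e6),
                        anatomy = anatomy_params(texture_sd = 0.05),
                        id_prefix = "P") {
  if (n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pseed <- derive_seed(seed, i)
    rec <- with_seed(pseed, {
      weight <- 0
      while (weight < 45 || weight > 120) weight <- rnorm(1, 75, 10)
      full_counts <- round(runif(1, full_counts_range[1],
                                 full_counts_range[2]))
      jit <- function(x, rel) x * runif(length(x), 1 - rel, 1 + rel)
      anat <- anatomy_params(
        head_radius_frac = pmin(jit(anatomy$head_radius_frac, 0.05), 1),
        cortex_frac = anatomy$cortex_frac,
        uptake_cortex = jit(anatomy$uptake_cortex, 0.10),
        uptake_white = jit(anatomy$uptake_white, 0.10),
        uptake_ventricle = jit(anatomy$uptake_ventricle, 0.10),
        texture_sd = anatomy$texture_sd
      )
      fracs <- pick_fractions(as.integer(fractions_per_patient))
      list(weight = weight, full_counts = full_counts, anat = anat,
           fracs = fracs)
    })
    activity <- generate_phantom(derive_seed(pseed, 1L), shape = shape,
                                 anatomy = rec$anat)
    fractions <- lapply(seq_along(rec$fracs), function(j) {
      f <- rec$fracs[j]
      fseed <- derive_seed(pseed, 2L, j)
      counts <- simulate_dose_fraction(activity, rec$full_counts, f, fseed)
      list(
        fraction = f,
        volume = normalize_volume(counts),
        scores = assign_scores(f, rec$weight, score_params,
                               seed = derive_seed(pseed, 3L, j),
                               full_counts = rec$full_counts)
      )
    })
    patients[[i]] <- structure(
      list(patient_id = sprintf("%s%02d", id_prefix, i),
           weight_kg = rec$weight, full_counts = rec$full_counts,
           seed = pseed, activity = activity, fractions = fractions),
      class = "qc_patient"
    )
  }
  structure(patients, class = "qc_cohort")
}

#' @export
print.qc_cohort <- function(x, ...) {
  nf <- sum(vapply(x, function(p) length(p$fractions), integer(1)))
  cat(sprintf("<qc_cohort> %d patients, %d scored volumes\n", length(x), nf))
  invisible(x)
}

#' @export
`[.qc_cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "qc_cohort")
}

#' Patient identifiers of a cohort
#' @param cohort A `qc_cohort`.
#' @return Character vector of patient ids.
#' @export
cohort_ids <- function(cohort) {
  vapply(cohort, function(p) p$patient_id, character(1))
}

#' Flatten cohort scores to a data frame
#'
#' @param cohort A `qc_cohort`.
#' @return Data frame with one row per (patient, fraction): `patient_id`,
#'   `weight_kg`, `full_counts`, `fraction`, `gqr`, `pr`, `dc`.
#' @export
cohort_scores <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    do.call(rbind, lapply(p$fractions, function(fr) {
      data.frame(patient_id = p$patient_id, weight_kg = p$weight_kg,
                 full_counts = p$full_counts, fraction = fr$fraction,
                 gqr = fr$scores[["gqr"]], pr = fr$scores[["pr"]],
                 dc = fr$scores[["dc"]])
    }))
  }))
}

#' Assert patient-level split hygiene
#'
#' Verifies that no patient id occurs in more than one of the supplied
#' cohorts (pretext / train / validation / test); called before every
#' training run and sweep.
#'
#' @param ... Named `qc_cohort` objects (or NULL entries, which are skipped).
#' @return Invisibly TRUE; errors naming the offending ids otherwise.
#' @export
assert_split_hygiene <- function(...) {
  groups <- Filter(Negate(is.null), list(...))
  ids <- unlist(lapply(groups, cohort_ids))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("patient id(s) present in more than one split: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
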