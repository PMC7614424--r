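# Patch datasets from cohorts, the dose-inference pretext task, and the
# pre-training pipelines.

#' Build a patch dataset from a cohort
#'
#' Extracts a balanced foreground patch set from every (patient, fraction)
#' volume and attaches regression targets: the three clinical scores
#' (`target = "clinical"`) or the standardised dose (`target = "pretext"`,
#' raw `fraction * full_counts / weight_kg`; rescaling to the unit range is
#' done by the caller over the training cohort).
#'
#' @param cohort A `qc_cohort`.
#' @param per_plane Patches per plane per volume.
#' @param size Patch size in pixels.
#' @param n_candidates Candidates drawn per volume before thresholding.
#' @param seed Integer seed.
#' @param target `"clinical"` or `"pretext"`.
#' @return List: `x` (size, size, N array), `y` (N x 3 scores or N x 1 raw
#'   dose target), `info` (per-patch provenance incl. patient and fraction).
#' @export
build_patch_dataset <- function(cohort, per_plane = 100L, size = 80L,
                                n_candidates = 1000L, seed = 1L,
                                target = c("clinical", "pretext")) {
  target <- match.arg(target)
  px_list <- list()
  info_list <- list()
  y_list <- list()
  k <- 0L
  for (p in cohort) {
    for (fr in p$fractions) {
      k <- k + 1L
      ps <- extract_patches(fr$volume, n_candidates, size, per_plane,
                            seed = derive_seed(seed, k),
                            patient_id = p$patient_id,
                            fraction = fr$fraction)
      n <- nrow(ps$info)
      px_list[[k]] <- ps$pixels
      info_list[[k]] <- ps$info
      y_list[[k]] <- if (target == "clinical") {
        matrix(rep(c(fr$scores[["gqr"]], fr$scores[["pr"]],
                     fr$scores[["dc"]]), each = n), n, 3,
               dimnames = list(NULL, c("gqr", "pr", "dc")))
      } else {
        matrix(fr$fraction * p$full_counts / p$weight_kg, n, 1,
               dimnames = list(NULL, "dose"))
      }
    }
  }
  size_eff <- dim(px_list[[1]])[1]
  n_tot <- sum(vapply(px_list, function(a) dim(a)[3], numeric(1)))
  x <- array(0, dim = c(size_eff, size_eff, n_tot))
  at <- 0L
  for (a in px_list) {
    n <- dim(a)[3]
    if (n > 0) x[, , (at + 1L):(at + n)] <- a
    at <- at + n
  }
  list(x = x, y = do.call(rbind, y_list), info = do.call(rbind, info_list))
}

#' Standardised-dose pretext target scaling
#'
#' The pretext regression target is the injected dose standardised by
#' patient weight, `fraction * full_counts / weight_kg`. Because the seven
#' count fractions span 2.3 decades, the target is taken on the log10 scale
#' by default before min-max rescaling to \[0, 1\] over the training set;
#' `log = FALSE` rescales the linear value instead.
#'
#' @param raw Raw standardised dose values of the training set.
#' @param log Use the log10 scale (default TRUE).
#' @return A `pretext_scaling` object (`lo`, `hi`, `log`).
#' @export
pretext_scaling <- function(raw, log = TRUE) {
  v <- if (log) log10(raw) else raw
  lo <- min(v); hi <- max(v)
  if (hi <= lo) hi <- lo + 1  # single-level cohort: constant target 0
  structure(list(lo = lo, hi = hi, log = log), class = "pretext_scaling")
}

#' Apply a pretext scaling
#' @param scaling A [pretext_scaling()].
#' @param raw Raw standardised dose values.
#' @return Unit-range targets (clamped at 0 below the training minimum).
#' @export
apply_pretext_scaling <- function(scaling, raw) {
  v <- if (scaling$log) log10(raw) else raw
  pmax((v - scaling$lo) / (scaling$hi - scaling$lo), 0)
}

#' Pre-train a dose-inference model (pretext task)
#'
#' Trains a dose-head backbone to regress the unit-scaled standardised dose
#' from patches of the pretext cohort, validating on a held-out patient
#' that must not belong to the cohort. Reports validation MAE on the
#' unit-scaled target, percentage exact agreement after assigning each
#' prediction to the nearest discrete fraction level, and the Spearman rank
#' correlation between per-volume mean predictions and the true count
#' fraction.
#'
#' @param cohort Pretext training `qc_cohort`.
#' @param config A [train_config()].
#' @param val_patient A single `qc_patient` (or length-1 `qc_cohort`) held
#'   out for validation.
#' @param spec A [backbone_spec()].
#' @param per_plane,size,n_candidates Patch extraction settings.
#' @param log_target Regress log10 standardised dose (default) or linear.
#' @return List: `model` (best checkpoint, dose head), `scaling`, `history`,
#'   `val_mae`, `val_exact_pct`, `val_spearman`, `val_predictions`.
#' @export
pretext_pretrain <- function(cohort, config = train_config(),
                             val_patient, spec = backbone_spec(),
                             per_plane = 8L, size = 32L,
                             n_candidates = 400L, log_target = TRUE) {
  if (inherits(val_patient, "qc_cohort")) {
    if (length(val_patient) != 1L) {
      stop("`val_patient` must be a single patient", call. = FALSE)
    }
    val_patient <- val_patient[[1]]
  }
  if (val_patient$patient_id %in% cohort_ids(cohort)) {
    stop("validation patient is part of the pretext cohort", call. = FALSE)
  }
  val_cohort <- structure(list(val_patient), class = "qc_cohort")
  tr <- build_patch_dataset(cohort, per_plane, size, n_candidates,
                            seed = derive_seed(config$seed, 11L),
                            target = "pretext")
  va <- build_patch_dataset(val_cohort, per_plane, size, n_candidates,
                            seed = derive_seed(config$seed, 12L),
                            target = "pretext")
  scaling <- pretext_scaling(tr$y[, 1], log = log_target)
  tr$y[, 1] <- apply_pretext_scaling(scaling, tr$y[, 1])
  va_raw <- va$y[, 1]
  va$y[, 1] <- apply_pretext_scaling(scaling, va_raw)
  model <- build_backbone(spec, head_spec("dose"), init = "random",
                          seed = derive_seed(config$seed, 13L))
  fit <- train(model, tr, va, config)
  pred <- predict.qc_model(fit$model, va$x)[, 1]
  # nearest-discrete-level assignment for exact agreement
  levels_raw <- sort(unique(va_raw))
  levels_scaled <- apply_pretext_scaling(scaling, levels_raw)
  nearest <- vapply(pred, function(p) {
    levels_scaled[which.min(abs(levels_scaled - p))]
  }, numeric(1))
  exact_pct <- 100 * mean(abs(nearest - va$y[, 1]) < 1e-9)
  per_vol <- tapply(pred, va$info$fraction, mean)
  rho <- spearman(as.numeric(per_vol), as.numeric(names(per_vol)))
  list(model = fit$model, scaling = scaling, history = fit$history,
       best_epoch = fit$best_epoch,
       val_mae = mean(abs(pred - va$y[, 1])),
       val_exact_pct = exact_pct, val_spearman = rho,
       val_predictions = data.frame(fraction = va$info$fraction,
                                    predicted = pred, target = va$y[, 1]))
}

#' Run a pre-training pipeline
#'
#' The four pipelines compared by the package:
#' * `"a"` — no pre-training: random initialisation, all five blocks and
#'   the clinical head trained.
#' * `"b"` — ImageNet pre-training (optional path; requires externally
#'   supplied VGG16 weights and fails explicitly without them).
#' * `"c"` — dose-inference pretext pre-training from random
#'   initialisation; the convolutional weights are then fixed (default
#'   freeze policy `k = 0`), the head replaced with the clinical head and
#'   trained.
#' * `"d"` — as `"c"` but starting from ImageNet weights (optional path,
#'   unavailable without the weight file).
#'
#' @param kind Pipeline: `"a"`, `"b"`, `"c"` or `"d"`.
#' @param clinical_train,clinical_val `qc_cohort`s for clinical training
#'   and validation (patient-disjoint).
#' @param pretext_cohort,pretext_val Pretext cohort and its validation
#'   patient (pipelines c/d); must be disjoint from all clinical patients.
#' @param config A [train_config()] for the clinical stage.
#' @param pretext_config Optional separate [train_config()] for the
#'   pretext stage (defaults to `config`).
#' @param freeze A [freeze_policy()] for the clinical stage of pipelines
#'   b/c/d; default `k = 0` for c/d (conv weights fully fixed).
#' @param spec A [backbone_spec()].
#' @param per_plane,size,n_candidates Patch extraction settings.
#' @param weights_file Optional VGG16 ImageNet weights (pipelines b/d).
#' @return List: `model` (trained clinical model), `history`,
#'   `best_epoch`, `kind`, plus `pretext` (the [pretext_pretrain()] result)
#'   for pipelines c/d.
#' @export
run_pipeline <- function(kind = c("a", "b", "c", "d"),
                         clinical_train, clinical_val,
                         pretext_cohort = NULL, pretext_val = NULL,
                         config = train_config(), pretext_config = NULL,
                         freeze = NULL, spec = backbone_spec(),
                         per_plane = 8L, size = 32L, n_candidates = 400L,
                         weights_file = NULL) {
  kind <- match.arg(kind)
  if (length(clinical_train) == 0L) {
    stop("clinical training cohort is empty", call. = FALSE)
  }
  pv <- if (!is.null(pretext_val) && inherits(pretext_val, "qc_patient")) {
    structure(list(pretext_val), class = "qc_cohort")
  } else pretext_val
  assert_split_hygiene(pretext = pretext_cohort, pretext_val = pv,
                       train = clinical_train, val = clinical_val)
  if (is.null(pretext_config)) pretext_config <- config
  tr <- build_patch_dataset(clinical_train, per_plane, size, n_candidates,
                            seed = derive_seed(config$seed, 21L),
                            target = "clinical")
  va <- build_patch_dataset(clinical_val, per_plane, size, n_candidates,
                            seed = derive_seed(config$seed, 22L),
                            target = "clinical")
  if (kind == "a") {
    model <- build_backbone(spec, head_spec("clinical"), init = "random",
                            seed = derive_seed(config$seed, 23L))
    model <- apply_freeze(model, freeze_policy(5L))
    fit <- train(model, tr, va, config)
    return(c(fit, list(kind = kind)))
  }
  if (kind %in% c("b", "d")) {
    # explicit unavailable-resource failure, never a silent fallback
    build_backbone(spec, head_spec("clinical"), init = "imagenet",
                   weights_file = weights_file)
  }
  # kind == "c": pretext pre-training, conv weights fixed by default
  if (is.null(pretext_cohort) || is.null(pretext_val)) {
    stop("pipeline c requires `pretext_cohort` and `pretext_val`",
         call. = FALSE)
  }
  pre <- pretext_pretrain(pretext_cohort, pretext_config, pretext_val,
                          spec, per_plane, size, n_candidates)
  model <- replace_head(pre$model, head_spec("clinical"),
                        seed = derive_seed(config$seed, 24L))
  model <- apply_freeze(model, if (is.null(freeze)) freeze_policy(0L)
                               else freeze)
  fit <- train(model, tr, va, config)
  c(fit, list(kind = kind, pretext = pre))
}
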