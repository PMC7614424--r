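# Sweep orchestration: freeze-depth sweep, transfer-patient-count sweep,
# and the pipeline comparison. All sweeps share seed management
# (derive_seed(master, level_index, run)) and emit long-format tables with
# per-run seeds, split membership and a config hash.

#' Sweep specification
#'
#' @param kind `"freeze_blocks"`, `"n_patients"` or `"pipelines"`.
#' @param levels Levels swept: subset of 0..5 for `freeze_blocks`, of
#'   1..`n(train cohort)` for `n_patients`, or pipeline labels such as
#'   `"a@1e-3"`, `"a@1e-4"`, `"c"` for `pipelines`.
#' @param n_runs Independent training runs per level (default 5).
#' @param master_seed Master seed; per-run seeds are derived from it.
#' @param config Base [train_config()].
#' @param spec [backbone_spec()].
#' @param per_plane,size,n_candidates Patch extraction settings.
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(kind = c("freeze_blocks", "n_patients", "pipelines"),
                       levels, n_runs = 5L, master_seed = 1L,
                       config = train_config(), spec = backbone_spec(),
                       per_plane = 8L, size = 32L, n_candidates = 400L) {
  kind <- match.arg(kind)
  if (kind == "freeze_blocks" && !all(levels %in% 0:5)) {
    stop("freeze_blocks levels must lie in 0..5", call. = FALSE)
  }
  if (kind == "n_patients" && any(levels < 1)) {
    stop("n_patients levels must be >= 1", call. = FALSE)
  }
  structure(
    list(kind = kind, levels = levels, n_runs = as.integer(n_runs),
         master_seed = as.integer(master_seed), config = config,
         spec = spec, per_plane = as.integer(per_plane),
         size = as.integer(size), n_candidates = as.integer(n_candidates)),
    class = "sweep_spec"
  )
}

check_cohorts <- function(cohorts, need_pretext = TRUE) {
  need <- c("train", "val", "test", if (need_pretext) c("pretext",
                                                        "pretext_val"))
  miss <- setdiff(need, names(cohorts))
  if (length(miss) > 0) {
    stop("`cohorts` must contain: ", paste(need, collapse = ", "),
         " (missing: ", paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  do.call(assert_split_hygiene, cohorts[need])
  invisible(TRUE)
}

sweep_row <- function(level, run, seed, report, splits, cfg_hash) {
  data.frame(level = level, run = run, seed = seed, report,
             train_ids = splits["train"], val_ids = splits["val"],
             test_ids = splits["test"], config_hash = cfg_hash,
             row.names = NULL)
}

split_ids_label <- function(cohorts) {
  c(train = paste(cohort_ids(cohorts$train), collapse = "+"),
    val = paste(cohort_ids(cohorts$val), collapse = "+"),
    test = paste(cohort_ids(cohorts$test), collapse = "+"))
}

run_config <- function(base, seed) {
  train_config(learning_rate = base$learning_rate,
               batch_size = base$batch_size, max_epochs = base$max_epochs,
               seed = seed, verbose = base$verbose)
}

#' Freeze-depth sweep
#'
#' For each level `k` (number of trainable last blocks) the pretext
#' pre-trained backbone is transfer-learned `n_runs` times with a fresh
#' clinical head, frozen first `5 - k` blocks, and evaluated on the fixed
#' test cohort. The pretext model is trained once per sweep (its own
#' derived seed).
#'
#' @param spec A [sweep_spec()] with kind `"freeze_blocks"`.
#' @param cohorts Named list of `qc_cohort`s: `pretext`, `pretext_val`,
#'   `train`, `val`, `test` (patient-disjoint).
#' @return Long-format data frame: one row per (level, run, metric) with
#'   the agreement metrics, the run seed, split ids and config hash.
#' @export
run_freeze_sweep <- function(spec, cohorts) {
  stopifnot(inherits(spec, "sweep_spec"), spec$kind == "freeze_blocks")
  check_cohorts(cohorts)
  if (length(cohorts$train) < 1L || length(cohorts$val) < 1L ||
      length(cohorts$test) < 1L) {
    stop("need >= 1 train, 1 val and 1 test patient", call. = FALSE)
  }
  cfg_hash <- config_hash(spec[c("config", "spec", "per_plane", "size",
                                 "n_candidates")])
  pre <- pretext_pretrain(cohorts$pretext,
                          run_config(spec$config,
                                     derive_seed(spec$master_seed, 99L)),
                          cohorts$pretext_val, spec$spec, spec$per_plane,
                          spec$size, spec$n_candidates)
  tr <- build_patch_dataset(cohorts$train, spec$per_plane, spec$size,
                            spec$n_candidates,
                            seed = derive_seed(spec$master_seed, 98L),
                            target = "clinical")
  va <- build_patch_dataset(cohorts$val, spec$per_plane, spec$size,
                            spec$n_candidates,
                            seed = derive_seed(spec$master_seed, 97L),
                            target = "clinical")
  labels <- split_ids_label(cohorts)
  out <- list()
  for (li in seq_along(spec$levels)) {
    k <- spec$levels[li]
    for (run in seq_len(spec$n_runs)) {
      seed <- derive_seed(spec$master_seed, li, run)
      model <- replace_head(pre$model, head_spec("clinical"), seed = seed)
      model <- apply_freeze(model, freeze_policy(k))
      fit <- train(model, tr, va, run_config(spec$config, seed))
      preds <- evaluate_on_cohort(fit$model, cohorts$test, spec$per_plane,
                                  spec$size, spec$n_candidates, seed = seed)
      out[[length(out) + 1L]] <- sweep_row(k, run, seed, eval_report(preds),
                                           labels, cfg_hash)
    }
  }
  do.call(rbind, out)
}

#' Transfer-patient-count sweep
#'
#' Sweeps the number of patients in the transfer-learning dataset. Patient
#' subsets are nested (n=1 is contained in n=2, etc.) to reduce
#' between-level variance; the freeze policy is fixed at the last two
#' blocks trainable. The pretext backbone is trained once per sweep.
#'
#' @param spec A [sweep_spec()] with kind `"n_patients"`.
#' @param cohorts As in [run_freeze_sweep()].
#' @param trainable_blocks Freeze level used at every sweep point
#'   (default 2: last two blocks + head).
#' @return Long-format results data frame as in [run_freeze_sweep()].
#' @export
run_patient_sweep <- function(spec, cohorts, trainable_blocks = 2L) {
  stopifnot(inherits(spec, "sweep_spec"), spec$kind == "n_patients")
  check_cohorts(cohorts)
  if (max(spec$levels) > length(cohorts$train)) {
    stop(sprintf("level %d exceeds the %d available training patients",
                 max(spec$levels), length(cohorts$train)), call. = FALSE)
  }
  cfg_hash <- config_hash(spec[c("config", "spec", "per_plane", "size",
                                 "n_candidates")])
  pre <- pretext_pretrain(cohorts$pretext,
                          run_config(spec$config,
                                     derive_seed(spec$master_seed, 99L)),
                          cohorts$pretext_val, spec$spec, spec$per_plane,
                          spec$size, spec$n_candidates)
  # fixed nested patient order, shuffled once by the master seed
  ord <- with_seed(derive_seed(spec$master_seed, 96L),
                   sample.int(length(cohorts$train)))
  va <- build_patch_dataset(cohorts$val, spec$per_plane, spec$size,
                            spec$n_candidates,
                            seed = derive_seed(spec$master_seed, 97L),
                            target = "clinical")
  out <- list()
  for (li in seq_along(spec$levels)) {
    n_pat <- spec$levels[li]
    sub <- cohorts$train[ord[seq_len(n_pat)]]
    tr <- build_patch_dataset(sub, spec$per_plane, spec$size,
                              spec$n_candidates,
                              seed = derive_seed(spec$master_seed, 95L, li),
                              target = "clinical")
    labels <- split_ids_label(list(train = sub, val = cohorts$val,
                                   test = cohorts$test))
    for (run in seq_len(spec$n_runs)) {
      seed <- derive_seed(spec$master_seed, li, run)
      model <- replace_head(pre$model, head_spec("clinical"), seed = seed)
      model <- apply_freeze(model, freeze_policy(trainable_blocks))
      fit <- train(model, tr, va, run_config(spec$config, seed))
      preds <- evaluate_on_cohort(fit$model, cohorts$test, spec$per_plane,
                                  spec$size, spec$n_candidates, seed = seed)
      out[[length(out) + 1L]] <- sweep_row(n_pat, run, seed,
                                           eval_report(preds), labels,
                                           cfg_hash)
    }
  }
  do.call(rbind, out)
}

# Parse a pipeline level label: "a", "a@1e-3", "c", "c@1e-4", ...
parse_pipeline_level <- function(label) {
  parts <- strsplit(label, "@", fixed = TRUE)[[1]]
  list(kind = parts[1],
       lr = if (length(parts) > 1) as.numeric(parts[2]) else NA_real_)
}

#' Pipeline comparison
#'
#' Trains and evaluates each requested pipeline `n_runs` times on fixed
#' cohorts. Levels are labels like `"a@1e-3"`, `"a@1e-4"`, `"c"` (an
#' optional `@lr` suffix overrides the learning rate of the clinical
#' stage). Pipelines b/d require ImageNet weights and fail explicitly when
#' unavailable. For pipeline c the pretext backbone is trained once per
#' sweep and shared across runs; each run re-initialises the clinical head
#' and retrains under the c freeze policy (conv weights fixed).
#'
#' @param spec A [sweep_spec()] with kind `"pipelines"`.
#' @param cohorts As in [run_freeze_sweep()] (pretext entries needed only
#'   when a c/d pipeline is requested).
#' @param c_epochs Epochs for the head-only clinical stage of pipeline c
#'   (head-only training is cheap, so more epochs are affordable;
#'   default 300).
#' @return Long-format results data frame; `level` is the pipeline label.
#' @export
run_pipeline_comparison <- function(spec, cohorts, c_epochs = 300L) {
  stopifnot(inherits(spec, "sweep_spec"), spec$kind == "pipelines")
  kinds <- vapply(spec$levels, function(l) parse_pipeline_level(l)$kind,
                  character(1))
  need_pretext <- any(kinds %in% c("c", "d"))
  check_cohorts(cohorts, need_pretext = need_pretext)
  cfg_hash <- config_hash(spec[c("config", "spec", "per_plane", "size",
                                 "n_candidates")])
  tr <- build_patch_dataset(cohorts$train, spec$per_plane, spec$size,
                            spec$n_candidates,
                            seed = derive_seed(spec$master_seed, 98L),
                            target = "clinical")
  va <- build_patch_dataset(cohorts$val, spec$per_plane, spec$size,
                            spec$n_candidates,
                            seed = derive_seed(spec$master_seed, 97L),
                            target = "clinical")
  pre <- NULL
  if (need_pretext) {
    pre <- pretext_pretrain(cohorts$pretext,
                            run_config(spec$config,
                                       derive_seed(spec$master_seed, 99L)),
                            cohorts$pretext_val, spec$spec, spec$per_plane,
                            spec$size, spec$n_candidates)
  }
  labels <- split_ids_label(cohorts)
  out <- list()
  for (li in seq_along(spec$levels)) {
    lv <- parse_pipeline_level(spec$levels[li])
    for (run in seq_len(spec$n_runs)) {
      seed <- derive_seed(spec$master_seed, li, run)
      lr <- if (is.na(lv$lr)) spec$config$learning_rate else lv$lr
      if (lv$kind == "a") {
        cfg <- train_config(learning_rate = lr,
                            batch_size = spec$config$batch_size,
                            max_epochs = spec$config$max_epochs, seed = seed)
        model <- build_backbone(spec$spec, head_spec("clinical"),
                                seed = derive_seed(seed, 1L))
        fit <- train(apply_freeze(model, freeze_policy(5L)), tr, va, cfg)
      } else if (lv$kind == "c") {
        cfg <- train_config(learning_rate = lr,
                            batch_size = spec$config$batch_size,
                            max_epochs = as.integer(c_epochs), seed = seed)
        model <- replace_head(pre$model, head_spec("clinical"),
                              seed = derive_seed(seed, 1L))
        fit <- train(apply_freeze(model, freeze_policy(0L)), tr, va, cfg)
      } else {
        # pipelines b/d need the optional ImageNet weight file
        build_backbone(spec$spec, head_spec("clinical"), init = "imagenet")
      }
      preds <- evaluate_on_cohort(fit$model, cohorts$test, spec$per_plane,
                                  spec$size, spec$n_candidates, seed = seed)
      out[[length(out) + 1L]] <- sweep_row(spec$levels[li], run, seed,
                                           eval_report(preds), labels,
                                           cfg_hash)
    }
  }
  do.call(rbind, out)
}
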