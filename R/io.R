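# Disk formats: NIfTI volumes, cohort manifests, patch-set containers and
# YAML configuration.

#' Write a volume as NIfTI-1
#'
#' @param volume A 3-D array or `activity_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel dimensions; taken from an `activity_volume`
#'   automatically.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(2.5, 2.5, 2.5)) {
  if (inherits(volume, "activity_volume")) {
    voxel_size_mm <- volume$voxel_size_mm
    volume <- volume$voxels
  }
  img <- RNifti::asNifti(volume, pixdim = voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A numeric array.
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a cohort to disk (NIfTI volumes + CSV manifest)
#'
#' The manifest has one row per (patient, fraction) with columns
#' `patient_id`, `weight_kg`, `fraction`, `volume_path`, `gqr`, `pr`,
#' `dc`, `seed`.
#'
#' @param cohort A `qc_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in cohort) {
    for (fr in p$fractions) {
      fn <- sprintf("%s_f%s.nii.gz", p$patient_id,
                    gsub("\\.", "p", format(fr$fraction)))
      write_volume(fr$volume, file.path(dir, fn),
                   voxel_size_mm = p$activity$voxel_size_mm)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, weight_kg = p$weight_kg,
        fraction = fr$fraction, volume_path = fn,
        gqr = fr$scores[["gqr"]], pr = fr$scores[["pr"]],
        dc = fr$scores[["dc"]], seed = p$seed
      )
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest (and optionally its volumes)
#'
#' @param manifest Path to a `manifest.csv` written by [write_cohort()].
#' @param load_volumes Also read the NIfTI volumes into a `qc_cohort`
#'   structure (without ground-truth activity).
#' @return The manifest data frame, or a `qc_cohort` when
#'   `load_volumes = TRUE`.
#' @export
read_cohort <- function(manifest, load_volumes = FALSE) {
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!load_volumes) return(df)
  dir <- dirname(manifest)
  patients <- lapply(split(df, df$patient_id), function(pd) {
    fractions <- lapply(seq_len(nrow(pd)), function(i) {
      list(fraction = pd$fraction[i],
           volume = read_volume(file.path(dir, pd$volume_path[i])),
           scores = c(gqr = pd$gqr[i], pr = pd$pr[i], dc = pd$dc[i]))
    })
    structure(list(patient_id = pd$patient_id[1],
                   weight_kg = pd$weight_kg[1],
                   full_counts = NA_real_, seed = pd$seed[1],
                   activity = NULL, fractions = fractions),
              class = "qc_patient")
  })
  structure(unname(patients[order(names(patients))]), class = "qc_cohort")
}

#' Write a patch set (array container + CSV index)
#'
#' Pixels go to `<prefix>.nii.gz` (size x size x n array) and the index to
#' `<prefix>.csv` with columns `patient_id`, `fraction`, `plane`, `slice`,
#' `row`, `col`.
#'
#' @param ps A `patch_set`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_patch_set <- function(ps, prefix) {
  RNifti::writeNifti(RNifti::asNifti(ps$pixels),
                     paste0(prefix, ".nii.gz"))
  write.csv(ps$info[c("patient_id", "fraction", "plane", "slice", "row",
                      "col")],
            paste0(prefix, ".csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a patch set written by [write_patch_set()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `patch_set`.
#' @export
read_patch_set <- function(prefix) {
  px <- read_volume(paste0(prefix, ".nii.gz"))
  info <- read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  structure(list(pixels = px, info = info, size = dim(px)[1]),
            class = "patch_set")
}

#' Load a YAML configuration
#'
#' Reads a YAML file with optional `synthetic:`, `patches:`, `backbone:`
#' and `training:` blocks and merges it over the package defaults.
#'
#' @param path Path to a YAML file (NULL returns the defaults).
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    synthetic = list(shape = c(96, 96, 64), n_patients = 7,
                     fractions_per_patient = 3, seed = 1),
    patches = list(n_candidates = 1000, size = 80, per_plane = 100),
    backbone = list(base_width = 8, input_size = 32),
    training = list(learning_rate = 1e-4, batch_size = 10,
                    max_epochs = 50, seed = 1)
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  for (block in names(user)) {
    for (key in names(user[[block]])) {
      defaults[[block]][[key]] <- user[[block]][[key]]
    }
  }
  defaults
}

#' Save a trained model checkpoint
#'
#' Parameters are saved in R's native serialisation alongside a JSON
#' sidecar recording the backbone spec, head spec, freeze policy and seed.
#'
#' @param model A `qc_model`.
#' @param prefix Output path prefix (`<prefix>.rds` + `<prefix>.json`).
#' @return `prefix`, invisibly.
#' @export
save_checkpoint <- function(model, prefix) {
  saveRDS(model, paste0(prefix, ".rds"))
  side <- list(
    spec = model$spec[c("n_blocks", "convs_per_block", "base_width",
                        "input_size", "input_channels")],
    head = model$head[c("kind", "outputs", "activation")],
    freeze = list(trainable_last_k_blocks =
                    model$freeze$trainable_last_k_blocks),
    seed = model$seed, n_params = n_params(model)
  )
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(prefix)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#'
#' @param prefix Path prefix.
#' @return A `qc_model`.
#' @export
load_checkpoint <- function(prefix) {
  readRDS(paste0(prefix, ".rds"))
}
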