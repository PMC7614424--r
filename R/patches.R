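# Patch extraction, background thresholding and balanced plane sampling.

PLANES <- c("transverse", "sagittal", "coronal")

# Dimensions of the 2-D slice grid for each plane of an (nx, ny, nz) volume.
plane_dims <- function(shape, plane) {
  switch(plane,
    transverse = c(shape[1], shape[2], nslices = shape[3]),
    sagittal   = c(shape[2], shape[3], nslices = shape[1]),
    coronal    = c(shape[1], shape[3], nslices = shape[2]),
    stop("unknown plane: ", plane, call. = FALSE)
  )
}

# Extract one square window. `row`/`col` are the top-left corner (1-based)
# within the plane's 2-D slice grid.
get_patch_pixels <- function(volume, plane, slice, row, col, size) {
  rr <- row:(row + size - 1L)
  cc <- col:(col + size - 1L)
  switch(plane,
    transverse = volume[rr, cc, slice],
    sagittal   = volume[slice, rr, cc],
    coronal    = volume[rr, slice, cc]
  )
}

#' Resolve a feasible patch size for a volume
#'
#' The clinical-grid default of 80 pixels is reduced (with a warning) to the
#' largest multiple of 16 that fits every plane when the volume is smaller
#' than the requested patch.
#'
#' @param shape Volume shape `(nx, ny, nz)`.
#' @param size Requested patch size.
#' @return Feasible patch size (integer).
#' @export
resolve_patch_size <- function(shape, size = 80L) {
  feasible <- min(shape)
  if (size <= feasible) return(as.integer(size))
  new_size <- 16L * (feasible %/% 16L)
  if (new_size < 16L) {
    stop("no feasible patch size: smallest volume dimension is ", feasible,
         call. = FALSE)
  }
  warning(sprintf("patch size reduced from %d to %d to fit volume %s",
                  size, new_size, paste(shape, collapse = "x")),
          call. = FALSE)
  new_size
}

#' Draw candidate patches uniformly over plane, slice and corner
#'
#' Candidates are drawn with replacement: the plane is chosen uniformly
#' among transverse, sagittal and coronal, then a valid slice and top-left
#' corner uniformly within bounds, so the candidates cover the whole 3-D
#' volume.
#'
#' @param volume A normalised 3-D array.
#' @param n Number of candidates (default 1000).
#' @param size Patch size in pixels; see [resolve_patch_size()].
#' @param seed Integer seed.
#' @return Data frame with columns `plane`, `slice`, `row`, `col`, `size`.
#' @export
extract_candidates <- function(volume, n = 1000L, size = 80L, seed = 1L) {
  shape <- dim(volume)
  size <- resolve_patch_size(shape, size)
  if (n == 0L) {
    return(data.frame(plane = character(0), slice = integer(0),
                      row = integer(0), col = integer(0),
                      size = integer(0)))
  }
  with_seed(seed, {
    plane <- sample(PLANES, n, replace = TRUE)
    out <- data.frame(plane = plane, slice = NA_integer_,
                      row = NA_integer_, col = NA_integer_,
                      size = as.integer(size))
    for (pl in PLANES) {
      sel <- which(plane == pl)
      if (length(sel) == 0) next
      pd <- plane_dims(shape, pl)
      out$slice[sel] <- sample.int(pd[3], length(sel), replace = TRUE)
      out$row[sel] <- sample.int(pd[1] - size + 1L, length(sel),
                                 replace = TRUE)
      out$col[sel] <- sample.int(pd[2] - size + 1L, length(sel),
                                 replace = TRUE)
    }
    out
  })
}

#' Background threshold rule for a patch
#'
#' A patch survives when its mean pixel value is at least one-eighth of the
#' mean value of the whole image volume; equality survives. Patches below
#' the threshold are treated as background.
#'
#' @param patch_pixels 2-D pixel matrix (or any numeric array).
#' @param volume_mean Mean pixel value of the whole volume (positive).
#' @return TRUE if the patch passes (is foreground).
#' @export
passes_background_threshold <- function(patch_pixels, volume_mean) {
  stopifnot_scalar_number(volume_mean, "volume_mean", positive = TRUE)
  mean(patch_pixels) >= volume_mean / 8
}

# Mean pixel value of each candidate (vectorised over the candidate table).
candidate_means <- function(volume, cand) {
  vapply(seq_len(nrow(cand)), function(i) {
    mean(get_patch_pixels(volume, cand$plane[i], cand$slice[i],
                          cand$row[i], cand$col[i], cand$size[i]))
  }, numeric(1))
}

#' Balanced per-plane sampling of surviving patches
#'
#' Keeps candidates that pass the background threshold, removes duplicated
#' locations, and samples `per_plane` patches without replacement from each
#' plane. When a plane has fewer survivors than requested and `volume` is
#' supplied, fresh candidates are drawn for that plane until it fills
#' (bounded at `50 * per_plane` redraw attempts); otherwise the shortfall is
#' an error naming the plane.
#'
#' @param candidates Candidate table from [extract_candidates()].
#' @param per_plane Patches to keep per plane (default 100, i.e. 300 total).
#' @param seed Integer seed.
#' @param volume The volume the candidates were drawn from (needed to
#'   evaluate the threshold and materialise pixels).
#' @param volume_mean Mean of the whole volume; computed from `volume` when
#'   omitted.
#' @param top_up Redraw fresh candidates for a plane that falls short of
#'   `per_plane` survivors (default TRUE); with `top_up = FALSE` a
#'   shortfall is an error naming the plane.
#' @return A `patch_set`: list with `pixels` (size x size x n array),
#'   `info` data frame and `size`.
#' @export
sample_balanced <- function(candidates, per_plane = 100L, seed = 1L,
                            volume = NULL, volume_mean = NULL,
                            top_up = TRUE) {
  if (per_plane == 0L) {
    info <- data.frame(plane = character(0), slice = integer(0),
                       row = integer(0), col = integer(0))
    return(new_patch_set(array(0, dim = c(0, 0, 0)), info, 0L))
  }
  if (nrow(candidates) == 0L) stop("no candidates supplied", call. = FALSE)
  if (is.null(volume)) {
    stop("`volume` is required to threshold and extract patches",
         call. = FALSE)
  }
  size <- candidates$size[1]
  if (is.null(volume_mean)) volume_mean <- mean(volume)
  pass <- candidate_means(volume, candidates) >= volume_mean / 8
  surv <- candidates[pass, , drop = FALSE]
  picked <- with_seed(seed, {
    rows <- list()
    for (pl in PLANES) {
      pool <- surv[surv$plane == pl, , drop = FALSE]
      pool <- pool[!duplicated(pool[c("slice", "row", "col")]), ,
                   drop = FALSE]
      if (nrow(pool) >= per_plane) {
        rows[[pl]] <- pool[sample.int(nrow(pool), per_plane), ,
                           drop = FALSE]
        next
      }
      if (!top_up) {
        stop(sprintf(
          "plane '%s' has only %d surviving patches (need %d); top-up disabled",
          pl, nrow(pool), per_plane), call. = FALSE)
      }
      # top-up: draw fresh candidates for this plane until filled
      pd <- plane_dims(dim(volume), pl)
      attempts <- 0L
      max_attempts <- 50L * per_plane
      while (nrow(pool) < per_plane && attempts < max_attempts) {
        k <- min(max_attempts - attempts, per_plane * 4L)
        fresh <- data.frame(
          plane = pl,
          slice = sample.int(pd[3], k, replace = TRUE),
          row = sample.int(pd[1] - size + 1L, k, replace = TRUE),
          col = sample.int(pd[2] - size + 1L, k, replace = TRUE),
          size = as.integer(size)
        )
        attempts <- attempts + k
        ok <- candidate_means(volume, fresh) >= volume_mean / 8
        pool <- rbind(pool[names(fresh)], fresh[ok, , drop = FALSE])
        pool <- pool[!duplicated(pool[c("slice", "row", "col")]), ,
                     drop = FALSE]
      }
      if (nrow(pool) < per_plane) {
        stop(sprintf(
          "plane '%s': could not find %d foreground patches after %d redraws",
          pl, per_plane, attempts), call. = FALSE)
      }
      rows[[pl]] <- pool[sample.int(nrow(pool), per_plane), , drop = FALSE]
    }
    do.call(rbind, rows)
  })
  rownames(picked) <- NULL
  px <- array(0, dim = c(size, size, nrow(picked)))
  for (i in seq_len(nrow(picked))) {
    px[, , i] <- get_patch_pixels(volume, picked$plane[i], picked$slice[i],
                                  picked$row[i], picked$col[i], size)
  }
  new_patch_set(px, picked[c("plane", "slice", "row", "col")], size)
}

new_patch_set <- function(pixels, info, size, patient_id = NA_character_,
                          fraction = NA_real_) {
  info$patient_id <- rep(patient_id, nrow(info))
  info$fraction <- rep(fraction, nrow(info))
  structure(list(pixels = pixels, info = info, size = as.integer(size)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  tab <- table(x$info$plane)
  cat(sprintf("<patch_set> %d patches of %dx%d (%s)\n", nrow(x$info),
              x$size, x$size,
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Extract a balanced foreground patch set from one volume
#'
#' Full per-volume pipeline: draw `n_candidates` random patches, reject
#' background by the one-eighth-of-volume-mean rule, and sample `per_plane`
#' survivors from each of the three anatomical planes.
#'
#' @param volume Normalised 3-D array.
#' @param n_candidates Candidates drawn before thresholding (default 1000).
#' @param size Patch size (default 80; auto-reduced for small volumes).
#' @param per_plane Patches kept per plane (default 100).
#' @param seed Integer seed.
#' @param patient_id,fraction Provenance stored in the patch index.
#' @return A `patch_set`.
#' @export
extract_patches <- function(volume, n_candidates = 1000L, size = 80L,
                            per_plane = 100L, seed = 1L,
                            patient_id = NA_character_,
                            fraction = NA_real_) {
  cand <- extract_candidates(volume, n_candidates, size,
                             seed = derive_seed(seed, 1L))
  ps <- sample_balanced(cand, per_plane, seed = derive_seed(seed, 2L),
                        volume = volume)
  ps$info$patient_id <- patient_id
  ps$info$fraction <- fraction
  ps
}

#' Replicate a greyscale patch into three identical channels
#'
#' The VGG-style backbone takes three-channel inputs; greyscale patches are
#' replicated along the channel axis.
#'
#' @param patch_pixels 2-D matrix (size x size).
#' @return 3-D array (size x size x 3) with identical channels.
#' @export
to_three_channel <- function(patch_pixels) {
  array(patch_pixels, dim = c(dim(patch_pixels), 3L))
}

# Batch version: (H, W, N) -> (H, W, 3, N).
batch_three_channel <- function(px) {
  d <- dim(px)
  out <- array(0, dim = c(d[1], d[2], 3L, d[3]))
  for (c in 1:3) out[, , c, ] <- px
  out
}
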