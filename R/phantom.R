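#' Anatomy parameters for the brain phantom
#'
#' Describes the compartments of the synthetic brain-like activity phantom:
#' a head ellipsoid containing a high-uptake cortical shell, a white-matter
#' interior, and two low-uptake ventricles. Uptake values are relative
#' expected-count densities (arbitrary units); everything outside the head
#' ellipsoid is exactly zero.
#'
#' @param head_radius_frac Ellipsoid semi-axes as a fraction of each half
#'   grid extent (length 3, values in (0, 1]).
#' @param cortex_frac Normalised radius above which a voxel belongs to the
#'   cortical shell (in (0, 1)).
#' @param uptake_cortex,uptake_white,uptake_ventricle Relative uptake of the
#'   three compartments; must be positive. Defaults follow typical FDG
#'   grey:white contrast with near-photopenic ventricles.
#' @param ventricle_radius_frac Ventricle semi-axes as a fraction of the head
#'   semi-axes (length 3).
#' @param ventricle_offset_frac Offset of each ventricle centre from the head
#'   centre along x, as a fraction of the head x semi-axis.
#' @param texture_sd Standard deviation of multiplicative voxel texture
#'   (0 disables texture; the cohort generator enables a small amount so
#'   patients are not piecewise constant).
#' @return An object of class `anatomy_params`.
#' @export
anatomy_params <- function(head_radius_frac = c(0.8, 0.8, 0.8),
                           cortex_frac = 0.78,
                           uptake_cortex = 4,
                           uptake_white = 1,
                           uptake_ventricle = 0.25,
                           ventricle_radius_frac = c(0.16, 0.32, 0.22),
                           ventricle_offset_frac = 0.2,
                           texture_sd = 0) {
  if (length(head_radius_frac) != 3L || any(head_radius_frac <= 0) ||
      any(head_radius_frac > 1)) {
    stop("`head_radius_frac` must be 3 values in (0, 1]", call. = FALSE)
  }
  ups <- c(uptake_cortex, uptake_white, uptake_ventricle)
  if (any(!is.finite(ups)) || any(ups <= 0)) {
    stop("compartment uptakes must be positive", call. = FALSE)
  }
  if (cortex_frac <= 0 || cortex_frac >= 1) {
    stop("`cortex_frac` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      head_radius_frac = head_radius_frac,
      cortex_frac = cortex_frac,
      uptake_cortex = uptake_cortex,
      uptake_white = uptake_white,
      uptake_ventricle = uptake_ventricle,
      ventricle_radius_frac = ventricle_radius_frac,
      ventricle_offset_frac = ventricle_offset_frac,
      texture_sd = texture_sd
    ),
    class = "anatomy_params"
  )
}

#' Generate a brain-like activity phantom
#'
#' Builds a 3-D nonnegative expected-count density with the compartment
#' structure of [anatomy_params()]: zero outside the head ellipsoid, a
#' cortical shell of highest uptake, lower white-matter uptake inside, and
#' two photopenic ventricles. Deterministic given `seed` (the seed only
#' matters when `texture_sd > 0`).
#'
#' @param seed Integer seed.
#' @param shape Grid shape `(nx, ny, nz)`; each component must be >= 32.
#' @param anatomy An [anatomy_params()] object.
#' @param voxel_size_mm Voxel edge lengths in millimetres (length 3).
#' @return An `activity_volume`: list with `voxels` (3-D array),
#'   `voxel_size_mm` and the generating `anatomy` and `seed`.
#' @export
generate_phantom <- function(seed, shape = c(96, 96, 64),
                             anatomy = anatomy_params(),
                             voxel_size_mm = c(2.5, 2.5, 2.5)) {
  if (length(shape) != 3L || any(shape < 32)) {
    stop("`shape` must have 3 components, each >= 32", call. = FALSE)
  }
  if (!inherits(anatomy, "anatomy_params")) {
    anatomy <- do.call(anatomy_params, anatomy)
  }
  shape <- as.integer(shape)
  ctr <- (shape + 1) / 2
  rad <- anatomy$head_radius_frac * shape / 2
  # normalised radius from head centre for every voxel
  gx <- (seq_len(shape[1]) - ctr[1]) / rad[1]
  gy <- (seq_len(shape[2]) - ctr[2]) / rad[2]
  gz <- (seq_len(shape[3]) - ctr[3]) / rad[3]
  rho2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  vox <- array(0, dim = shape)
  inside <- rho2 <= 1
  shell <- inside & rho2 > anatomy$cortex_frac^2
  vox[inside] <- anatomy$uptake_white
  vox[shell] <- anatomy$uptake_cortex
  # two ventricles, offset +/- along x
  vrad <- anatomy$ventricle_radius_frac * rad
  for (s in c(-1, 1)) {
    vc <- ctr + c(s * anatomy$ventricle_offset_frac * rad[1], 0, 0)
    vx <- (seq_len(shape[1]) - vc[1]) / vrad[1]
    vy <- (seq_len(shape[2]) - vc[2]) / vrad[2]
    vz <- (seq_len(shape[3]) - vc[3]) / vrad[3]
    vrho2 <- outer(outer(vx^2, vy^2, `+`), vz^2, `+`)
    vox[inside & vrho2 <= 1] <- anatomy$uptake_ventricle
  }
  if (anatomy$texture_sd > 0) {
    tex <- with_seed(seed, {
      array(rnorm(prod(shape), 1, anatomy$texture_sd), dim = shape)
    })
    vox <- vox * pmax(tex, 0)
  }
  structure(
    list(voxels = vox, voxel_size_mm = voxel_size_mm,
         anatomy = anatomy, seed = as.integer(seed)),
    class = "activity_volume"
  )
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<activity_volume> %d x %d x %d voxels (%.1f x %.1f x %.1f mm), %.0f%% background\n",
    d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
    x$voxel_size_mm[3], 100 * mean(x$voxels == 0)
  ))
  invisible(x)
}

# Separable 3-D Gaussian smoothing with zero padding, kernel truncated at
# 4 sigma. sigma_vox is per-axis in voxel units; axes with sigma ~ 0 are
# skipped. Operates on a plain 3-D array.
gaussian_smooth_3d <- function(x, sigma_vox) {
  d <- dim(x)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-3) next
    r <- min(d[ax] - 1L, ceiling(4 * s))
    k <- dnorm(-r:r, sd = s)
    k <- k / sum(k)
    n <- d[ax]
    # banded convolution matrix (zero padding outside)
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n - abs(off))
      if (off >= 0) K[cbind(idx + off, idx)] <- k[off + r + 1]
      else K[cbind(idx, idx - off)] <- k[off + r + 1]
    }
    if (ax == 1) {
      x <- array(K %*% matrix(x, nrow = n), dim = d)
    } else if (ax == 2) {
      xp <- aperm(x, c(2, 1, 3))
      xp <- array(K %*% matrix(xp, nrow = n), dim = dim(xp))
      x <- aperm(xp, c(2, 1, 3))
    } else {
      xp <- aperm(x, c(3, 1, 2))
      xp <- array(K %*% matrix(xp, nrow = n), dim = dim(xp))
      x <- aperm(xp, c(2, 3, 1))
    }
  }
  x
}

#' Resolution model for count thinning
#'
#' Full-width-at-half-maximum of the Gaussian resolution kernel applied
#' after thinning, as a function of the count fraction: lower count
#' fractions are reconstructed with more smoothing, emulating the joint
#' noise increase and resolution loss of low-dose reconstructions.
#'
#' @param fraction Count fraction in (0, 1].
#' @param fwhm_full_mm FWHM at the full count level (mm).
#' @param fwhm_slope_mm Additional FWHM per decade of count reduction (mm).
#' @return FWHM in millimetres.
#' @export
dose_fwhm_mm <- function(fraction, fwhm_full_mm = 4, fwhm_slope_mm = 3) {
  fwhm_full_mm + fwhm_slope_mm * (-log10(fraction))
}

#' Simulate a reduced-count acquisition of an activity volume
#'
#' Emulates list-mode count thinning in image space: every voxel receives an
#' independent Poisson draw with mean `fraction * full_counts *
#' activity / sum(activity)`, and the resulting count image is smoothed with
#' a fraction-dependent Gaussian kernel ([dose_fwhm_mm()]) so that low count
#' fractions show both higher noise and lower resolution. The expected total
#' count of the returned volume is `fraction * full_counts`.
#'
#' @param activity An [generate_phantom()] `activity_volume` (or a plain
#'   nonnegative 3-D array, in which case `voxel_size_mm` applies).
#' @param full_counts Total expected counts of the full (100%) acquisition.
#' @param fraction Count fraction in (0, 1].
#' @param seed Integer seed for the Poisson draw.
#' @param fwhm_full_mm,fwhm_slope_mm Resolution model, see [dose_fwhm_mm()].
#' @param voxel_size_mm Used only when `activity` is a plain array.
#' @return A 3-D array of smoothed counts (not normalised).
#' @export
simulate_dose_fraction <- function(activity, full_counts, fraction, seed,
                                   fwhm_full_mm = 4, fwhm_slope_mm = 3,
                                   voxel_size_mm = c(2.5, 2.5, 2.5)) {
  stopifnot_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(full_counts, "full_counts", positive = TRUE)
  if (inherits(activity, "activity_volume")) {
    vox <- activity$voxels
    voxel_size_mm <- activity$voxel_size_mm
  } else {
    vox <- activity
  }
  if (any(vox < 0)) stop("activity must be nonnegative", call. = FALSE)
  tot <- sum(vox)
  if (tot <= 0) {
    stop("activity has no support (all voxels zero)", call. = FALSE)
  }
  lam <- fraction * full_counts * vox / tot
  counts <- with_seed(seed, {
    array(rpois(length(lam), lam), dim = dim(vox))
  })
  fwhm <- dose_fwhm_mm(fraction, fwhm_full_mm, fwhm_slope_mm)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  gaussian_smooth_3d(counts, sigma_vox)
}

#' Normalise a count volume to the unit interval
#'
#' Divides by the maximum voxel value so that values lie in \[0, 1\] with
#' maximum exactly 1; this is the input scale for patch extraction and the
#' network, and it deliberately removes absolute activity information.
#'
#' @param counts A nonnegative array with at least one positive voxel.
#' @return The array scaled by `1 / max(counts)`.
#' @export
normalize_volume <- function(counts) {
  m <- max(counts)
  if (!is.finite(m) || m <= 0) {
    stop("cannot normalise an all-zero volume", call. = FALSE)
  }
  counts / m
}
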