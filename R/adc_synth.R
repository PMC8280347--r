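#' Specification of a synthetic ADC lesion
#'
#' A contusion-like lesion: a hemorrhagic core of reduced ADC (restricted
#' diffusion from blood products) surrounded by an edema rim of raised ADC
#' (increased interstitial fluid).  The core change applies uniformly inside
#' `core_radius`; the rim change applies at full strength at the core edge
#' and tapers linearly to zero at the outer rim edge.
#'
#' @param center length-3 lesion centre in mm (volume frame).
#' @param core_radius mm (> 0).
#' @param rim_thickness mm (>= 0).
#' @param core_delta ADC change in the core, 10^-6 mm^2/s (<= 0).
#' @param rim_delta ADC change at the inner rim edge, 10^-6 mm^2/s (>= 0).
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, core_radius, rim_thickness,
                        core_delta, rim_delta) {
  stopifnot(length(center) == 3, core_radius > 0, rim_thickness >= 0,
            core_delta <= 0, rim_delta >= 0)
  structure(list(center = as.numeric(center), core_radius = core_radius,
                 rim_thickness = rim_thickness, core_delta = core_delta,
                 rim_delta = rim_delta),
            class = "lesion_spec")
}

#' Generate a synthetic ADC phantom volume
#'
#' Emulates a clinical ADC map: background gray/white matter at
#' 750 x 10^-6 mm^2/s plus additive Gaussian voxel noise, a central
#' ellipsoidal ventricle with CSF values drawn uniformly in [3000, 4000],
#' and contusion lesions per [lesion_spec()] (uniform core change, linearly
#' tapered rim change).  Fully deterministic for a fixed seed.  A lesion
#' whose core+rim sphere leaves the grid is rejected, as is any combination
#' that would drive a voxel ADC negative (raised as an error rather than
#' clipped).
#'
#' @param dims length-3 grid shape, default the clinical 128 x 128 x 45.
#' @param spacing mm per axis; default 1.8 mm in-plane (230 mm field of view
#'   over a 128 matrix) and 4 mm between slices.
#' @param lesions list of [lesion_spec()] (may be empty).
#' @param noise_sd additive Gaussian noise SD, 10^-6 mm^2/s (>= 0).
#' @param seed integer RNG seed.
#' @param baseline background ADC, 10^-6 mm^2/s.
#' @param ventricle_radii length-3 ventricle semi-axes in mm; `NULL` for no
#'   ventricle.
#' @param ventricle_center length-3 ventricle centre in mm; default the
#'   volume centre.
#' @return an [adc_volume()].
#' @export
generate_adc_phantom <- function(dims = c(128L, 128L, 45L),
                                 spacing = c(1.8, 1.8, 4),
                                 lesions = list(), noise_sd = 0,
                                 seed = 1L, baseline = 750,
                                 ventricle_radii = c(16, 30, 10),
                                 ventricle_center = NULL) {
  stopifnot(length(dims) == 3, all(dims >= 1), all(spacing > 0),
            noise_sd >= 0, baseline > 0)
  dims <- as.integer(dims)
  extent <- (dims - 1) * spacing
  if (is.null(ventricle_center)) ventricle_center <- extent / 2
  # voxel centre coordinates (mm), origin at voxel (1,1,1)
  cx <- (seq_len(dims[1]) - 1) * spacing[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  vol <- array(baseline, dims)
  if (noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(dims), 0, noise_sd), dims)

  X <- array(rep(cx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)

  for (les in lesions) {
    stopifnot(inherits(les, "lesion_spec"))
    rtot <- les$core_radius + les$rim_thickness
    if (any(les$center - rtot < -1e-9) ||
        any(les$center + rtot > extent + 1e-9))
      stop("lesion extends outside the volume grid")
    r <- sqrt((X - les$center[1])^2 + (Y - les$center[2])^2 +
                (Z - les$center[3])^2)
    core <- r <= les$core_radius
    vol[core] <- vol[core] + les$core_delta
    if (les$rim_thickness > 0) {
      rim <- r > les$core_radius & r <= rtot
      taper <- 1 - (r[rim] - les$core_radius) / les$rim_thickness
      vol[rim] <- vol[rim] + les$rim_delta * taper
    }
  }
  if (!is.null(ventricle_radii)) {
    inside <- ((X - ventricle_center[1]) / ventricle_radii[1])^2 +
      ((Y - ventricle_center[2]) / ventricle_radii[2])^2 +
      ((Z - ventricle_center[3]) / ventricle_radii[3])^2 <= 1
    vol[inside] <- stats::runif(sum(inside), 3000, 4000)
  }
  if (any(vol < 0))
    stop("lesion/noise combination drives ADC negative; ",
         "reduce core_delta magnitude or noise_sd")
  adc_volume(vol, spacing)
}

# save/restore the global RNG state so generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
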