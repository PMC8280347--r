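#' ADC volume container
#'
#' Regular-grid apparent diffusion coefficient map.  Values are in
#' 10^-6 mm^2/s; spacing and origin are in mm; voxel centres sit at
#' origin + (index - 1) * spacing with 1-based, x-fastest indices.
#'
#' @param values 3D numeric array (nx, ny, nz), all values >= 0.
#' @param spacing length-3 voxel spacing in mm (> 0).
#' @param origin length-3 position of the first voxel centre (mm).
#' @return object of class `adc_volume`.
#' @export
adc_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (any(values < 0)) stop("ADC values must be non-negative")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "adc_volume")
}

#' @export
print.adc_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("adc_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("ADC range [%.0f, %.0f] x 1e-6 mm^2/s\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Assemble an ADC volume from transverse slice files or matrices
#'
#' Stacks equally sized 2D slices bottom-to-top into a regular volume, the
#' workflow used for scanner-exported ADC slice series (e.g. 45 transverse
#' slices 4 mm apart on a 128 x 128 in-plane matrix).  Values pass through
#' unmodified, in 10^-6 mm^2/s.
#'
#' @param slices ordered list of numeric matrices, or a character vector of
#'   file paths to whitespace/comma-delimited text slices.
#' @param in_plane_spacing mm per in-plane voxel (> 0).
#' @param slice_spacing mm between slices (> 0).
#' @param origin length-3 position of the first voxel centre (mm).
#' @return an [adc_volume()] with nz = number of slices.
#' @export
load_adc_slices <- function(slices, in_plane_spacing = 1.8,
                            slice_spacing = 4, origin = c(0, 0, 0)) {
  stopifnot(in_plane_spacing > 0, slice_spacing > 0)
  if (is.character(slices)) {
    slices <- lapply(slices, function(f)
      as.matrix(utils::read.table(f, header = FALSE, sep = "")))
  }
  if (length(slices) == 0L) stop("empty slice list")
  dims <- vapply(slices, dim, integer(2))
  ok <- dims[1, ] == dims[1, 1] & dims[2, ] == dims[2, 1]
  if (!all(ok))
    stop("slices with mismatched dimensions: ",
         paste(which(!ok), collapse = ", "))
  vol <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) vol[, , k] <- as.numeric(slices[[k]])
  adc_volume(vol, c(in_plane_spacing, in_plane_spacing, slice_spacing),
             origin)
}

#' Delta-ADC against the gray/white-matter baseline
#'
#' Voxel-wise change from the baseline mean ADC of normal gray and white
#' matter (default 750 x 10^-6 mm^2/s), so that hemorrhagic restricted
#' diffusion appears as negative change and vasogenic edema as positive
#' change.  The identity value = baseline + change always reconstructs the
#' input.
#'
#' @param vol an [adc_volume()].
#' @param baseline baseline ADC A0 in 10^-6 mm^2/s (> 0).
#' @return object of class `delta_adc_volume` with fields `change` (array),
#'   `baseline`, `spacing`, `origin`, and `csf_mask` (values >= 3000, the
#'   CSF literature floor, excluded from lesion statistics by default).
#' @export
delta_adc <- function(vol, baseline = 750) {
  stopifnot(inherits(vol, "adc_volume"), baseline > 0)
  structure(list(change = vol$values - baseline, baseline = baseline,
                 spacing = vol$spacing, origin = vol$origin,
                 csf_mask = vol$values >= 3000),
            class = "delta_adc_volume")
}

#' Classify a voxel value by literature ADC ranges
#'
#' Normal ranges (10^-6 mm^2/s): gray matter 700-1000, white matter 670-800,
#' CSF 3000-4000, endpoints inclusive.  A value may match several labels
#' (GM/WM overlap); an empty result marks an abnormal value, a possible
#' lesion.
#'
#' @param value numeric vector of ADC values (>= 0).
#' @return list of character vectors, each a subset of `c("GM","WM","CSF")`.
#' @export
classify_tissue <- function(value) {
  stopifnot(all(value >= 0))
  lapply(value, function(v) {
    out <- character(0)
    if (v >= 700 && v <= 1000) out <- c(out, "GM")
    if (v >= 670 && v <= 800) out <- c(out, "WM")
    if (v >= 3000 && v <= 4000) out <- c(out, "CSF")
    out
  })
}

# trilinear interpolation of a 3D array at physical points (mm), voxel
# centres at origin + (i-1)*spacing
.trilinear <- function(values, spacing, origin, pts) {
  d <- dim(values)
  g <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1  # fractional index
  lo <- floor(g)
  fr <- g - lo
  # clamp so that points on the upper boundary interpolate from the last cell
  for (j in 1:3) {
    at_top <- lo[, j] >= d[j]
    lo[at_top, j] <- d[j] - 1
    fr[at_top, j] <- 1
    at_bot <- lo[, j] < 1
    lo[at_bot, j] <- 1
    fr[at_bot, j] <- 0
  }
  idx <- function(di, dj, dk)
    cbind(lo[, 1] + di, lo[, 2] + dj, lo[, 3] + dk)
  v <- values[idx(0, 0, 0)] * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
    values[idx(1, 0, 0)] * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
    values[idx(0, 1, 0)] * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
    values[idx(1, 1, 0)] * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
    values[idx(0, 0, 1)] * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
    values[idx(1, 0, 1)] * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
    values[idx(0, 1, 1)] * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
    values[idx(1, 1, 1)] * fr[, 1] * fr[, 2] * fr[, 3]
  v
}

#' Sample a straight line profile through a volume
#'
#' Trilinear interpolation at `n_samples` equally spaced points from `p0` to
#' `p1` (mm, same frame as the volume), with arc length measured from `p0`.
#' Works on [adc_volume()] and `delta_adc_volume` objects; for the latter
#' the CSF mask is sampled alongside (a sample is flagged CSF if nearer than
#' half a voxel to a masked voxel centre).
#'
#' @param vol an [adc_volume()] or `delta_adc_volume`.
#' @param p0,p1 length-3 endpoints in mm.
#' @param n_samples number of samples (>= 2).
#' @return object of class `line_profile`: data.frame-like list with
#'   `arc_length` (mm), `values`, logical `csf`, and endpoints.
#' @export
sample_line <- function(vol, p0, p1, n_samples = 200) {
  stopifnot(length(p0) == 3, length(p1) == 3, n_samples >= 2)
  if (all(p0 == p1)) stop("line endpoints coincide")
  values <- if (inherits(vol, "adc_volume")) vol$values else vol$change
  d <- dim(values)
  lo_mm <- vol$origin
  hi_mm <- vol$origin + (d - 1) * vol$spacing
  for (p in list(p0, p1)) {
    if (any(p < lo_mm - 1e-9) || any(p > hi_mm + 1e-9)) {
      clip <- pmin(pmax(p, lo_mm), hi_mm)
      stop(sprintf(paste0("line endpoint (%.1f, %.1f, %.1f) outside volume ",
                          "bounds; nearest in-bounds point is ",
                          "(%.1f, %.1f, %.1f)"),
                   p[1], p[2], p[3], clip[1], clip[2], clip[3]))
    }
  }
  s <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + s * (p1[1] - p0[1]),
               p0[2] + s * (p1[2] - p0[2]),
               p0[3] + s * (p1[3] - p0[3]))
  v <- .trilinear(values, vol$spacing, vol$origin, pts)
  csf <- rep(FALSE, n_samples)
  if (!is.null(vol$csf_mask)) {
    nearest <- round(sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, "/")) + 1
    for (j in 1:3) nearest[, j] <- pmin(pmax(nearest[, j], 1), d[j])
    csf <- vol$csf_mask[nearest]
  }
  structure(list(arc_length = s * sqrt(sum((p1 - p0)^2)), values = v,
                 csf = csf, p0 = p0, p1 = p1),
            class = "line_profile")
}

# ---- I/O --------------------------------------------------------------------

#' Read and write ADC volumes
#'
#' NIfTI I/O goes through RNifti with voxel spacing in the header (mm);
#' values are stored as-is in 10^-6 mm^2/s.  The raw format is a flat
#' little-endian float64 binary (x fastest) with a JSON sidecar carrying
#' dims, spacing, origin and units; round-trips are bit-exact.
#'
#' @param vol an [adc_volume()].
#' @param path output path (`.nii`/`.nii.gz` for NIfTI; anything else for
#'   raw + `.json` sidecar).
#' @return the path, invisibly (writers); an [adc_volume()] (readers).
#' @export
write_adc <- function(vol, path) {
  stopifnot(inherits(vol, "adc_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(vol$values), con, size = 8, endian = "little")
    close(con)
    meta <- list(dims = dim(vol$values), spacing = vol$spacing,
                 origin = vol$origin, units = "1e-6 mm^2/s",
                 dtype = "float64", order = "x-fastest",
                 endian = "little")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_adc
#' @param origin origin override when the source format carries none.
#' @export
read_adc <- function(path, origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("ADC volume not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    adc_volume(array(as.numeric(img), dim(img)),
               RNifti::pixdim(img)[1:3], origin)
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    con <- file(path, "rb")
    v <- readBin(con, "numeric", n = prod(meta$dims), size = 8,
                 endian = "little")
    close(con)
    adc_volume(array(v, meta$dims), meta$spacing, meta$origin)
  }
}

#' Write a line profile as CSV
#'
#' @param profile a [sample_line()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "line_profile"))
  utils::write.csv(data.frame(arc_length_mm = profile$arc_length,
                              value = profile$values, csf = profile$csf),
                   path, row.names = FALSE)
  invisible(path)
}
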