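#' Injury thresholds for the correspondence analysis
#'
#' Effective strain rate above 250 1/s marks the coup injury of focal
#' impacts with skull indentation; tensile (minimum) pressure below -90 kPa
#' marks coup-contrecoup injury; the Delta-ADC magnitude above
#' 200 x 10^-6 mm^2/s (about four times typical map noise) marks a
#' significant ADC change.
#'
#' @param strain_rate 1/s (> 0).
#' @param tensile_pressure Pa (< 0; pressure convention is compression
#'   positive, so tensile exceedance means pressure below this value).
#' @param delta_adc 10^-6 mm^2/s (> 0), threshold on |Delta-ADC|.
#' @return object of class `injury_thresholds`.
#' @export
injury_thresholds <- function(strain_rate = 250, tensile_pressure = -90e3,
                              delta_adc = 200) {
  stopifnot(strain_rate > 0, tensile_pressure < 0, delta_adc > 0)
  structure(list(strain_rate = strain_rate,
                 tensile_pressure = tensile_pressure,
                 delta_adc = delta_adc),
            class = "injury_thresholds")
}

#' Coup-contrecoup axis through a head
#'
#' The coup point is the impact location on the outer surface; the
#' contrecoup point is where the ray from the coup point through the head
#' centroid exits the opposite surface.  Methods exist for a
#' `phantom_mesh` (ray-facet intersection), a `phantom_geometry`
#' (analytic ellipsoid), and an `adc_volume`/`delta_adc_volume` (grid
#' bounding box).
#'
#' @param impact_point length-3 impact location (same frame/units as
#'   `object`); projected to the surface, an error if it lies deep inside.
#' @param object the head description.
#' @return list with `coup` and `contrecoup` points and `length`.
#' @export
coup_contrecoup_axis <- function(impact_point, object) {
  UseMethod("coup_contrecoup_axis", object)
}

#' @export
coup_contrecoup_axis.phantom_mesh <- function(impact_point, object) {
  mesh <- object
  bn <- mesh$boundary_nodes
  d2 <- rowSums(sweep(mesh$nodes[bn, , drop = FALSE], 2, impact_point)^2)
  near <- which.min(d2)
  if (sqrt(d2[near]) > 2.5 * mesh$edge_length)
    stop("impact point is not on (or near) the outer surface")
  coup <- mesh$nodes[bn[near], ]
  centroid <- colSums(mesh$nodes[mesh$elems[, 1], ] * mesh$volumes +
                        mesh$nodes[mesh$elems[, 2], ] * mesh$volumes +
                        mesh$nodes[mesh$elems[, 3], ] * mesh$volumes +
                        mesh$nodes[mesh$elems[, 4], ] * mesh$volumes) /
    (4 * sum(mesh$volumes))
  dir <- centroid - coup
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-12) stop("impact point coincides with the head centroid")
  dir <- dir / nd
  tt <- .ray_mesh_hits(coup, dir, mesh)
  if (!length(tt)) stop("ray through the centroid does not exit the mesh")
  contrecoup <- coup + max(tt) * dir
  list(coup = coup, contrecoup = contrecoup, length = max(tt))
}

#' @export
coup_contrecoup_axis.phantom_geometry <- function(impact_point, object) {
  ax <- object$outer_radii
  rho <- sqrt(sum((impact_point / ax)^2))
  if (rho < 0.8) stop("impact point is deep inside the head interior")
  coup <- impact_point / rho  # radial projection to the ellipsoid
  dir <- -coup
  dir <- dir / sqrt(sum(dir^2))
  # (coup + t d) on the ellipsoid: quadratic a t^2 + b t + c = 0
  a <- sum((dir / ax)^2)
  b <- 2 * sum(coup * dir / ax^2)
  cc <- sum((coup / ax)^2) - 1
  tt <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  contrecoup <- coup + tt * dir
  list(coup = coup, contrecoup = contrecoup, length = tt)
}

#' @export
coup_contrecoup_axis.adc_volume <- function(impact_point, object) {
  d <- dim(object$values)
  lo <- object$origin
  hi <- object$origin + (d - 1) * object$spacing
  p <- pmin(pmax(impact_point, lo), hi)
  centre <- (lo + hi) / 2
  dir <- centre - p
  dir <- dir / sqrt(sum(dir^2))
  # exit parameter through the axis-aligned box
  tmax <- Inf
  for (j in 1:3) {
    if (abs(dir[j]) < 1e-15) next
    t1 <- (lo[j] - p[j]) / dir[j]
    t2 <- (hi[j] - p[j]) / dir[j]
    tmax <- min(tmax, max(t1, t2))
  }
  list(coup = p, contrecoup = p + tmax * dir, length = tmax)
}

#' @export
coup_contrecoup_axis.delta_adc_volume <- function(impact_point, object) {
  fake <- structure(list(values = object$change, spacing = object$spacing,
                         origin = object$origin), class = "adc_volume")
  coup_contrecoup_axis(impact_point, fake)
}

# Moller-Trumbore ray/triangle intersection over all boundary facets;
# returns positive hit parameters
.ray_mesh_hits <- function(orig, dir, mesh) {
  tri <- mesh$boundary_facets
  v0 <- mesh$nodes[tri[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tri[, 2], , drop = FALSE] - v0
  e2 <- mesh$nodes[tri[, 3], , drop = FALSE] - v0
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-18
  tvec <- sweep(v0, 2, orig, "-") * -1
  u <- rowSums(tvec * pv) / det
  qv <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
              tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
              tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  vv <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tpar <- rowSums(e2 * qv) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tpar > 1e-9
  tpar[hit]
}

#' Depth of threshold exceedance along a profile
#'
#' The contiguous distance, from the cortex end of a coup-contrecoup
#' profile, over which the field satisfies the injury criterion
#' (`exceed_above`: value > threshold; `exceed_below`: value < threshold).
#' The crossing point is linearly interpolated between samples; CSF-masked
#' samples are skipped without breaking contiguity; depth is measured from
#' the first unmasked sample (the cortex entry).  Returns 0 when the first
#' sample already fails; later, detached exceedance runs are attached as
#' attribute `secondary_runs`.
#'
#' @param profile a [sample_line()] / [sample_envelope_line()] result.
#' @param threshold in the profile's units.
#' @param direction `"exceed_above"` or `"exceed_below"`.
#' @param from `"coup_end"` (profile start) or `"contrecoup_end"`.
#' @param gap_tolerance sub-threshold stretches no longer than this (same
#'   units as the arc length) do not break contiguity.  Zero by default;
#'   used with the interpolation-kernel width when scanning |Delta-ADC|
#'   profiles, where the hemorrhagic-core / edema-rim sign change crosses
#'   the threshold band over less than a voxel.
#' @return depth in the profile's arc-length units (mm), with attribute
#'   `secondary_runs`.
#' @export
depth_of_exceedance <- function(profile, threshold,
                                direction = c("exceed_above", "exceed_below"),
                                from = c("coup_end", "contrecoup_end"),
                                gap_tolerance = 0) {
  direction <- match.arg(direction)
  from <- match.arg(from)
  if (!length(profile$values)) stop("empty profile")
  v <- profile$values
  s <- profile$arc_length
  msk <- if (is.null(profile$csf)) rep(FALSE, length(v)) else profile$csf
  if (from == "contrecoup_end") {
    v <- rev(v); msk <- rev(msk)
    s <- max(s) - rev(s)
  }
  keep <- !msk & !is.na(v)
  v <- v[keep]; s <- s[keep]
  if (!length(v)) stop("profile entirely masked")
  s <- s - s[1]
  pass <- if (direction == "exceed_above") v > threshold else v < threshold
  if (gap_tolerance > 0 && any(pass)) {
    # bridge interior sub-threshold stretches shorter than the tolerance
    r0 <- rle(pass)
    e0 <- cumsum(r0$lengths)
    s0 <- e0 - r0$lengths + 1L
    for (k in seq_along(r0$values)) {
      # dip extent measured between the bracketing passing samples
      if (!r0$values[k] && k > 1L && k < length(r0$values) &&
          (s[e0[k] + 1L] - s[s0[k] - 1L]) <= gap_tolerance)
        pass[s0[k]:e0[k]] <- TRUE
    }
  }
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cross <- function(i0, i1) {
    # linear interpolation of the threshold crossing between samples i0, i1
    if (abs(v[i1] - v[i0]) < 1e-300) return(s[i1])
    s[i0] + (v[i0] - threshold) / (v[i0] - v[i1]) * (s[i1] - s[i0])
  }
  run_extent <- function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    a <- if (i0 == 1L) s[1] else cross(i0 - 1L, i0)
    b <- if (i1 == length(v)) s[length(v)] else cross(i1, i1 + 1L)
    c(a, b)
  }
  pk <- which(runs$values)
  if (!length(pk) || pk[1] != 1L) {
    depth <- 0
    sec <- lapply(pk, run_extent)
  } else {
    depth <- run_extent(1L)[2]
    sec <- lapply(pk[-1], run_extent)
  }
  attr(depth, "secondary_runs") <- sec
  depth
}

#' Sample an envelope field along a line through the mesh
#'
#' Piecewise-constant sampling of a per-element envelope measure along the
#' coup-contrecoup segment.  Samples in regions listed in `mask_regions`
#' (skull and CSF by default, mirroring the convention of displaying brain
#' fields only) are flagged like CSF samples of ADC profiles and skipped by
#' [depth_of_exceedance()] without breaking contiguity; samples outside the
#' mesh are masked as well.
#'
#' @param env a [field_envelope()].
#' @param mesh the `phantom_mesh` the envelope refers to.
#' @param p0,p1 endpoints in the mesh frame (m).
#' @param measure envelope column name, or `"min_pressure"` for the
#'   pressure minimum.
#' @param n_samples number of samples.
#' @param mask_regions region labels masked out.
#' @param positions optional deformed nodal positions for sampling in the
#'   deformed configuration (default: reference/undeformed).
#' @return a `line_profile` with arc length in mm.
#' @export
sample_envelope_line <- function(env, mesh, p0, p1, measure,
                                 n_samples = 200,
                                 mask_regions = c("cortical", "cancellous",
                                                  "csf", "ventricle_csf"),
                                 positions = NULL) {
  stopifnot(inherits(env, "field_envelope"))
  field <- if (identical(measure, "min_pressure")) env$min_pressure
           else env$max[, measure]
  s <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + s * (p1[1] - p0[1]),
               p0[2] + s * (p1[2] - p0[2]),
               p0[3] + s * (p1[3] - p0[3]))
  nodes <- if (is.null(positions)) mesh$nodes else positions
  el <- cpp_locate_points(nodes, mesh$elems, pts, tol = 1e-8)
  vals <- rep(NA_real_, n_samples)
  vals[el > 0] <- field[el[el > 0]]
  masked <- el == 0L
  if (length(mask_regions)) {
    bad <- which(mesh$region_labels %in% mask_regions)
    masked <- masked | (el > 0 & mesh$region[pmax(el, 1L)] %in% bad)
  }
  structure(list(arc_length = s * sqrt(sum((p1 - p0)^2)) * 1e3,
                 values = vals, csf = masked, p0 = p0, p1 = p1),
            class = "line_profile")
}

#' Coup-contrecoup correspondence report
#'
#' The core mapping step: samples the Delta-ADC volume and the simulated
#' envelope fields along the coup-contrecoup axis (each in its own frame,
#' with the coup/contrecoup points supplied by the caller), computes the
#' depth of exceedance of each injury threshold from both cortex ends, and
#' tabulates the Delta-ADC change range over each lesion window next to the
#' biomechanical exceedance depths.  Sides without exceedance are reported
#' as `NA` and printed as "-".
#'
#' @param delta a `delta_adc_volume` (see [delta_adc()]).
#' @param env a [field_envelope()] from a simulation.
#' @param mesh the simulated `phantom_mesh`.
#' @param axis_image list with `coup`/`contrecoup` points in the image
#'   frame (mm), e.g. from [coup_contrecoup_axis()] on the volume.
#' @param axis_sim list with `coup`/`contrecoup` points in the simulation
#'   frame (m).
#' @param thresholds an [injury_thresholds()].
#' @param n_samples samples per profile.
#' @return object of class `correspondence_report`: data.frame with one row
#'   per side (coup, contrecoup) and columns `adc_min`, `adc_max`
#'   (10^-6 mm^2/s), `adc_depth_mm`, `strain_rate_depth_mm`,
#'   `pressure_depth_mm`.
#' @export
correspondence_report <- function(delta, env, mesh, axis_image, axis_sim,
                                  thresholds = injury_thresholds(),
                                  n_samples = 200) {
  stopifnot(inherits(delta, "delta_adc_volume"),
            inherits(thresholds, "injury_thresholds"))
  prof_adc <- sample_line(delta, axis_image$coup, axis_image$contrecoup,
                          n_samples)
  abs_prof <- prof_adc
  abs_prof$values <- abs(prof_adc$values)
  # |Delta-ADC| briefly crosses the threshold band where the hemorrhagic
  # core (negative change) meets the edema rim (positive change); bridge
  # dips up to twice the interpolation-kernel width along the axis
  axdir <- axis_image$contrecoup - axis_image$coup
  axdir <- abs(axdir) / sqrt(sum(axdir^2))
  adc_gap <- 2 * sum(axdir * delta$spacing)
  prof_sr <- sample_envelope_line(env, mesh, axis_sim$coup,
                                  axis_sim$contrecoup,
                                  "effective_strain_rate", n_samples)
  prof_p <- sample_envelope_line(env, mesh, axis_sim$coup,
                                 axis_sim$contrecoup,
                                 "min_pressure", n_samples)
  side_row <- function(end) {
    d_adc <- depth_of_exceedance(abs_prof, thresholds$delta_adc,
                                 "exceed_above", end,
                                 gap_tolerance = adc_gap)
    rng <- c(NA_real_, NA_real_)
    if (d_adc > 0) {
      # signed Delta-ADC range over the lesion-depth window from this end
      depth_along <- if (end == "coup_end") prof_adc$arc_length
                     else max(prof_adc$arc_length) - prof_adc$arc_length
      win <- depth_along <= as.numeric(d_adc) & !prof_adc$csf
      rng <- range(prof_adc$values[win], na.rm = TRUE)
    }
    d_sr <- depth_of_exceedance(prof_sr, thresholds$strain_rate,
                                "exceed_above", end)
    d_p <- depth_of_exceedance(prof_p, thresholds$tensile_pressure,
                               "exceed_below", end)
    data.frame(side = sub("_end", "", end),
               adc_min = rng[1], adc_max = rng[2],
               adc_depth_mm = ifelse(d_adc > 0, as.numeric(d_adc), NA),
               strain_rate_depth_mm = ifelse(d_sr > 0, as.numeric(d_sr), NA),
               pressure_depth_mm = ifelse(d_p > 0, as.numeric(d_p), NA))
  }
  rep <- rbind(side_row("coup_end"), side_row("contrecoup_end"))
  structure(rep, class = c("correspondence_report", "data.frame"),
            thresholds = thresholds)
}

#' @export
print.correspondence_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  fmt <- function(v, digits = 0) ifelse(is.na(v), "-",
                                        formatC(v, digits = digits,
                                                format = "f"))
  cat(sprintf(
    "| side | ADC change range | ADC depth | strain rate > %g 1/s | pressure < %g kPa |\n",
    th$strain_rate, th$tensile_pressure / 1e3))
  cat("|---|---|---|---|---|\n")
  for (i in seq_len(nrow(x))) {
    rng <- if (is.na(x$adc_min[i])) "-" else
      sprintf("(%s, %s)", fmt(x$adc_min[i]), fmt(x$adc_max[i]))
    cat(sprintf("| %s | %s | %s | %s | %s |\n", x$side[i], rng,
                fmt(x$adc_depth_mm[i], 1),
                fmt(x$strain_rate_depth_mm[i], 1),
                fmt(x$pressure_depth_mm[i], 1)))
  }
  invisible(x)
}

#' Write a correspondence report as CSV
#'
#' @param report a [correspondence_report()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Sensitivity sweep over the impact angular velocity
#'
#' Re-runs the impact simulation on the same phantom for each angular
#' velocity in the grid and tabulates peak head acceleration, residual
#' skull indentation, and the coup/contrecoup depths of strain-rate and
#' tensile-pressure exceedance.  Peak acceleration and residual indentation
#' are expected non-decreasing in the angular velocity; a warning is issued
#' when the coarse phantom violates the trend.  Failed runs are recorded
#' and the sweep continues.
#'
#' @param preset a [case_preset()] (or compatible list with `condition`,
#'   `materials`, `anthropometry`).
#' @param omegas numeric grid of angular velocities (rad/s).
#' @param mesh a `phantom_mesh`.
#' @param thresholds an [injury_thresholds()].
#' @param ... passed to [run_impact()].
#' @return data.frame with one row per grid point.
#' @export
sensitivity_sweep <- function(preset, omegas, mesh,
                              thresholds = injury_thresholds(), ...) {
  if (!length(omegas)) stop("empty angular-velocity grid")
  rows <- lapply(omegas, function(w) {
    cond <- preset$condition
    cond$angular_velocity <- w
    res <- tryCatch({
      hs <- impact_state(cond, preset$anthropometry)
      sim <- run_impact(mesh, preset$materials, hs, cond, ...)
      u <- cond$impact_direction
      proj <- mesh$nodes[mesh$boundary_nodes, , drop = FALSE] %*% u
      apex <- mesh$nodes[mesh$boundary_nodes[which.max(proj)], ]
      axis <- coup_contrecoup_axis(apex, mesh)
      psr <- sample_envelope_line(sim$envelope, mesh, axis$coup,
                                  axis$contrecoup, "effective_strain_rate")
      pp <- sample_envelope_line(sim$envelope, mesh, axis$coup,
                                 axis$contrecoup, "min_pressure")
      d <- function(prof, thr, dir, end)
        as.numeric(depth_of_exceedance(prof, thr, dir, end))
      data.frame(
        omega = w, peak_acc_g = sim$peak_acc_g,
        residual_indentation_mm = sim$residual_indentation * 1e3,
        sr_depth_coup_mm = d(psr, thresholds$strain_rate, "exceed_above",
                             "coup_end"),
        sr_depth_contrecoup_mm = d(psr, thresholds$strain_rate,
                                   "exceed_above", "contrecoup_end"),
        p_depth_coup_mm = d(pp, thresholds$tensile_pressure, "exceed_below",
                            "coup_end"),
        p_depth_contrecoup_mm = d(pp, thresholds$tensile_pressure,
                                  "exceed_below", "contrecoup_end"),
        failed = FALSE, message = "")
    }, error = function(e)
      data.frame(omega = w, peak_acc_g = NA, residual_indentation_mm = NA,
                 sr_depth_coup_mm = NA, sr_depth_contrecoup_mm = NA,
                 p_depth_coup_mm = NA, p_depth_contrecoup_mm = NA,
                 failed = TRUE, message = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  ok <- !out$failed
  if (sum(ok) >= 2) {
    ordd <- order(out$omega[ok])
    if (is.unsorted(out$peak_acc_g[ok][ordd]) ||
        is.unsorted(out$residual_indentation_mm[ok][ordd]))
      warning("peak acceleration or residual indentation not monotone in ",
              "angular velocity at this phantom resolution")
  }
  out
}
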