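#' Synthetic ADC volume emulating a clinical case
#'
#' Builds the case-like ADC phantom used when no clinical volume is
#' supplied, and returns the coup/contrecoup points of its image frame.
#' The coup-contrecoup line runs along +x through the volume centre.  Case
#' 1 plants a single coup contusion whose significant |Delta-ADC| extent is
#' about 10 mm with change range (-450, +1150); case 2 plants a 30 mm coup
#' contusion with range (-750, +950) and a 20 mm edema-only contrecoup
#' lesion with range (0, +1100); the central ventricle carries CSF values.
#'
#' @param case_id 1 or 2; any other value plants no lesion.
#' @param dims,spacing grid shape and spacing, see [generate_adc_phantom()].
#' @param noise_sd additive Gaussian noise SD (10^-6 mm^2/s).
#' @param seed RNG seed.
#' @param lesions override the case lesion list (`NULL` = case default).
#' @return list with `volume` ([adc_volume()]), `coup`, `contrecoup` (mm),
#'   and `lesions`.
#' @export
case_adc_phantom <- function(case_id, dims = c(128L, 128L, 45L),
                             spacing = c(1.8, 1.8, 4), noise_sd = 0,
                             seed = 1L, lesions = NULL) {
  yc <- (dims[2] - 1) * spacing[2] / 2
  zc <- (dims[3] - 1) * spacing[3] / 2
  coup <- c(30, yc, zc)
  contrecoup <- c(195, yc, zc)
  if (is.null(lesions)) {
    lesions <- if (identical(as.integer(case_id), 1L)) {
      list(lesion_spec(c(33, yc, zc), core_radius = 5, rim_thickness = 3,
                       core_delta = -450, rim_delta = 1150))
    } else if (identical(as.integer(case_id), 2L)) {
      list(lesion_spec(c(44, yc, zc), core_radius = 12, rim_thickness = 6,
                       core_delta = -750, rim_delta = 950),
           lesion_spec(c(198, yc, zc), core_radius = 1, rim_thickness = 27,
                       core_delta = 0, rim_delta = 1100))
    } else list()
  }
  vol <- generate_adc_phantom(dims = dims, spacing = spacing,
                              lesions = lesions, noise_sd = noise_sd,
                              seed = seed)
  list(volume = vol, coup = coup, contrecoup = contrecoup, lesions = lesions)
}

#' Case configuration for the end-to-end pipeline
#'
#' Bundles everything one reconstruction needs: the impact condition and
#' anthropometry (defaulted from the case presets), phantom geometry,
#' material overrides, injury thresholds, ADC source, numerical settings
#' and the output directory.  Every default is echoed into the resolved
#' configuration written to the run manifest, so no silent defaults.
#'
#' @param case_id 1 or 2.
#' @param condition,anthro,geometry,materials,thresholds overrides of the
#'   case presets.
#' @param adc list: `noise_sd`, `dims`, `spacing`, `lesions` (NULL = case
#'   default), or `path` to an existing volume readable by [read_adc()].
#' @param out_dir output directory (`NULL` = no files written).
#' @param seed integer seed for all stochastic inputs.
#' @param penalty_stiffness,dt_safety,n_history,n_snapshots solver settings
#'   passed to [run_impact()].
#' @return object of class `case_config`.
#' @export
case_config <- function(case_id = 1, condition = NULL, anthro = NULL,
                        geometry = phantom_geometry(), materials = NULL,
                        thresholds = injury_thresholds(),
                        adc = list(), out_dir = NULL, seed = 1L,
                        penalty_stiffness = 1e12, dt_safety = 0.8,
                        n_history = 400, n_snapshots = 50) {
  preset <- case_preset(case_id)
  cfg <- list(
    case_id = preset$case_id,
    condition = if (is.null(condition)) preset$condition else condition,
    anthropometry = if (is.null(anthro)) preset$anthropometry else anthro,
    geometry = geometry,
    materials = if (is.null(materials)) preset$materials else materials,
    thresholds = thresholds,
    adc = utils::modifyList(list(noise_sd = 0, dims = c(128L, 128L, 45L),
                                 spacing = c(1.8, 1.8, 4), lesions = NULL,
                                 path = NULL), adc),
    out_dir = out_dir, seed = as.integer(seed),
    penalty_stiffness = penalty_stiffness, dt_safety = dt_safety,
    n_history = n_history, n_snapshots = n_snapshots)
  class(cfg) <- "case_config"
  cfg
}

#' Run a case end-to-end
#'
#' Orchestrates the full reconstruction: fall biodynamics, phantom meshing,
#' explicit impact simulation, measure envelopes, synthetic (or loaded) ADC
#' volume, and the coup-contrecoup correspondence report.  With an output
#' directory set, writes the time-history CSV, envelope CSV and VTU, the
#' correspondence report CSV, and a JSON provenance manifest (resolved
#' configuration, seed, stage wall times).  A stage failure produces a
#' bundle holding the completed stages plus a failure record.
#'
#' @param config a [case_config()].
#' @return list of class `case_bundle`: `head_state`, `mesh`, `sim`,
#'   `adc`, `report`, `manifest`, `failure` (NULL on success).
#' @export
run_case <- function(config) {
  stopifnot(inherits(config, "case_config"))
  bundle <- list(failure = NULL)
  times <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    times[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  result <- tryCatch({
    bundle$head_state <- stage("biodynamics",
      impact_state(config$condition, config$anthropometry))
    bundle$mesh <- stage("mesh",
      generate_head_phantom(config$geometry, config$seed))
    bundle$sim <- stage("simulation",
      run_impact(bundle$mesh, config$materials, bundle$head_state,
                 config$condition,
                 penalty_stiffness = config$penalty_stiffness,
                 dt_safety = config$dt_safety,
                 n_history = config$n_history,
                 n_snapshots = config$n_snapshots))
    bundle$adc <- stage("adc", {
      if (!is.null(config$adc$path)) {
        vol <- read_adc(config$adc$path)
        ax <- coup_contrecoup_axis(c(0, 0, 0) + vol$origin, vol)
        list(volume = vol, coup = ax$coup, contrecoup = ax$contrecoup)
      } else {
        case_adc_phantom(config$case_id, dims = config$adc$dims,
                         spacing = config$adc$spacing,
                         noise_sd = config$adc$noise_sd, seed = config$seed,
                         lesions = config$adc$lesions)
      }
    })
    bundle$report <- stage("correspondence", {
      u <- config$condition$impact_direction
      bn <- bundle$mesh$boundary_nodes
      proj <- bundle$mesh$nodes[bn, , drop = FALSE] %*% u
      apex <- bundle$mesh$nodes[bn[which.max(proj)], ]
      axis_sim <- coup_contrecoup_axis(apex, bundle$mesh)
      delta <- delta_adc(bundle$adc$volume)
      correspondence_report(delta, bundle$sim$envelope, bundle$mesh,
                            list(coup = bundle$adc$coup,
                                 contrecoup = bundle$adc$contrecoup),
                            axis_sim, config$thresholds)
    })
    TRUE
  }, error = function(e) {
    bundle$failure <<- conditionMessage(e)
    FALSE
  })

  bundle$manifest <- list(
    config = .serialize_config(config),
    config_hash = .config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("coupmap")),
    r_version = R.version.string,
    stage_seconds = times,
    failed = !isTRUE(result), failure = bundle$failure)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    if (!is.null(bundle$sim)) {
      write_history_csv(bundle$sim, file.path(od, "history.csv"))
      write_envelope_csv(bundle$sim$envelope, bundle$mesh,
                         file.path(od, "envelope.csv"))
      write_vtu(bundle$mesh, file.path(od, "envelope.vtu"),
                cell_data = c(
                  as.list(as.data.frame(bundle$sim$envelope$max)),
                  list(min_pressure = bundle$sim$envelope$min_pressure)))
    }
    if (!is.null(bundle$report))
      write_report_csv(bundle$report, file.path(od, "report.csv"))
    jsonlite::write_json(bundle$manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  class(bundle) <- "case_bundle"
  bundle
}

# plain-list view of a config for the manifest (functions/classes stripped)
.serialize_config <- function(config) {
  rapply(unclass(config), function(x) x, how = "list")
}

.config_hash <- function(config) {
  # hash the scientific configuration only; the output location does not
  # change what is computed
  cfg <- .serialize_config(config)
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

#' Write envelope extrema as CSV
#'
#' Long format: element id, region label, measure, extremum value, time of
#' extremum (ms); includes the pressure minimum.
#'
#' @param env a [field_envelope()].
#' @param mesh the corresponding `phantom_mesh`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_envelope_csv <- function(env, mesh, path) {
  m <- env$n_elements
  lab <- mesh$region_labels[mesh$region]
  long <- do.call(rbind, lapply(env$measures, function(ms)
    data.frame(element = seq_len(m), region = lab, measure = ms,
               extremum = env$max[, ms], time_ms = env$t_max[, ms] * 1e3)))
  long <- rbind(long,
                data.frame(element = seq_len(m), region = lab,
                           measure = "min_pressure",
                           extremum = env$min_pressure,
                           time_ms = env$t_min_pressure * 1e3))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
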