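make_profile <- function(values, arc, csf = NULL) {
  structure(list(arc_length = arc, values = values,
                 csf = if (is.null(csf)) rep(FALSE, length(values)) else csf,
                 p0 = c(0, 0, 0),
                 p1 = c(if (length(arc)) max(arc) else 0, 0, 0)),
            class = "line_profile")
}

test_that("depth of exceedance interpolates the crossing point", {
  # hand-worked case: 300 for 0-10 mm, 100 beyond, threshold 250 -> 10.5 mm
  arc <- seq(0, 20, by = 2)
  v <- ifelse(arc <= 10, 300, 100)
  d <- depth_of_exceedance(make_profile(v, arc), 250, "exceed_above",
                           "coup_end")
  expect_equal(as.numeric(d), 10.5)
  # all below threshold: zero
  expect_equal(as.numeric(depth_of_exceedance(make_profile(rep(10, 11), arc),
                                              250, "exceed_above")), 0)
  # uniform exceedance: full axis length
  expect_equal(as.numeric(depth_of_exceedance(make_profile(rep(400, 11), arc),
                                              250, "exceed_above")), 20)
  # exceed_below mirrors the logic (tensile pressure convention)
  vp <- ifelse(arc <= 10, -120e3, -10e3)
  dp <- depth_of_exceedance(make_profile(vp, arc), -90e3, "exceed_below")
  expect_equal(as.numeric(dp), 10 + 2 * ((-120e3) - (-90e3)) /
                 ((-120e3) - (-10e3)))
  # contrecoup end measures from the other side
  dc <- depth_of_exceedance(make_profile(rev(v), arc), 250, "exceed_above",
                            "contrecoup_end")
  expect_equal(as.numeric(dc), 10.5)
  # masked samples are skipped without breaking contiguity
  vm <- c(300, 300, 0, 300, 300, 100, 100)
  arcm <- seq(0, 12, by = 2)
  msk <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  dm <- depth_of_exceedance(make_profile(vm, arcm, msk), 250, "exceed_above")
  expect_equal(as.numeric(dm), 8 + 2 * 50 / 200)
  # depth measured from the first unmasked sample (cortex entry)
  vlead <- c(0, 0, 300, 300, 100)
  msk2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  dl <- depth_of_exceedance(make_profile(vlead, seq(0, 8, by = 2), msk2),
                            250, "exceed_above")
  expect_equal(as.numeric(dl), 2 + 2 * 50 / 200)
  expect_error(depth_of_exceedance(make_profile(numeric(0), numeric(0)), 1),
               "empty")
})

test_that("depth of exceedance agrees with a brute-force scan oracle", {
  set.seed(17)
  for (k in 1:300) {
    n <- sample(5:40, 1)
    arc <- sort(stats::runif(n, 0, 50))
    arc <- arc - arc[1]
    v <- stats::rnorm(n)
    thr <- stats::rnorm(1, sd = 0.5)
    d <- as.numeric(depth_of_exceedance(make_profile(v, arc), thr,
                                        "exceed_above"))
    # oracle: walk samples until the first failure, interpolate linearly
    if (v[1] <= thr) {
      expect_equal(d, 0)
    } else {
      i <- which(v <= thr)[1]
      if (is.na(i)) {
        expect_equal(d, arc[n])
      } else {
        expected <- arc[i - 1] + (v[i - 1] - thr) / (v[i - 1] - v[i]) *
          (arc[i] - arc[i - 1])
        expect_equal(d, expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("coup-contrecoup axis is diametric on symmetric heads", {
  # analytic sphere: impact at (r,0,0) -> contrecoup at (-r,0,0)
  geo <- phantom_geometry(outer_radii = c(0.08, 0.08, 0.08))
  ax <- coup_contrecoup_axis(c(0.08, 0, 0), geo)
  expect_equal(ax$coup, c(0.08, 0, 0))
  expect_equal(ax$contrecoup, c(-0.08, 0, 0), tolerance = 1e-12)
  expect_equal(ax$length, 0.16)
  # ellipsoid apex maps to the opposite apex
  geo2 <- phantom_geometry()
  ax2 <- coup_contrecoup_axis(c(0.1, 0, 0), geo2)
  expect_equal(ax2$contrecoup, c(-0.1, 0, 0), tolerance = 1e-9)
  expect_error(coup_contrecoup_axis(c(0.01, 0, 0), geo2), "interior")
  # mesh-based: within a facet size of the diametric point, and the axis
  # length matches the head extent along the ray
  mesh <- small_phantom()
  bn <- mesh$boundary_nodes
  apex <- mesh$nodes[bn[which.max(mesh$nodes[bn, 1])], ]
  axm <- coup_contrecoup_axis(apex, mesh)
  expect_lt(sqrt(sum((axm$contrecoup - c(-apex[1], apex[2], apex[3]))^2)),
            2.5 * mesh$edge_length)
  expect_gt(axm$length, 0.8 * 2 * 0.1)
  expect_lte(axm$length, 2 * 0.1 + 2 * mesh$edge_length)
  expect_error(coup_contrecoup_axis(c(0, 0, 0), mesh), "surface")
})

test_that("envelope line sampling masks non-brain regions", {
  mesh <- small_phantom()
  env <- field_envelope(nrow(mesh$elems))
  cols <- env$measures
  v <- matrix(0, nrow(mesh$elems), length(cols), dimnames = list(NULL, cols))
  v[, "effective_strain_rate"] <- ifelse(mesh$region == 4, 300, 50)
  env <- update_envelope(env, v, 0.001)
  bn <- mesh$boundary_nodes
  apex <- mesh$nodes[bn[which.max(mesh$nodes[bn, 1])], ]
  ax <- coup_contrecoup_axis(apex, mesh)
  prof <- sample_envelope_line(env, mesh, ax$coup, ax$contrecoup,
                               "effective_strain_rate")
  # skull/CSF samples are masked; brain samples carry the planted value
  expect_true(any(prof$csf))
  expect_true(all(prof$values[!prof$csf] == 300))
})

test_that("correspondence report recovers planted depth patterns and sides", {
  mesh <- small_phantom()
  m <- nrow(mesh$elems)
  # synthetic envelope: strain rate 300 1/s within 10 mm of the +x brain
  # surface, 100 elsewhere; pressure envelope harmless
  cen <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
            mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  geo <- phantom_geometry()
  brain_x <- geo$outer_radii[1] - 0.010  # brain surface semi-axis ~ x apex
  env <- field_envelope(m)
  v <- matrix(0, m, length(env$measures),
              dimnames = list(NULL, env$measures))
  depth_x <- brain_x - cen[, 1]
  v[, "effective_strain_rate"] <- ifelse(mesh$region == 4 & depth_x < 0.012,
                                         300, 100)
  v[, "pressure"] <- 0
  env <- update_envelope(env, v, 0.001)
  adc <- case_adc_phantom(1, noise_sd = 0, seed = 2)
  delta <- delta_adc(adc$volume)
  bn <- mesh$boundary_nodes
  apex <- mesh$nodes[bn[which.max(mesh$nodes[bn, 1])], ]
  ax_sim <- coup_contrecoup_axis(apex, mesh)
  rep1 <- correspondence_report(delta, env, mesh,
                                list(coup = adc$coup,
                                     contrecoup = adc$contrecoup),
                                ax_sim)
  coup <- rep1[rep1$side == "coup", ]
  ccp <- rep1[rep1$side == "contrecoup", ]
  expect_lt(abs(coup$adc_depth_mm - 10.5), 1.8)     # planted ~10 mm lesion
  expect_equal(coup$adc_min, -450, tolerance = 0.01)
  # positive edema rim registered (its 3 mm width is under-resolved by the
  # 1.8 mm voxels, so the sampled peak sits well below the planted +1150)
  expect_gt(coup$adc_max, 400)
  expect_true(is.na(ccp$adc_depth_mm))              # no contrecoup lesion
  expect_gt(coup$strain_rate_depth_mm, 5)
  expect_lt(coup$strain_rate_depth_mm, 25)
  expect_true(is.na(ccp$strain_rate_depth_mm))
  expect_true(is.na(coup$pressure_depth_mm))        # "-" entries
  expect_true(is.na(ccp$pressure_depth_mm))
  # report symmetry: swapping the axis endpoints swaps the sides
  rep2 <- correspondence_report(delta, env, mesh,
                                list(coup = adc$contrecoup,
                                     contrecoup = adc$coup),
                                list(coup = ax_sim$contrecoup,
                                     contrecoup = ax_sim$coup))
  expect_equal(rep2[rep2$side == "contrecoup", -1],
               coup[, -1], tolerance = 1e-6, ignore_attr = TRUE)
  # zero-field envelope and lesion-free volume: all entries empty
  env0 <- update_envelope(field_envelope(m),
                          matrix(0, m, length(env$measures),
                                 dimnames = list(NULL, env$measures)), 0)
  vol0 <- case_adc_phantom(0, noise_sd = 0, seed = 2)
  rep0 <- correspondence_report(delta_adc(vol0$volume), env0, mesh,
                                list(coup = vol0$coup,
                                     contrecoup = vol0$contrecoup), ax_sim)
  expect_true(all(is.na(rep0$adc_depth_mm)))
  expect_true(all(is.na(rep0$strain_rate_depth_mm)))
  expect_true(all(is.na(rep0$pressure_depth_mm)))
  expect_output(print(rep1), "\\| coup \\|")
})

test_that("sensitivity sweep is consistent and monotone on a coarse phantom", {
  mesh <- small_phantom()
  pre <- case_preset(1)
  pre$condition$duration <- 0.008
  # singleton grid row matches a direct run
  sw1 <- sensitivity_sweep(pre, 30, mesh)
  hs <- impact_state(pre$condition, pre$anthropometry)
  direct <- run_impact(mesh, pre$materials, hs, pre$condition)
  expect_equal(sw1$peak_acc_g, direct$peak_acc_g, tolerance = 1e-10)
  expect_equal(sw1$residual_indentation_mm,
               direct$residual_indentation * 1e3, tolerance = 1e-10)
  # omega = 0: head merely rests on the object under gravity -- accelerations
  # at the resting-contact scale (~1 g), no measurable indentation
  sw0 <- sensitivity_sweep(pre, 0, mesh)
  expect_lt(sw0$peak_acc_g, 3)
  expect_lt(sw0$residual_indentation_mm, 0.01)
  # +-10% omega: residual indentation strictly increasing
  sw <- sensitivity_sweep(pre, c(27, 30, 33), mesh)
  expect_false(any(sw$failed))
  expect_true(all(diff(sw$residual_indentation_mm) > 0))
  expect_true(all(diff(sw$peak_acc_g) > 0))
})
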