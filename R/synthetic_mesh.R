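#' Layered head phantom geometry
#'
#' Nested-ellipsoid stand-in for an anatomical head: an outer ellipsoid with
#' concentric shells of cortical bone, cancellous bone and CSF around a
#' brain interior containing a single central ellipsoidal ventricle.
#' Defaults approximate a 50th-percentile adult head (outer semi-axes
#' 0.10/0.085/0.075 m, cortical 4 mm, cancellous 3 mm, CSF 3 mm).
#'
#' @param outer_radii length-3 ellipsoid semi-axes (m).
#' @param cortical_thickness,cancellous_thickness,csf_thickness shell
#'   thicknesses (m, > 0); their sum must be smaller than the smallest outer
#'   semi-axis.
#' @param ventricle_radii length-3 semi-axes of the central ventricle (m).
#' @param target_edge_length lattice edge length for meshing (m, > 0).
#' @return object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(outer_radii = c(0.100, 0.085, 0.075),
                             cortical_thickness = 0.004,
                             cancellous_thickness = 0.003,
                             csf_thickness = 0.003,
                             ventricle_radii = c(0.018, 0.022, 0.012),
                             target_edge_length = 0.012) {
  stopifnot(length(outer_radii) == 3, all(outer_radii > 0),
            cortical_thickness > 0, cancellous_thickness > 0,
            csf_thickness > 0, length(ventricle_radii) == 3,
            all(ventricle_radii > 0), target_edge_length > 0)
  shells <- cortical_thickness + cancellous_thickness + csf_thickness
  if (shells >= min(outer_radii))
    stop("shell thicknesses exceed the smallest outer semi-axis: ",
         "the skull/CSF shells would overlap the centre")
  if (any(ventricle_radii >= outer_radii - shells))
    stop("ventricle does not fit inside the brain region")
  structure(list(outer_radii = outer_radii,
                 cortical_thickness = cortical_thickness,
                 cancellous_thickness = cancellous_thickness,
                 csf_thickness = csf_thickness,
                 ventricle_radii = ventricle_radii,
                 target_edge_length = target_edge_length),
            class = "phantom_geometry")
}

# Kuhn (Freudenthal) 6-tetrahedra decomposition of the unit cube, as corner
# offsets.  Translation-invariant, hence face-conforming across a lattice.
.kuhn_tets <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    off <- matrix(0L, 4L, 3L)
    for (i in 1:3) {
      off[i + 1L, ] <- off[i, ]
      off[i + 1L, p[i]] <- off[i + 1L, p[i]] + 1L
    }
    off
  })
})

.tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 2], ] - nodes[elems[, 1], ]
  b <- nodes[elems[, 3], ] - nodes[elems[, 1], ]
  c3 <- nodes[elems[, 4], ] - nodes[elems[, 1], ]
  cx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  cy <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  cz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  (a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

.triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# build a phantom_mesh object from raw arrays: computes volumes, boundary
# facets (faces used by exactly one element, ordered outward), nodal contact
# areas and characteristic lengths.
.finalize_mesh <- function(nodes, elems, region, region_labels, edge_length) {
  vol <- .tet_volumes(nodes, elems)
  if (any(vol <= 0)) stop("degenerate or inverted element in generated mesh")
  # faces: local node triples opposite each vertex, wound outward for a
  # positively oriented tet
  face_idx <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  m <- nrow(elems)
  faces <- matrix(0L, 4L * m, 3L)
  for (f in 1:4) faces[seq.int(f, by = 4L, length.out = m), ] <-
      elems[, face_idx[f, ], drop = FALSE]
  key <- apply(faces, 1L, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  boundary <- faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
  areas <- .triangle_areas(nodes, boundary)
  nodal_area <- numeric(nrow(nodes))
  for (j in 1:3) {
    add <- tapply(areas / 3, boundary[, j], sum)
    nodal_area[as.integer(names(add))] <-
      nodal_area[as.integer(names(add))] + add
  }
  # characteristic element length: minimum altitude 3V / A_max
  amax <- numeric(m)
  for (f in 1:4) {
    fa <- .triangle_areas(nodes, elems[, face_idx[f, ], drop = FALSE])
    amax <- pmax(amax, fa)
  }
  structure(list(nodes = nodes, elems = elems, region = as.integer(region),
                 region_labels = region_labels, volumes = vol,
                 boundary_facets = boundary,
                 boundary_nodes = sort(unique(as.integer(boundary))),
                 nodal_area = nodal_area, h_char = 3 * vol / amax,
                 edge_length = edge_length),
            class = "phantom_mesh")
}

#' @export
print.phantom_mesh <- function(x, ...) {
  cat("phantom_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "tets,",
      nrow(x$boundary_facets), "boundary facets\n")
  cat("regions:", paste(sprintf("%s=%d", x$region_labels,
                                tabulate(x$region,
                                         length(x$region_labels))),
                        collapse = ", "), "\n")
  invisible(x)
}

# lattice tetrahedralization of an axis-aligned box; cells can be filtered
# by a predicate on tet centroids.
.lattice_mesh <- function(origin, ncell, h, keep = NULL) {
  nx <- ncell[1]; ny <- ncell[2]; nz <- ncell[3]
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  gx <- origin[1] + h[1] * (0:nx)
  gy <- origin[2] + h[2] * (0:ny)
  gz <- origin[3] + h[3] * (0:nz)
  nodes <- cbind(rep(gx, times = (ny + 1) * (nz + 1)),
                 rep(rep(gy, each = nx + 1), times = nz + 1),
                 rep(gz, each = (nx + 1) * (ny + 1)))
  cells <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  elems <- matrix(0L, nrow(cells) * 6L, 4L)
  row <- 0L
  for (t in 1:6) {
    off <- .kuhn_tets[[t]]
    ids <- sapply(1:4, function(a)
      nid(cells$i + off[a, 1], cells$j + off[a, 2], cells$k + off[a, 3]))
    elems[seq.int(t, by = 6L, length.out = nrow(cells)), ] <- ids
  }
  # fix orientation once per Kuhn variant (translation invariant)
  vol <- .tet_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  if (!is.null(keep)) {
    cen <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
              nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
    sel <- keep(cen)
    elems <- elems[sel, , drop = FALSE]
  }
  # drop unused nodes, renumber
  used <- sort(unique(as.integer(elems)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4L)
  list(nodes = nodes[used, , drop = FALSE], elems = elems)
}

#' Generate the layered head phantom mesh
#'
#' Deterministic lattice tetrahedralization (Kuhn 6-tet decomposition of a
#' cubic lattice at the target edge length) clipped to the outer ellipsoid.
#' Each tetrahedron carries exactly one region label, assigned from the
#' nested-ellipsoid shell containing its centroid: cortical (outermost),
#' cancellous, csf, brain, with a central ventricle_csf ellipsoid.
#'
#' @param geometry a [phantom_geometry()].
#' @param seed integer; fixes any stochastic meshing choice (the lattice
#'   construction is fully deterministic, the seed is recorded for
#'   provenance).
#' @return a `phantom_mesh`: nodes (m), 1-based tetrahedra, integer region
#'   per element with labels `cortical, cancellous, csf, brain,
#'   ventricle_csf`, reference volumes, boundary facets with nodal contact
#'   areas and per-element characteristic lengths.
#' @export
generate_head_phantom <- function(geometry = phantom_geometry(), seed = 1L) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  h <- geometry$target_edge_length
  a0 <- geometry$outer_radii
  a1 <- a0 - geometry$cortical_thickness
  a2 <- a1 - geometry$cancellous_thickness
  a3 <- a2 - geometry$csf_thickness
  av <- geometry$ventricle_radii
  ncell <- ceiling(2 * a0 / h) + 2L
  origin <- -ncell * h / 2
  rho <- function(cen, ax) sqrt((cen[, 1] / ax[1])^2 + (cen[, 2] / ax[2])^2 +
                                  (cen[, 3] / ax[3])^2)
  raw <- .lattice_mesh(origin, ncell, rep(h, 3),
                       keep = function(cen) rho(cen, a0) <= 1)
  if (nrow(raw$elems) == 0L)
    stop("mesher produced no elements for region 'cortical': ",
         "edge length ", h, " m too coarse for the outer ellipsoid")
  cen <- (raw$nodes[raw$elems[, 1], ] + raw$nodes[raw$elems[, 2], ] +
            raw$nodes[raw$elems[, 3], ] + raw$nodes[raw$elems[, 4], ]) / 4
  labels <- c("cortical", "cancellous", "csf", "brain", "ventricle_csf")
  region <- integer(nrow(cen))
  region[rho(cen, a1) > 1] <- 1L
  region[region == 0L & rho(cen, a2) > 1] <- 2L
  region[region == 0L & rho(cen, a3) > 1] <- 3L
  region[region == 0L & rho(cen, av) <= 1] <- 5L
  region[region == 0L] <- 4L
  missing <- setdiff(seq_along(labels), unique(region))
  if (length(missing))
    stop("mesher failure at requested edge length for region(s): ",
         paste(labels[missing], collapse = ", "),
         " (refine target_edge_length)")
  mesh <- .finalize_mesh(raw$nodes, raw$elems, region, labels, h)
  mesh$geometry <- geometry
  mesh$seed <- as.integer(seed)
  mesh
}

#' Generate a box mesh (verification fixture)
#'
#' Kuhn-lattice tetrahedralization of an axis-aligned box, used for the
#' solver verification problems (patch test, bars, contact blocks).
#'
#' @param lengths length-3 box dimensions (m).
#' @param ncell length-3 number of cells per axis.
#' @param origin length-3 corner coordinates (m).
#' @param label region label for all elements.
#' @return a `phantom_mesh` with a single region.
#' @export
generate_box_mesh <- function(lengths, ncell, origin = c(0, 0, 0),
                              label = "solid") {
  stopifnot(length(lengths) == 3, all(lengths > 0),
            length(ncell) == 3, all(ncell >= 1))
  raw <- .lattice_mesh(origin, as.integer(ncell), lengths / ncell)
  .finalize_mesh(raw$nodes, raw$elems, rep(1L, nrow(raw$elems)), label,
                 max(lengths / ncell))
}

#' Minimum dihedral angle of a tetrahedral mesh
#'
#' Element quality measure; the Kuhn lattice tets used here have a fixed
#' quality with minimum dihedral angle of 45 degrees.
#'
#' @param mesh a `phantom_mesh`.
#' @return smallest dihedral angle over all elements, degrees.
#' @export
mesh_min_dihedral <- function(mesh) {
  nodes <- mesh$nodes; elems <- mesh$elems
  face_idx <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  normals <- vector("list", 4L)
  for (f in 1:4) {
    tri <- elems[, face_idx[f, ], drop = FALSE]
    a <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
    b <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
    nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    normals[[f]] <- nrm / sqrt(rowSums(nrm^2))
  }
  mn <- Inf
  for (f1 in 1:3) for (f2 in (f1 + 1):4) {
    cosang <- rowSums(normals[[f1]] * normals[[f2]])
    ang <- 180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    mn <- min(mn, ang)
  }
  mn
}

#' Euler characteristic of the mesh boundary surface
#'
#' V - E + F over the boundary triangulation; 2 for a closed surface
#' homeomorphic to a sphere.
#'
#' @param mesh a `phantom_mesh`.
#' @return integer Euler characteristic.
#' @export
boundary_euler_characteristic <- function(mesh) {
  tri <- mesh$boundary_facets
  v <- length(unique(as.integer(tri)))
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  e <- nrow(unique(edges))
  v - e + nrow(tri)
}

#' Region volumes of a phantom mesh
#'
#' @param mesh a `phantom_mesh`.
#' @return named numeric vector of summed element volumes per region (m^3).
#' @export
region_volumes <- function(mesh) {
  v <- tapply(mesh$volumes, factor(mesh$region,
                                   levels = seq_along(mesh$region_labels),
                                   labels = mesh$region_labels), sum)
  v[is.na(v)] <- 0
  v
}

# ---- mesh writers -----------------------------------------------------------

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Region labels are stored as the physical and elementary tags of each
#' tetrahedron.
#'
#' @param mesh a `phantom_mesh`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(nrow(mesh$elems))), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(mesh$elems)),
                     mesh$region, mesh$region, mesh$elems[, 1],
                     mesh$elems[, 2], mesh$elems[, 3], mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write a mesh (with optional cell data) as VTK unstructured grid (VTU)
#'
#' ASCII XML VTU with the integer region label as cell data, plus any extra
#' per-cell or per-point arrays.
#'
#' @param mesh a `phantom_mesh`.
#' @param path output file path.
#' @param cell_data named list of numeric vectors (length = n elements).
#' @param point_data named list of numeric vectors or 3-column matrices
#'   (length/rows = n nodes).
#' @param points optional deformed nodal coordinates to write instead of the
#'   reference ones.
#' @return the path, invisibly.
#' @export
write_vtu <- function(mesh, path, cell_data = list(), point_data = list(),
                      points = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  xyz <- if (is.null(points)) mesh$nodes else points
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.10g %.10g %.10g", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(sprintf("%d %d %d %d", mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
                     mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(m) * 4L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('        </DataArray>')
  w('      </Cells>')
  cell_data <- c(list(region = as.numeric(mesh$region)), cell_data)
  w('      <CellData>')
  for (nm in names(cell_data)) {
    w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
              nm))
    writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        w(sprintf(paste0('        <DataArray type="Float64" Name="%s" ',
                         'NumberOfComponents="3" format="ascii">'), nm))
        writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
                  nm))
        writeLines(sprintf("%.10g", v), con)
      }
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
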