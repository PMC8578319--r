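# File formats: VTK legacy and Gmsh v2 for meshes and fields, GeoJSON for
# region polygons, NIfTI for images, CSV/JSON for profiles and reports,
# YAML for run configurations.

#' Write a mesh (with optional fields) as legacy VTK
#'
#' ASCII legacy VTK unstructured grid with triangle cells; nodal fields go
#' to POINT_DATA, per-element fields to CELL_DATA. 2D coordinates are
#' written with z = 0.
#'
#' @param mesh a `vent_mesh`.
#' @param path output file.
#' @param point_data named list of per-node scalar vectors or two-column
#'   matrices (written as vectors with z = 0).
#' @param cell_data named list of per-triangle scalar vectors.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("# vtk DataFile Version 2.0")
  w("ventmech export")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS ", n, " double")
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  w("CELLS ", m, " ", 4 * m)
  utils::write.table(cbind(3L, mesh$tri - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  w("CELL_TYPES ", m)
  writeLines(rep("5", m), con)
  if (length(point_data) > 0) {
    w("POINT_DATA ", n)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        w("VECTORS ", nm, " double")
        utils::write.table(cbind(v, 0), con, row.names = FALSE,
                           col.names = FALSE)
      } else {
        w("SCALARS ", nm, " double 1")
        w("LOOKUP_TABLE default")
        writeLines(format(v, trim = TRUE), con)
      }
    }
  }
  if (length(cell_data) > 0) {
    w("CELL_DATA ", m)
    for (nm in names(cell_data)) {
      w("SCALARS ", nm, " double 1")
      w("LOOKUP_TABLE default")
      writeLines(format(cell_data[[nm]], trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Write a mesh in Gmsh v2 ASCII format
#'
#' Region tags become physical surface groups (1 = white_matter, 2 =
#' gray_matter, 3 = csf; other regions are numbered in order of
#' appearance).
#'
#' @param mesh a `vent_mesh`.
#' @param path output file.
#' @export
write_msh <- function(mesh, path) {
  regions <- unique(mesh$region)
  canon <- c("white_matter", "gray_matter", "csf")
  regs <- c(intersect(canon, regions), setdiff(regions, canon))
  rid <- match(mesh$region, regs)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(length(regs))
  for (i in seq_along(regs)) w("2 ", i, " \"", regs[i], "\"")
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Nodes"); w(n)
  utils::write.table(cbind(seq_len(n), mesh$nodes, 0), con,
                     row.names = FALSE, col.names = FALSE)
  w("$EndNodes")
  m <- nrow(mesh$tri)
  w("$Elements"); w(m)
  utils::write.table(cbind(seq_len(m), 2L, 2L, rid, rid, mesh$tri), con,
                     row.names = FALSE, col.names = FALSE)
  w("$EndElements")
  invisible(path)
}

#' Read a Gmsh v2 ASCII mesh written by [write_msh()]
#'
#' @param path file path.
#' @return a `vent_mesh` (without boundary sets or tips).
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(tag) {
    i0 <- which(lines == paste0("$", tag)) + 1L
    i1 <- which(lines == paste0("$End", tag)) - 1L
    lines[i0:i1]
  }
  pn <- sect("PhysicalNames")
  k <- as.integer(pn[1])
  regs <- character(k)
  for (i in seq_len(k)) {
    f <- strsplit(pn[i + 1], " ")[[1]]
    regs[as.integer(f[2])] <- gsub("\"", "", f[3])
  }
  nd <- sect("Nodes")
  nmat <- matrix(scan(text = nd[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
  el <- sect("Elements")
  emat <- matrix(as.integer(scan(text = el[-1], quiet = TRUE)), ncol = 8,
                 byrow = TRUE)
  mesh <- list(
    nodes = nmat[, 2:3, drop = FALSE],
    tri = emat[, 6:8, drop = FALSE],
    region = regs[emat[, 4]],
    h = NA_real_, origin = rep("file", nrow(nmat)),
    bsets = list(), tips = NULL, min_angle = NA_real_
  )
  class(mesh) <- "vent_mesh"
  mesh
}

#' Write region polygons as GeoJSON
#'
#' One Feature per region with a `region` property, coordinates in mm.
#'
#' @param geometry a `vent_geometry`.
#' @param path output file.
#' @export
write_geometry_geojson <- function(geometry, path) {
  feats <- lapply(names(geometry$region_polygons), function(r) {
    P <- geometry$region_polygons[[r]]
    ring <- rbind(P, P[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(region = r),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(
                        lapply(seq_len(nrow(ring)),
                               function(i) as.numeric(ring[i, ])))))
    )
  })
  obj <- list(type = "FeatureCollection",
              properties = list(provenance = geometry$provenance),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region polygons from GeoJSON written by [write_geometry_geojson()]
#'
#' @param path file path.
#' @return a `vent_geometry` (provenance `"external"` unless recorded).
#' @export
read_geometry_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  polys <- list()
  for (f in obj$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    polys[[f$properties$region]] <- ring[-nrow(ring), , drop = FALSE]
  }
  geom <- list(region_polygons = polys, tips = NULL, arcs = NULL,
               horn_radii = NULL, spec = NULL,
               provenance = obj$properties$provenance %||% "external")
  class(geom) <- "vent_geometry"
  geom
}

#' Write a 2D image as NIfTI
#'
#' Stores the matrix as a single-slice NIfTI volume with the pixel size in
#' the header (mm).
#'
#' @param img numeric or logical matrix.
#' @param path output file (.nii or .nii.gz).
#' @param pixel_size pixel edge (mm).
#' @export
write_image_nifti <- function(img, path, pixel_size = 0.7) {
  arr <- array(as.numeric(img), dim = c(nrow(img), ncol(img), 1))
  hdr <- list(pixdim = c(-1, pixel_size, pixel_size, 1, 0, 0, 0, 0))
  nim <- RNifti::asNifti(arr, hdr)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a 2D image from NIfTI
#'
#' @param path file path.
#' @return list with `img` (matrix) and `pixel_size` (mm).
#' @export
read_image_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  list(img = arr, pixel_size = RNifti::pixdim(nim)[1])
}

#' Write the wall profile (with frames) as CSV
#'
#' @param profile a [project_wall_stretches()] profile.
#' @param path output file.
#' @export
write_wall_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write horn metrics as JSON
#'
#' @param horns a [horn_metrics()] object.
#' @param path output file.
#' @export
write_horn_metrics_json <- function(horns, path) {
  jsonlite::write_json(
    list(horns = horns$horns,
         wall_fraction_elevated = horns$wall_fraction_elevated,
         drop_fraction = horns$drop_fraction),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' The nested spec/material/load objects are flattened to plain lists with
#' unit-suffixed names and reconstructed on read.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  flat <- list(
    spec = unclass(config$spec),
    materials = list(mu_kpa = as.list(config$materials$mu),
                     kappa_kpa = as.list(config$materials$kappa)),
    loads = list(p_lv_pa = config$loads$p_lv,
                 p_sas_pa = config$loads$p_sas),
    pipeline = config[setdiff(names(config),
                              c("spec", "materials", "loads"))]
  )
  yaml::write_yaml(flat, path, precision = 12)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  flat <- yaml::read_yaml(path)
  spec <- do.call(subject_spec, c(
    flat$spec[setdiff(names(flat$spec), "cortex_semiaxes")],
    list(cortex_semiaxes = unlist(flat$spec$cortex_semiaxes))
  ))
  mats <- material_params()
  mats$mu <- unlist(flat$materials$mu_kpa)
  mats$kappa <- unlist(flat$materials$kappa_kpa)
  loads <- load_case(p_lv = flat$loads$p_lv_pa, p_sas = flat$loads$p_sas_pa)
  do.call(run_config, c(list(spec = spec, materials = mats, loads = loads),
                        flat$pipeline))
}
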