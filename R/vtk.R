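#' Write a mesh (with optional cell fields) as VTK legacy ASCII
#'
#' Unstructured-grid legacy format, quad cells, with per-cell data arrays.
#' Region and vessel id are always written; numeric fields are written at
#' full double precision so a reload reproduces them bit-exactly.
#'
#' @param mesh a `"phantom_mesh"`.
#' @param path output file.
#' @param fields named list of per-element numeric/logical vectors.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, fields = list(), title = "headblast phantom") {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elem)
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elem[, 1] - 1L, mesh$elem[, 2] - 1L,
                     mesh$elem[, 3] - 1L, mesh$elem[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.integer(mesh$region)), con)
  writeLines(c("SCALARS vessel_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", mesh$vessel_id), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (is.logical(v)) {
      writeLines(c(sprintf("SCALARS %s int 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%d", as.integer(v)), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", v), con)
    }
  }
  invisible(path)
}

#' Read back a VTK legacy file written by [write_mesh_vtk()]
#'
#' Minimal reader for the subset of the legacy format this package writes;
#' round-trips points and cell fields bit-exactly.
#'
#' @param path VTK file.
#' @return list with `nodes`, `elem`, and `fields` (named list of cell
#'   arrays, including `region` and `vessel_id` as integers).
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  nn <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- do.call(rbind, strsplit(ln[ip + seq_len(nn)], " "))
  nodes <- cbind(as.numeric(pts[, 1]), as.numeric(pts[, 2]))
  ic <- grep("^CELLS", ln)[1]
  ne <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cl <- do.call(rbind, strsplit(ln[ic + seq_len(ne)], " "))
  elem <- matrix(as.integer(cl[, 2:5]), ne, 4) + 1L
  fields <- list()
  for (i in grep("^SCALARS", ln)) {
    parts <- strsplit(ln[i], " ")[[1]]
    nm <- parts[2]; typ <- parts[3]
    vals <- ln[i + 1 + seq_len(ne)]
    fields[[nm]] <- if (typ == "int") as.integer(vals) else as.numeric(vals)
  }
  list(nodes = nodes, elem = elem, fields = fields)
}

#' Write a simulation's snapshot series and summaries
#'
#' One VTK legacy file per stored snapshot (pressure, cavitation flags and
#' the running maxima at end time), plus CSV summary tables, a structured
#' pattern report and a run manifest with file checksums.
#'
#' @param sim a `"blast_sim"`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_vtk_series <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  m <- sim$maxima
  for (k in seq_along(sim$snapshots)) {
    s <- sim$snapshots[[k]]
    f <- file.path(dir, sprintf("snapshot_%04d.vtk", k))
    write_mesh_vtk(sim$mesh, f,
                   fields = list(pressure_kPa = s$pressure,
                                 cavitating_now = s$cavitating,
                                 ever_cavitated = m$ever_cavitated,
                                 max_shear_strain = m$max_shear_strain,
                                 max_dil_strain = m$max_dil_strain,
                                 max_shear_rate = m$max_shear_rate,
                                 max_dil_rate = m$max_dil_rate),
                   title = sprintf("t = %.6f ms", s$time))
    files <- c(files, f)
  }
  files
}

#' @rdname write_vtk_series
#' @export
write_summaries <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "region_summary.csv")
  utils::write.csv(region_summary(sim), f, row.names = FALSE)
  files <- c(files, f)
  if (any(sim$mesh$vessel_id > 0)) {
    f <- file.path(dir, "vessel_summary.csv")
    utils::write.csv(vessel_cavitation_summary(sim), f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "pattern_report.json")
  rep <- cavitation_pattern_report(sim)
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE), f)
  files <- c(files, f)
  f <- file.path(dir, "energy_ledger.csv")
  utils::write.csv(sim$energy, f, row.names = FALSE)
  files <- c(files, f)
  man <- run_manifest(sim, files)
  fm <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE), fm)
  invisible(c(files, fm))
}

#' Run manifest
#'
#' Reproducibility record: configuration snapshot, package version, mesh
#' hash and an inventory of output files with checksums.
#'
#' @param sim a `"blast_sim"`.
#' @param files files to inventory.
#' @return list (serializable to JSON).
#' @export
run_manifest <- function(sim, files = character()) {
  cfg <- sim$config
  list(package = "headblast",
       version = as.character(utils::packageVersion("headblast")),
       scenario = list(peak_overpressure_kPa = cfg$scenario$peak_overpressure,
                       duration_ms = cfg$scenario$duration,
                       decay = cfg$scenario$decay,
                       direction = cfg$scenario$direction,
                       wall = cfg$scenario$wall),
       materials_preset = attr(cfg$materials, "preset"),
       end_time_ms = cfg$end_time,
       cfl_factor = cfg$cfl_factor,
       dt_s = sim$dt, n_steps = sim$n_steps,
       n_elements = nrow(sim$mesh$elem),
       mesh_hash = mesh_hash(sim$mesh),
       files = lapply(stats::setNames(as.list(files), basename(files)),
                      function(f) unname(tools::md5sum(f))))
}

#' @rdname run_manifest
#' @param mesh a `"phantom_mesh"`.
#' @export
mesh_hash <- function(mesh) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(round(mesh$nodes, 12), mesh$elem, as.integer(mesh$region)), f)
  unname(tools::md5sum(f))
}
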