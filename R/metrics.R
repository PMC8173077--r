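#' Scalar strain invariants used by the output metrics
#'
#' The reported "shear strain" is the largest in-plane principal shear of
#' the accumulated strain tensor, \eqn{(\varepsilon_1 - \varepsilon_2)/2 =
#' \sqrt{((\varepsilon_{xx}-\varepsilon_{yy})/2)^2 + \varepsilon_{xy}^2}};
#' the "dilatational strain" is the in-plane trace. Rates divide per-step
#' increments by the step size.
#'
#' @param eps n x 3 matrix of strain components `(xx, yy, xy)` (tensor
#'   shear).
#' @return data.frame with `shear` and `dilatational` columns.
#' @export
strain_invariants <- function(eps) {
  eps <- matrix(eps, ncol = 3)
  data.frame(shear = sqrt(((eps[, 1] - eps[, 2]) / 2)^2 + eps[, 3]^2),
             dilatational = eps[, 1] + eps[, 2])
}

#' Update element-wise running maxima
#'
#' Given the accumulated strain after a step, the step increment and the
#' step size, updates the four running maxima: max |shear strain|, max
#' |dilatational strain|, max |shear strain rate|, max |dilatational
#' strain rate|. This is the reference implementation of the bookkeeping
#' the solver kernel performs every step.
#'
#' @param maxima n x 4 matrix (may be zero-initialized).
#' @param eps_acc n x 3 accumulated strain after the step.
#' @param deps n x 3 strain increment of the step.
#' @param dt step size (s).
#' @return updated n x 4 matrix.
#' @export
update_running_maxima <- function(maxima, eps_acc, deps, dt) {
  stopifnot(dt > 0)
  a <- strain_invariants(eps_acc)
  d <- strain_invariants(deps)
  cbind(pmax(maxima[, 1], abs(a$shear)),
        pmax(maxima[, 2], abs(a$dilatational)),
        pmax(maxima[, 3], abs(d$shear) / dt),
        pmax(maxima[, 4], abs(d$dilatational) / dt))
}

element_centroids <- function(mesh) {
  cbind(rowMeans(matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)),
        rowMeans(matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)))
}

# minimum distance from each centroid in `from` to a set of node positions
min_dist_nodes <- function(cent, from, pts) {
  out <- rep(Inf, sum(from))
  if (nrow(pts) == 0) return(out)
  fc <- cent[from, , drop = FALSE]
  step <- max(1L, floor(2e6 / nrow(pts)))
  for (s in seq(1, nrow(fc), by = step)) {
    e <- min(nrow(fc), s + step - 1L)
    d2 <- outer(fc[s:e, 1], pts[, 1], `-`)^2 + outer(fc[s:e, 2], pts[, 2], `-`)^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Classify elements into anatomical interface bands
#'
#' Labels tissue elements by proximity to the interfaces of interest:
#' `perivascular` (tissue within the band width of a vessel wall),
#' `periventricular` (white matter near a ventricle), `subpial` (gray
#' matter near CSF), `gray-white` (either tissue near that interface),
#' everything else `bulk`. Distances are measured from element centroids to
#' the shared interface nodes; elements touching an interface node are
#' always in its band, so the one-element band survives any mesh
#' resolution. Precedence: vessel > ventricle > pial > gray-white.
#'
#' @param mesh a `"phantom_mesh"`.
#' @param band_width band width (mm, > 0; default 1).
#' @return character vector, one label per element (non-tissue elements
#'   get `""`).
#' @export
classify_interface_bands <- function(mesh, band_width = 1) {
  if (band_width <= 0) stop("band_width must be positive")
  cent <- element_centroids(mesh)
  reg <- as.character(mesh$region)
  tissue <- reg %in% c("GRAY", "WHITE")
  lab <- ifelse(tissue, "bulk", "")

  nodes_of <- function(sel) unique(as.vector(mesh$elem[sel, , drop = FALSE]))
  in_band <- function(from, iface_nodes) {
    if (length(iface_nodes) == 0) return(rep(FALSE, nrow(mesh$elem)))
    touch <- matrix(mesh$elem %in% iface_nodes, nrow(mesh$elem), 4)
    near <- rep(FALSE, nrow(mesh$elem))
    near[from] <- min_dist_nodes(cent, from,
                                 mesh$nodes[iface_nodes, , drop = FALSE]) <= band_width
    from & (rowSums(touch) > 0 | near)
  }

  gray <- reg == "GRAY"; white <- reg == "WHITE"
  gw_nodes <- intersect(nodes_of(gray), nodes_of(white))
  lab[in_band(tissue, gw_nodes)] <- "gray-white"
  pial_nodes <- intersect(nodes_of(gray), nodes_of(reg == "CSF"))
  lab[in_band(gray, pial_nodes)] <- "subpial"
  vent_nodes <- intersect(nodes_of(white), nodes_of(reg == "VENTRICLE"))
  lab[in_band(white, vent_nodes)] <- "periventricular"
  is_wall <- mesh$vessel_id > 0 & reg != "VESSEL_LUMEN"
  if (any(is_wall)) {
    lab[in_band(tissue, nodes_of(is_wall)) | is_wall] <- "perivascular"
  }
  lab
}

#' Per-band region summary
#'
#' Cavitated area and strain/strain-rate percentiles per interface band.
#'
#' @param sim a `"blast_sim"`.
#' @param band_width band width (mm).
#' @return data.frame: band, element count, area, cavitated area (mm^2),
#'   95th-percentile max shear strain and max shear strain rate.
#' @export
region_summary <- function(sim, band_width = 1) {
  lab <- classify_interface_bands(sim$mesh, band_width)
  m <- sim$maxima
  bands <- c("subpial", "perivascular", "periventricular", "gray-white", "bulk")
  out <- do.call(rbind, lapply(bands, function(b) {
    sel <- lab == b
    if (!any(sel)) return(data.frame(band = b, n = 0, area_mm2 = 0,
                                     cavitated_area_mm2 = 0,
                                     p95_max_shear_strain = NA_real_,
                                     p95_max_shear_rate = NA_real_))
    data.frame(band = b, n = sum(sel), area_mm2 = sum(sim$mesh$area[sel]),
               cavitated_area_mm2 = sum(sim$mesh$area[sel & m$ever_cavitated]),
               p95_max_shear_strain =
                 unname(stats::quantile(m$max_shear_strain[sel], 0.95)),
               p95_max_shear_rate =
                 unname(stats::quantile(m$max_shear_rate[sel], 0.95)))
  }))
  rownames(out) <- NULL
  out
}

#' Per-vessel cavitation summary
#'
#' Cavitated lumen area and fraction plus the maximum wall-band shear
#' strain rate, per embedded vessel, ordered by diameter and position.
#'
#' @param sim a `"blast_sim"` run on a vascular mesh, or a list with
#'   `mesh` and `maxima` fields.
#' @return data.frame: vessel id, diameter (mm), position index, lumen
#'   area, cavitated lumen area (mm^2), cavitated fraction, max wall-band
#'   shear strain rate (1/s).
#' @export
vessel_cavitation_summary <- function(sim) {
  mesh <- sim$mesh; m <- sim$maxima
  ids <- sort(unique(mesh$vessel_id[mesh$vessel_id > 0]))
  spec <- mesh$params$vessel_spec
  out <- do.call(rbind, lapply(ids, function(v) {
    lum <- mesh$vessel_id == v & mesh$region == "VESSEL_LUMEN"
    wall <- mesh$vessel_id == v & mesh$region != "VESSEL_LUMEN"
    la <- sum(mesh$area[lum])
    ca <- sum(mesh$area[lum & m$ever_cavitated])
    data.frame(vessel = v,
               diameter = spec[[v]]$diameter,
               position = spec[[v]]$position,
               lumen_area_mm2 = la, cavitated_area_mm2 = ca,
               cavitated_fraction = ca / la,
               max_wall_shear_rate =
                 if (any(wall)) max(m$max_shear_rate[wall]) else NA_real_)
  }))
  if (is.null(out))
    out <- data.frame(vessel = integer(), diameter = numeric(),
                      position = integer(), lumen_area_mm2 = numeric(),
                      cavitated_area_mm2 = numeric(),
                      cavitated_fraction = numeric(),
                      max_wall_shear_rate = numeric())
  out[order(out$diameter, out$position), ]
}

#' Structured cavitation pattern report
#'
#' Per-region cavitated areas, presence flags for sulcal and ventricular
#' cavitation, and a coup/contrecoup asymmetry index of the cavitated area
#' along the blast direction through the mesh centroid (+1 = all on the
#' struck side, -1 = all opposite, 0 = balanced or none).
#'
#' @param sim a `"blast_sim"`.
#' @param scenario scenario used (defaults to the one in the config).
#' @return list with `region_cavitated_area` (named, mm^2), flags
#'   `sulcal_cavitation`, `ventricular_cavitation`, `asymmetry_index`,
#'   and `total_cavitated_area`.
#' @export
cavitation_pattern_report <- function(sim, scenario = sim$config$scenario) {
  mesh <- sim$mesh
  cav <- sim$maxima$ever_cavitated
  reg <- as.character(mesh$region)
  areas <- tapply(mesh$area * cav, reg, sum)
  areas[is.na(areas)] <- 0
  cent <- element_centroids(mesh)
  # sulcal CSF: outer-CSF elements radially inside the gyral crown line,
  # i.e. CSF deeper than the skull-adjacent layer
  csf <- reg == "CSF"
  sulcal <- csf & in_sulcus(mesh)
  d <- scenario$direction
  proj <- as.numeric(scale(cent %*% d, scale = FALSE))
  wcav <- mesh$area * cav
  coup <- sum(wcav[proj < 0])    # struck side: earliest arrival = most negative
  # arrival increases with projection on d; struck side has smaller proj
  contre <- sum(wcav[proj >= 0])
  denom <- coup + contre
  list(region_cavitated_area = as.list(areas),
       sulcal_cavitation = sum(mesh$area[sulcal & cav]) > 0,
       sulcal_cavitated_area = sum(mesh$area[sulcal & cav]),
       ventricular_cavitation = areas[["VENTRICLE"]] > 0,
       asymmetry_index = if (denom > 0) (coup - contre) / denom else 0,
       total_cavitated_area = sum(wcav))
}

# CSF elements lying inside a sulcus: deeper than the crown baseline of
# the cortical boundary (works for the polar phantom layout)
in_sulcus <- function(mesh) {
  if (is.null(mesh$params)) return(rep(FALSE, nrow(mesh$elem)))
  p <- mesh$params
  cent <- element_centroids(mesh)
  a <- p$brain_width / 2; b <- p$brain_length / 2
  # crown ellipse: points with sqrt((x/a)^2 + (y/b)^2) < 1 are inside it
  rho <- sqrt((cent[, 1] / a)^2 + (cent[, 2] / b)^2)
  as.character(mesh$region) == "CSF" & rho < 1 - 0.25 * p$gray_thickness / min(a, b)
}
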