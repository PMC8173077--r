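#' Parameters of the 2D mid-plane head phantom
#'
#' The phantom emulates an idealized axial mid-plane of a human head:
#' an elliptical brain with a periodic gyral/sulcal cortical boundary,
#' a constant-thickness gray-matter ribbon, CSF filling the sulci and the
#' skull-brain gap, a closed elastic skull shell, paired ventricles as
#' CSF-filled cavities inside the white matter, and optional circular
#' fluid-filled vessel channels with resolved wall bands.
#'
#' Absolute dimensions are generator defaults chosen to match typical adult
#' axial proportions (they are not literature values): brain 140 x 170 mm,
#' skull 7 mm, CSF layer 2.5 mm, gray 3 mm, 8 gyri per side.
#'
#' @param brain_width,brain_length brain axis extents (mm).
#' @param skull_thickness,csf_layer_thickness,gray_thickness layer
#'   thicknesses (mm).
#' @param n_gyri_per_side gyri per hemisphere; 0 gives a smooth convex
#'   cortical boundary.
#' @param sulcal_depth,sulcal_width sulcus depth and full width (mm).
#' @param ventricle_shape list of closed polygons (n x 2 matrices, mm), or
#'   `NULL` for the default paired ventricles.
#' @param vessel_spec list of vessels, each `list(diameter, position,
#'   center)` with diameter in mm (0.6, 0.8, 1.2 or 1.6), position index
#'   1-6 (1 = most peripheral) and center (mm). See [vessel_array_spec()].
#' @param target_element_size nominal element size (mm).
#' @param min_elements_through_thin_layers resolution contract for the
#'   skull, CSF and gray layers and the vessel wall bands (default 5).
#' @param jitter amplitude of optional smooth cortical boundary jitter (mm,
#'   default 0 = deterministic shape).
#' @param seed integer seed controlling only the jitter.
#' @return object of class `"geometry_params"`.
#' @export
geometry_params <- function(brain_width = 140, brain_length = 170,
                            skull_thickness = 7, csf_layer_thickness = 2.5,
                            gray_thickness = 3, n_gyri_per_side = 8,
                            sulcal_depth = 12, sulcal_width = 8,
                            ventricle_shape = NULL, vessel_spec = list(),
                            target_element_size = 2,
                            min_elements_through_thin_layers = 5L,
                            jitter = 0, seed = 1L) {
  p <- list(brain_width = brain_width, brain_length = brain_length,
            skull_thickness = skull_thickness,
            csf_layer_thickness = csf_layer_thickness,
            gray_thickness = gray_thickness,
            n_gyri_per_side = as.integer(n_gyri_per_side),
            sulcal_depth = sulcal_depth, sulcal_width = sulcal_width,
            ventricle_shape = ventricle_shape, vessel_spec = vessel_spec,
            target_element_size = target_element_size,
            min_elements_through_thin_layers =
              as.integer(min_elements_through_thin_layers),
            jitter = jitter, seed = as.integer(seed))
  lens <- c(brain_width, brain_length, skull_thickness, csf_layer_thickness,
            gray_thickness, sulcal_width, target_element_size)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (sulcal_depth < 0 || sulcal_depth >= brain_width / 2)
    stop("sulcal_depth must be in [0, brain half-width)")
  if (p$min_elements_through_thin_layers < 1)
    stop("min_elements_through_thin_layers must be >= 1")
  if (is.null(p$ventricle_shape))
    p$ventricle_shape <- default_ventricles(p)
  for (v in p$vessel_spec)
    if (!all(c("diameter", "position", "center") %in% names(v)))
      stop("each vessel_spec entry needs diameter, position, center")
  class(p) <- "geometry_params"
  p
}

# Paired lateral ventricles: mirrored rotated ellipses near the center.
default_ventricles <- function(p) {
  sc <- min(p$brain_width / 140, p$brain_length / 170)
  ell <- function(cx, cy, a, b, rot, n = 28) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    x <- a * cos(th); y <- b * sin(th)
    cbind(cx + x * cos(rot) - y * sin(rot), cy + x * sin(rot) + y * cos(rot))
  }
  list(ell(-9 * sc, 2 * sc, 4.5 * sc, 14 * sc, 10 * pi / 180),
       ell(9 * sc, 2 * sc, 4.5 * sc, 14 * sc, -10 * pi / 180))
}

#' Default vessel array
#'
#' Places vessels on straight rays from the cortex toward the ventricles,
#' one ray per diameter, at six evenly spaced depths; position 1 is closest
#' to the periphery. Centers are computed from the phantom proportions.
#'
#' @param params a [geometry_params()] (vessel-free; used for proportions).
#' @param diameters vessel diameters (mm), one ray each.
#' @param positions depth indices to include (subset of 1:6).
#' @return list of `list(diameter, position, center)` entries suitable for
#'   the `vessel_spec` field.
#' @export
vessel_array_spec <- function(params = geometry_params(),
                              diameters = c(0.6, 0.8, 1.2, 1.6),
                              positions = 1:6) {
  stopifnot(all(diameters %in% c(0.6, 0.8, 1.2, 1.6)))
  ray_angles <- c(-48, -16, 16, 48)[seq_along(diameters)] * pi / 180
  a <- params$brain_width / 2; b <- params$brain_length / 2
  h <- params$target_element_size
  a_c <- 0.8 * 0.35 * min(a, b)     # core block half-width (matches builder)
  spec <- list()
  for (k in seq_along(diameters)) {
    th <- ray_angles[k]
    u <- c(a * cos(th), b * sin(th)); u <- u / sqrt(sum(u^2))
    r_crown <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
    r_sqv <- a_c / max(abs(cos(th)), abs(sin(th)))
    # keep the embedding patches inside white matter and apart; successive
    # depths alternate a small lateral stagger so their patches stay
    # angularly disjoint even where radial spacing is tight
    r_outer <- r_crown - params$sulcal_depth - params$gray_thickness - 2.2 * h - 1
    r_inner <- r_sqv + 2.2 * h + 1
    if ((r_outer - r_inner) / 5 < 2.2 * h)
      stop(sprintf(paste0("resolution contract violated: six vessel positions ",
                          "need spacing >= 2.2 x element size along the ray ",
                          "(have %.2g mm, need %.2g mm); reduce ",
                          "target_element_size"),
                   (r_outer - r_inner) / 5, 2.2 * h))
    rr <- seq(r_outer, r_inner, length.out = 6)
    perp <- c(-u[2], u[1])
    off <- 1.6 * 0.6 * diameters[k] + 1.5
    for (j in positions)
      spec[[length(spec) + 1]] <- list(diameter = diameters[k], position = j,
                                       center = rr[j] * u +
                                         (2 * (j %% 2) - 1) * off * perp)
  }
  spec
}

#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf(paste0("<geometry_params> brain %g x %g mm, skull %g, CSF %g, ",
                     "gray %g mm\n  %d gyri/side (depth %g, width %g mm), ",
                     "%d vessels, h = %g mm\n"),
              x$brain_width, x$brain_length, x$skull_thickness,
              x$csf_layer_thickness, x$gray_thickness, x$n_gyri_per_side,
              x$sulcal_depth, x$sulcal_width, length(x$vessel_spec),
              x$target_element_size))
  invisible(x)
}

# signed areas of quads (shoelace)
quad_areas_signed <- function(nodes, elem) {
  x <- matrix(nodes[elem, 1], nrow(elem), 4)
  y <- matrix(nodes[elem, 2], nrow(elem), 4)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
           (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
           (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
           (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py)
    xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

# Coons (transfinite) patch: edges b (bottom), t (top), l (left), r (right)
# are (m+1) x 2 matrices; returns array [(m+1) x (m+1) x 2] grid.
coons_patch <- function(b, t, l, r) {
  m <- nrow(b) - 1L
  s <- seq(0, 1, length.out = m + 1)
  g <- array(0, c(m + 1, m + 1, 2))
  for (d in 1:2) {
    for (j in seq_len(m + 1)) {
      v <- s[j]
      g[, j, d] <- (1 - v) * b[, d] + v * t[, d] +
        (1 - s) * l[j, d] + s * r[j, d] -
        ((1 - s) * (1 - v) * b[1, d] + s * (1 - v) * b[m + 1, d] +
           (1 - s) * v * t[1, d] + s * v * t[m + 1, d])
    }
  }
  g
}

#' Build the 2D head phantom mesh
#'
#' Generates a conformal all-quadrilateral mesh of the mid-plane phantom:
#' a structured polar multi-block layout (skull, CSF, gray rings following
#' the gyral boundary; white rings blending into a central Coons-patch core
#' block), with ventricles labeled as CSF-filled cavities and vessels
#' embedded by local patch remeshing (radial O-grid with a five-element
#' wall band of total thickness 10% of the vessel diameter around each
#' lumen). The mesh is deterministic given the parameters and seed.
#'
#' @param params a [geometry_params()].
#' @return object of class `"phantom_mesh"`: list with `nodes` (n x 2, mm),
#'   `elem` (quads, 1-based CCW), `region` (factor: SKULL, GRAY, WHITE,
#'   CSF, VENTRICLE, VESSEL_LUMEN), `vessel_id` (integer, 0 = none; set on
#'   lumen and wall-band elements), `vessel_part` ("", "lumen", "wall"),
#'   `area` (mm^2), `boundary_faces` (exterior edges with outward normals),
#'   `params`.
#' @export
build_head_geometry <- function(params = geometry_params()) {
  p <- params
  h <- p$target_element_size
  minel <- p$min_elements_through_thin_layers
  a <- p$brain_width / 2; b <- p$brain_length / 2

  # angular resolution: multiple of 8 so the core square has aligned corners
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  n_theta <- max(40L, as.integer(round(per / h / 8)) * 8L)
  arc <- per / n_theta
  if (p$n_gyri_per_side > 0 && p$sulcal_width < 1.5 * arc)
    stop(sprintf(paste0("resolution contract violated: sulcal_width %.3g mm ",
                        "< 1.5 x angular element spacing %.3g mm; ",
                        "reduce target_element_size or widen sulci"),
                 p$sulcal_width, arc))
  if (p$sulcal_depth > 0 && p$n_gyri_per_side > 0 &&
      p$gray_thickness + p$sulcal_depth >= 0.55 * min(a, b))
    stop("resolution contract violated: sulcal_depth + gray too deep for brain")

  theta <- 2 * pi * (0:(n_theta - 1)) / n_theta
  px <- a * cos(theta); py <- b * sin(theta)
  r_crown <- sqrt(px^2 + py^2)
  ux <- px / r_crown; uy <- py / r_crown

  # sulcal profile: gaussian dips (FWHM = sulcal_width) at evenly spaced
  # sulcus centers, mirror-symmetric about the y axis
  dip <- numeric(n_theta)
  if (p$n_gyri_per_side > 0 && p$sulcal_depth > 0) {
    ns <- 2L * p$n_gyri_per_side
    sulci <- pi / 2 + 2 * pi * (0:(ns - 1)) / ns
    sigma <- p$sulcal_width / 2.355
    for (sc in sulci) {
      dth <- abs(((theta - sc + pi) %% (2 * pi)) - pi)
      dip <- dip + exp(-0.5 * (dth * r_crown / sigma)^2)
    }
    dip <- pmin(dip, 1) * p$sulcal_depth
  }
  if (p$jitter > 0) {
    set.seed(p$seed)
    ph <- stats::runif(3, 0, 2 * pi); am <- stats::runif(3)
    jt <- p$jitter * (am[1] * sin(2 * theta + ph[1]) +
                        am[2] * sin(3 * theta + ph[2]) +
                        am[3] * sin(5 * theta + ph[3])) / sum(am)
    # keep symmetric-capable: jitter applied as-is (asymmetric by design)
    dip <- pmax(dip + jt - min(jt), 0)
  }

  r_brain <- r_crown - dip                     # wavy cortical boundary
  r_gw <- r_brain - p$gray_thickness           # gray-white boundary
  r_skin <- r_crown + p$csf_layer_thickness    # skull inner (smooth)
  r_skout <- r_skin + p$skull_thickness        # skull outer

  n_sk <- max(minel, ceiling(p$skull_thickness / h))
  n_csf <- max(minel, ceiling(p$csf_layer_thickness / h))
  n_gr <- max(minel, ceiling(p$gray_thickness / h))

  r_core <- 0.35 * min(a, b)
  a_c <- 0.8 * r_core                          # core block half-width (param space)
  # block boundary along each ray; corners fall exactly on the 45-degree
  # parameter slots, which the Coons corner indices use
  r_sq <- a_c / pmax(abs(cos(theta)), abs(sin(theta)))
  if (any(r_gw <= r_sq + 2 * h))
    stop("core block too large for the white-matter layer; enlarge brain or shrink layers")
  n_wh <- max(4L, ceiling(stats::median(r_gw - r_sq) / h))

  # ring radius table R[i, j], j = 1..n_rings+1 from skull outer inward
  ring_list <- list()
  addseq <- function(from, to, n) {
    # n+1 radii per theta; drop first row when appending
    sapply(seq(0, 1, length.out = n + 1), function(s) from + s * (to - from))
  }
  R <- addseq(r_skout, r_skin, n_sk)
  R <- cbind(R, addseq(r_skin, r_brain, n_csf)[, -1])
  R <- cbind(R, addseq(r_brain, r_gw, n_gr)[, -1])
  R <- cbind(R, addseq(r_gw, r_sq, n_wh)[, -1])
  n_rings <- ncol(R) - 1L

  nodes <- matrix(0, n_theta * (n_rings + 1L), 2)
  idx <- function(i, j) (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  for (j in seq_len(n_rings + 1L))
    nodes[idx(seq_len(n_theta), j), ] <- cbind(R[, j] * ux, R[, j] * uy)

  # core block: Coons patch on the innermost ring (the square boundary)
  m <- n_theta / 4L
  c_idx <- function(q) as.integer(round(n_theta / 8 + q * n_theta / 4)) %% n_theta + 1L
  # corner angular slots at 45, 135, 225, 315 degrees
  i45 <- c_idx(0); i135 <- c_idx(1); i225 <- c_idx(2); i315 <- c_idx(3)
  ring_ids <- idx(seq_len(n_theta), n_rings + 1L)
  wrapseq <- function(from, to) {   # inclusive angular index walk (CCW)
    if (to >= from) from:to else c(from:n_theta, 1:to)
  }
  bot_i <- wrapseq(i225, i315)                 # u: 0..m at w = 0
  right_i <- wrapseq(i315, i45)                # w: 0..m at u = m
  top_i <- rev(wrapseq(i45, i135))             # u: 0..m at w = m
  left_i <- rev(wrapseq(i135, i225))           # w: 0..m at u = 0
  eb <- nodes[ring_ids[bot_i], , drop = FALSE]
  et <- nodes[ring_ids[top_i], , drop = FALSE]
  el <- nodes[ring_ids[left_i], , drop = FALSE]
  er <- nodes[ring_ids[right_i], , drop = FALSE]
  g <- coons_patch(eb, et, el, er)
  core_id <- matrix(0L, m + 1, m + 1)
  core_id[, 1] <- ring_ids[bot_i]
  core_id[, m + 1] <- ring_ids[top_i]
  core_id[1, ] <- ring_ids[left_i]
  core_id[m + 1, ] <- ring_ids[right_i]
  new_nodes <- matrix(0, (m - 1)^2, 2)
  k <- 0L
  for (jj in 2:m) for (ii in 2:m) {
    k <- k + 1L
    new_nodes[k, ] <- g[ii, jj, ]
    core_id[ii, jj] <- nrow(nodes) + k
  }
  nodes <- rbind(nodes, new_nodes)

  # ring elements (CCW: j+1 ring is inner)
  elems <- vector("list", n_rings + 1L)
  for (j in seq_len(n_rings)) {
    i <- seq_len(n_theta)
    elems[[j]] <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  # core elements
  ce <- matrix(0L, m * m, 4)
  k <- 0L
  for (jj in seq_len(m)) for (ii in seq_len(m)) {
    k <- k + 1L
    ce[k, ] <- c(core_id[ii, jj], core_id[ii + 1, jj],
                 core_id[ii + 1, jj + 1], core_id[ii, jj + 1])
  }
  elems[[n_rings + 1L]] <- ce
  elem <- do.call(rbind, elems)

  # ring element bookkeeping for vessel patch lookup: (i, j) of ring quads
  ring_elem_i <- rep(seq_len(n_theta), n_rings)
  ring_elem_j <- rep(seq_len(n_rings), each = n_theta)
  n_ring_elem <- n_theta * n_rings

  region <- character(nrow(elem))
  jreg <- function(j) {
    if (j <= n_sk) "SKULL"
    else if (j <= n_sk + n_csf) "CSF"
    else if (j <= n_sk + n_csf + n_gr) "GRAY"
    else "WHITE"
  }
  region[seq_len(n_ring_elem)] <- vapply(ring_elem_j, jreg, "")
  region[(n_ring_elem + 1L):nrow(elem)] <- "WHITE"

  # fix orientation to CCW uniformly
  ar <- quad_areas_signed(nodes, elem)
  flip <- ar < 0
  elem[flip, ] <- elem[flip, c(4, 3, 2, 1)]

  # ventricles: centroid-in-polygon relabel of white elements
  cx <- rowMeans(matrix(nodes[elem, 1], nrow(elem), 4))
  cy <- rowMeans(matrix(nodes[elem, 2], nrow(elem), 4))
  for (poly in p$ventricle_shape) {
    inside <- point_in_polygon(cx, cy, poly) & region == "WHITE"
    region[inside] <- "VENTRICLE"
  }

  mesh <- list(nodes = nodes, elem = elem, region = region,
               vessel_id = integer(nrow(elem)),
               vessel_part = character(nrow(elem)))

  # vessel embedding by patch remeshing
  if (length(p$vessel_spec) > 0) {
    used <- rep(FALSE, nrow(elem))
    keep <- rep(TRUE, nrow(elem))
    add_nodes <- list(); add_elem <- list(); add_region <- list()
    add_vid <- list(); add_part <- list(); centers <- list()
    for (vk in seq_along(p$vessel_spec)) {
      v <- p$vessel_spec[[vk]]
      ctr <- as.numeric(v$center)
      D <- v$diameter
      r_lum <- D / 2; r_w <- 0.6 * D   # lumen + 10% diameter wall band
      # containing ring cell
      d2 <- (cx - ctr[1])^2 + (cy - ctr[2])^2
      cand <- order(d2)[1]
      if (cand > n_ring_elem || region[cand] != "WHITE")
        stop(sprintf("vessel %d: center not inside the white-matter ring region", vk))
      ic <- ring_elem_i[cand]; jc <- ring_elem_j[cand]
      # rectangular odd x odd block sized per direction: angular cells
      # shrink toward the core, so angular and radial extents are chosen
      # independently; any odd x odd block has a loop length divisible by 4
      arc_c <- sqrt(sum((nodes[idx(ic + 1L, jc), ] - nodes[idx(ic, jc), ])^2))
      ring_c <- sqrt(sum((nodes[idx(ic, jc + 1L), ] - nodes[idx(ic, jc), ])^2))
      r_need <- max(1.5 * r_w, r_w + 0.15)
      ki <- max(1L, ceiling(r_need / arc_c))
      kj <- max(1L, ceiling(r_need / ring_c))
      ok <- FALSE
      for (kb in 0:4) {
        ni <- 2L * ki + 1L; nj <- 2L * kj + 1L
        irange <- ((ic - ki - 1L + seq_len(ni) - 1L) %% n_theta) + 1L
        jrange <- (jc - kj):(jc + kj)
        if (min(jrange) <= n_sk + n_csf + n_gr || max(jrange) > n_rings)
          stop(sprintf("vessel %d: patch leaves the white-matter layer", vk))
        cells <- as.vector(outer(irange, (jrange - 1L) * n_theta, `+`))
        loop <- block_loop(irange, jrange, idx)
        lp <- nodes[loop, , drop = FALSE]
        # snap the lumen center to the patch centroid so the O-grid stays
        # well-shaped regardless of where the requested center falls in a cell
        ctr <- c(mean(lp[, 1]), mean(lp[, 2]))
        rl <- sqrt((lp[, 1] - ctr[1])^2 + (lp[, 2] - ctr[2])^2)
        if (min(rl) > max(1.5 * r_w, r_w + 0.15)) { ok <- TRUE; break }
        # grow only the deficient direction: outer/inner loop edges bound
        # the radial extent, side edges the angular extent
        worst <- which.min(rl)
        if (worst <= ni || (worst > ni + nj && worst <= 2L * ni + nj))
          kj <- kj + 1L else ki <- ki + 1L
      }
      if (!ok) stop(sprintf("vessel %d: cannot fit patch", vk))
      if (any(region[cells] != "WHITE"))
        stop(sprintf("vessel %d: patch overlaps a non-white region", vk))
      if (any(used[cells]))
        stop(sprintf("vessel %d: patch overlaps another vessel", vk))
      used[cells] <- TRUE
      keep[cells] <- FALSE
      patch <- vessel_patch(nodes, loop, ctr, D, minel, vk,
                            n_node0 = nrow(nodes) + Reduce(`+`, lapply(add_nodes, nrow), 0L))
      add_nodes[[length(add_nodes) + 1L]] <- patch$nodes
      add_elem[[length(add_elem) + 1L]] <- patch$elem
      add_region[[length(add_region) + 1L]] <- patch$region
      add_vid[[length(add_vid) + 1L]] <- patch$vid
      add_part[[length(add_part) + 1L]] <- patch$part
      centers[[vk]] <- ctr
    }
    mesh$vessel_centers <- do.call(rbind, centers)
    mesh$nodes <- rbind(nodes, do.call(rbind, add_nodes))
    mesh$elem <- rbind(elem[keep, , drop = FALSE], do.call(rbind, add_elem))
    mesh$region <- c(region[keep], unlist(add_region))
    mesh$vessel_id <- c(integer(sum(keep)), unlist(add_vid))
    mesh$vessel_part <- c(character(sum(keep)), unlist(add_part))
  }

  ar <- quad_areas_signed(mesh$nodes, mesh$elem)
  fl <- ar < 0
  mesh$elem[fl, ] <- mesh$elem[fl, c(4, 3, 2, 1)]
  ar <- abs(ar)
  if (any(ar <= 0)) stop("internal error: degenerate element")
  mesh$area <- ar

  # exterior boundary faces: skull outer ring, CCW -> outward normal (dy, -dx)
  i <- seq_len(n_theta)
  bf_n1 <- idx(i, 1L); bf_n2 <- idx(i + 1L, 1L)
  ex <- mesh$nodes[bf_n2, 1] - mesh$nodes[bf_n1, 1]
  ey <- mesh$nodes[bf_n2, 2] - mesh$nodes[bf_n1, 2]
  len <- sqrt(ex^2 + ey^2)
  mesh$boundary_faces <- data.frame(
    n1 = bf_n1, n2 = bf_n2, nx = ey / len, ny = -ex / len,
    cx = 0.5 * (mesh$nodes[bf_n1, 1] + mesh$nodes[bf_n2, 1]),
    cy = 0.5 * (mesh$nodes[bf_n1, 2] + mesh$nodes[bf_n2, 2]),
    length = len)
  # drop unused nodes (interiors of removed vessel blocks) and remap
  used <- sort(unique(c(as.vector(mesh$elem),
                        mesh$boundary_faces$n1, mesh$boundary_faces$n2)))
  if (length(used) < nrow(mesh$nodes)) {
    remap <- integer(nrow(mesh$nodes))
    remap[used] <- seq_along(used)
    mesh$nodes <- mesh$nodes[used, , drop = FALSE]
    mesh$elem <- matrix(remap[mesh$elem], ncol = 4)
    mesh$boundary_faces$n1 <- remap[mesh$boundary_faces$n1]
    mesh$boundary_faces$n2 <- remap[mesh$boundary_faces$n2]
  }

  mesh$params <- p
  mesh$layer_rings <- c(skull = n_sk, csf = n_csf, gray = n_gr, white = n_wh)
  mesh$region <- factor(mesh$region,
                        levels = c("SKULL", "CSF", "GRAY", "WHITE",
                                   "VENTRICLE", "VESSEL_LUMEN"))
  class(mesh) <- "phantom_mesh"
  mesh
}

# ordered CCW loop of node ids around an index block of ring cells
block_loop <- function(irange, jrange, idx) {
  ni <- length(irange); j0 <- min(jrange); j1 <- max(jrange) + 1L
  i_ext <- c(irange, irange[ni] + 1L)
  # outer edge (j0, increasing i), right edge (i max, increasing j),
  # inner edge (j1, decreasing i), left edge (i min, decreasing j)
  c(idx(i_ext[1:ni], j0),
    idx(i_ext[ni + 1L], j0:(j1 - 1L)),
    idx(rev(i_ext[2:(ni + 1L)]), j1),
    idx(i_ext[1L], rev((j0 + 1L):j1)))
}

# O-grid vessel patch inside a removed block: transition rings from the
# block boundary loop to the wall band, five wall rings (total thickness
# 10% of the diameter), lumen rings and a Coons core on the innermost
# circle. Ring node angles drift smoothly from the loop-node bearings to a
# uniform distribution so the inner rings are evenly sampled circles.
vessel_patch <- function(nodes, loop, ctr, D, minel, vid, n_node0) {
  N <- length(loop)
  stopifnot(N %% 4L == 0L)
  lp <- nodes[loop, , drop = FALSE]
  dx <- lp[, 1] - ctr[1]; dy <- lp[, 2] - ctr[2]
  Rl <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  # uniform target angles anchored to the mean bearing offset
  base <- 2 * pi * (seq_len(N) - 1L) / N
  off <- atan2(mean(sin(phi - base)), mean(cos(phi - base)))
  chi <- base + off
  dphi <- ((phi - chi + pi) %% (2 * pi)) - pi   # wrapped drift per node

  r_lum <- D / 2; r_w <- 0.6 * D
  wall_t <- 0.1 * D / minel
  # geometric transition from the loop radius down to r_w
  q <- 1.4
  n_tr <- max(2L, ceiling(log(mean(Rl) / r_w) / log(q)))
  s_tr <- (n_tr:0) / n_tr                       # 1 at loop, 0 at r_w
  # radius schedule and angle-drift weight per ring level (level 1 = loop)
  radii <- list(Rl)
  drift <- c(1)
  for (j in 2:(n_tr + 1L)) {
    radii[[j]] <- r_w * (Rl / r_w)^s_tr[j]
    drift <- c(drift, s_tr[j])
  }
  for (k in seq_len(minel)) {                   # wall band rings
    radii[[length(radii) + 1L]] <- rep(r_w - k * wall_t, N)
    drift <- c(drift, 0)
  }
  r_mid <- 0.62 * r_lum                         # lumen intermediate ring
  radii[[length(radii) + 1L]] <- rep(r_mid, N)
  drift <- c(drift, 0)
  n_levels <- length(radii)

  all_new <- list(); ids <- list()
  ids[[1]] <- loop
  n_added <- 0L
  for (j in 2:n_levels) {
    ang <- chi + drift[j] * dphi
    all_new[[j - 1L]] <- cbind(ctr[1] + radii[[j]] * cos(ang),
                               ctr[2] + radii[[j]] * sin(ang))
    ids[[j]] <- n_node0 + n_added + seq_len(N)
    n_added <- n_added + N
  }

  elem <- list(); region <- c(); vidv <- c(); part <- c()
  for (j in seq_len(n_levels - 1L)) {
    i <- seq_len(N); ip <- c(2:N, 1L)
    elem[[j]] <- cbind(ids[[j]][i], ids[[j]][ip], ids[[j + 1L]][ip], ids[[j + 1L]][i])
    lev_part <- if (j <= n_tr) "" else if (j <= n_tr + minel) "wall" else "lumen"
    region <- c(region, rep(if (lev_part == "lumen") "VESSEL_LUMEN" else "WHITE", N))
    vidv <- c(vidv, rep(if (lev_part == "") 0L else vid, N))
    part <- c(part, rep(lev_part, N))
  }
  # core: Coons patch across the innermost circle, logical corners at the
  # quarter slots of the (uniform-angle) ring
  m <- N / 4L
  in_ids <- ids[[n_levels]]
  ring_xy <- all_new[[n_levels - 1L]]
  wrap <- function(a) ((a - 1L) %% N) + 1L
  bot <- wrap(1:(m + 1L)); right <- wrap((m + 1L):(2L * m + 1L))
  top <- rev(wrap((2L * m + 1L):(3L * m + 1L))); left <- rev(wrap(c((3L * m + 1L):N, 1L)))
  g <- coons_patch(ring_xy[bot, , drop = FALSE], ring_xy[top, , drop = FALSE],
                   ring_xy[left, , drop = FALSE], ring_xy[right, , drop = FALSE])
  core_id <- matrix(0L, m + 1L, m + 1L)
  core_id[, 1L] <- in_ids[bot]; core_id[, m + 1L] <- in_ids[top]
  core_id[1L, ] <- in_ids[left]; core_id[m + 1L, ] <- in_ids[right]
  newc <- matrix(0, (m - 1L)^2, 2); k <- 0L
  for (jj in 2:m) for (ii in 2:m) {
    k <- k + 1L
    newc[k, ] <- g[ii, jj, ]
    core_id[ii, jj] <- n_node0 + n_added + k
  }
  ce <- matrix(0L, m * m, 4); k <- 0L
  for (jj in seq_len(m)) for (ii in seq_len(m)) {
    k <- k + 1L
    ce[k, ] <- c(core_id[ii, jj], core_id[ii + 1L, jj],
                 core_id[ii + 1L, jj + 1L], core_id[ii, jj + 1L])
  }
  elem[[length(elem) + 1L]] <- ce
  region <- c(region, rep("VESSEL_LUMEN", m * m))
  vidv <- c(vidv, rep(vid, m * m))
  part <- c(part, rep("lumen", m * m))
  list(nodes = rbind(do.call(rbind, all_new), newc),
       elem = do.call(rbind, elem),
       region = region, vid = vidv, part = part)
}

#' Per-region mesh statistics
#'
#' Element counts and element-size summaries per region, in the format of a
#' mesh-statistics table. Size is an element-diameter measure: the edge of
#' the equal-area square, sqrt(area).
#'
#' @param mesh a `"phantom_mesh"`.
#' @param aspect_warn warn when max element aspect ratio exceeds this
#'   (default 10).
#' @return data.frame with region, n_elements, min/max/mean size (mm).
#' @export
mesh_statistics <- function(mesh, aspect_warn = 10) {
  size <- sqrt(mesh$area)
  regs <- levels(mesh$region)
  rows <- lapply(regs, function(r) {
    sel <- mesh$region == r
    if (!any(sel)) return(NULL)
    data.frame(region = r, n_elements = sum(sel),
               min_size = min(size[sel]), max_size = max(size[sel]),
               mean_size = mean(size[sel]))
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(region = "TOTAL", n_elements = nrow(mesh$elem),
                               min_size = min(size), max_size = max(size),
                               mean_size = mean(size)))
  asp <- element_aspect(mesh)
  attr(tab, "max_aspect") <- max(asp)
  if (max(asp) > aspect_warn)
    warning(sprintf("max element aspect ratio %.1f exceeds %g", max(asp), aspect_warn))
  tab
}

# aspect ratio: longest edge / (area / longest edge)
element_aspect <- function(mesh) {
  x <- matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)
  y <- matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)
  lmax <- 0
  for (k in 1:4) {
    kp <- k %% 4 + 1
    lmax <- pmax(lmax, sqrt((x[, kp] - x[, k])^2 + (y[, kp] - y[, k])^2))
  }
  lmax / (mesh$area / lmax)
}

# characteristic element length for CFL: area / longest edge
element_char_length <- function(mesh) {
  x <- matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)
  y <- matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)
  lmax <- 0
  for (k in 1:4) {
    kp <- k %% 4 + 1
    lmax <- pmax(lmax, sqrt((x[, kp] - x[, k])^2 + (y[, kp] - y[, k])^2))
  }
  mesh$area / lmax
}

#' @export
print.phantom_mesh <- function(x, ...) {
  cat(sprintf("<phantom_mesh> %d nodes, %d quad elements\n",
              nrow(x$nodes), nrow(x$elem)))
  print(table(x$region))
  nv <- length(unique(x$vessel_id[x$vessel_id > 0]))
  if (nv > 0) cat(sprintf("  %d embedded vessels\n", nv))
  invisible(x)
}

#' @export
summary.phantom_mesh <- function(object, ...) mesh_statistics(object, ...)

#' @export
plot.phantom_mesh <- function(x, field = NULL, ...) {
  cols <- c(SKULL = "gray70", CSF = "steelblue1", GRAY = "tan3",
            WHITE = "wheat", VENTRICLE = "steelblue3", VESSEL_LUMEN = "red3")
  xm <- matrix(x$nodes[x$elem, 1], nrow(x$elem), 4)
  ym <- matrix(x$nodes[x$elem, 2], nrow(x$elem), 4)
  graphics::plot(NA, xlim = range(xm), ylim = range(ym), asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  if (is.null(field)) {
    cc <- cols[as.character(x$region)]
  } else {
    pal <- grDevices::hcl.colors(64, "viridis")
    rng <- range(field, finite = TRUE)
    cc <- pal[pmin(64, 1 + floor(63 * (field - rng[1]) / max(rng[2] - rng[1], 1e-30)))]
  }
  graphics::polygon(as.vector(rbind(t(xm), NA)), as.vector(rbind(t(ym), NA)),
                    col = rep(cc, each = 1), border = NA)
  invisible(x)
}

#' Simple structured rectangle mesh
#'
#' Axis-aligned nx-by-ny quad grid, usable anywhere a phantom mesh is
#' (single-region; handy for bar-propagation and convergence tests).
#'
#' @param nx,ny element counts.
#' @param width,height extents (mm).
#' @param region region label for all elements.
#' @param origin lower-left corner (mm).
#' @return a `"phantom_mesh"`.
#' @export
grid_mesh <- function(nx, ny, width, height, region = "WHITE",
                      origin = c(0, 0)) {
  xs <- seq(0, width, length.out = nx + 1) + origin[1]
  ys <- seq(0, height, length.out = ny + 1) + origin[2]
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  el <- matrix(0L, nx * ny, 4); k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1L
    el[k, ] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
  }
  storage.mode(el) <- "integer"
  mesh <- list(nodes = nodes, elem = el,
               region = factor(rep(region, nx * ny),
                               levels = c("SKULL", "CSF", "GRAY", "WHITE",
                                          "VENTRICLE", "VESSEL_LUMEN")),
               vessel_id = integer(nx * ny), vessel_part = character(nx * ny))
  mesh$area <- quad_areas_signed(nodes, el)
  # all four exterior sides, outward normals
  bf <- list()
  add <- function(n1, n2) {
    ex <- nodes[n2, 1] - nodes[n1, 1]; ey <- nodes[n2, 2] - nodes[n1, 2]
    len <- sqrt(ex^2 + ey^2)
    data.frame(n1 = n1, n2 = n2, nx = ey / len, ny = -ex / len,
               cx = 0.5 * (nodes[n1, 1] + nodes[n2, 1]),
               cy = 0.5 * (nodes[n1, 2] + nodes[n2, 2]), length = len)
  }
  bf[[1]] <- add(nid(seq_len(nx), 1L), nid(seq_len(nx) + 1L, 1L))             # bottom
  bf[[2]] <- add(nid(nx + 1L, seq_len(ny)), nid(nx + 1L, seq_len(ny) + 1L))   # right
  bf[[3]] <- add(nid(seq_len(nx) + 1L, ny + 1L), nid(seq_len(nx), ny + 1L))   # top
  bf[[4]] <- add(nid(1L, seq_len(ny) + 1L), nid(1L, seq_len(ny)))             # left
  mesh$boundary_faces <- do.call(rbind, bf)
  mesh$params <- NULL
  class(mesh) <- "phantom_mesh"
  mesh
}
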