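test_that("phantom regions, layer resolution, and mesh quality contracts", {
  mesh <- coarse_phantom()
  expect_setequal(as.character(unique(mesh$region)),
                  c("SKULL", "CSF", "GRAY", "WHITE", "VENTRICLE"))
  # resolution contract: >= 5 rings through skull, CSF and gray layers
  expect_true(all(mesh$layer_rings[c("skull", "csf", "gray")] >= 5))
  # independent count: CSF elements crossed along a crown-ward wedge
  cent <- cbind(rowMeans(matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)),
                rowMeans(matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)))
  ang <- atan2(cent[, 2], cent[, 1])
  n_theta <- sum(mesh$region == "SKULL") / mesh$layer_rings[["skull"]]
  wedge <- abs(ang - pi / 2) < 0.55 * (2 * pi / n_theta) & mesh$region == "CSF"
  expect_gte(length(unique(round(sqrt(rowSums(cent[wedge, , drop = FALSE]^2)), 3))), 5)
  # no inverted or degenerate elements
  expect_true(all(mesh$area > 0))
  # conformal: every edge shared by at most two elements, boundary by one
  edges <- rbind(mesh$elem[, c(1, 2)], mesh$elem[, c(2, 3)],
                 mesh$elem[, c(3, 4)], mesh$elem[, c(4, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_lte(max(table(key)), 2)
})

test_that("phantom is deterministic and mirror-symmetric", {
  m1 <- build_head_geometry(coarse_params())
  m2 <- build_head_geometry(coarse_params())
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elem, m2$elem)
  expect_identical(m1$region, m2$region)
  # left-right reflection maps the node set onto itself within 1e-9 mm
  n <- m1$nodes
  idx <- sample.int(nrow(n), 300)
  d <- vapply(idx, function(k)
    min(sqrt((n[, 1] + n[k, 1])^2 + (n[, 2] - n[k, 2])^2)), 0)
  expect_lt(max(d), 1e-9)
})

test_that("zero gyri gives a smooth convex brain boundary with no sulcal pockets", {
  mesh <- build_head_geometry(coarse_params(n_gyri_per_side = 0, sulcal_depth = 0))
  expect_equal(sum(headblast:::in_sulcus(mesh)), 0)
  # gray boundary radius varies smoothly (no dips): compare gray centroid
  # radii against the crown ellipse
  cent <- cbind(rowMeans(matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)),
                rowMeans(matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)))
  g <- mesh$region == "GRAY"
  rho <- sqrt((cent[g, 1] / 70)^2 + (cent[g, 2] / 85)^2)
  expect_lt(diff(range(rho)), 0.06)
})

test_that("the full 4-diameter x 6-position vessel array embeds 24 resolved lumens", {
  gp0 <- geometry_params(target_element_size = 1.5)
  gp <- geometry_params(target_element_size = 1.5,
                        vessel_spec = vessel_array_spec(gp0))
  mesh <- cached("mesh24", build_head_geometry(gp))
  expect_equal(length(unique(mesh$vessel_id[mesh$region == "VESSEL_LUMEN"])), 24L)
  cent <- cbind(rowMeans(matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)),
                rowMeans(matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)))
  for (v in seq_len(24)) {
    D <- gp$vessel_spec[[v]]$diameter
    wall <- mesh$vessel_id == v & mesh$region != "VESSEL_LUMEN"
    r <- sqrt((cent[wall, 1] - mesh$vessel_centers[v, 1])^2 +
                (cent[wall, 2] - mesh$vessel_centers[v, 2])^2)
    # five distinct element rings spanning the 10%-of-diameter band;
    # quad centroids on a circular arc sit inside it by the chord sagitta
    expect_equal(length(unique(round(r, 8))), 5L)
    nwall <- sum(wall) / 5
    sagitta <- (D / 2) * (1 - cos(pi / nwall))
    expect_gt(min(r), D / 2 - sagitta - 1e-9)
    expect_lt(max(r), 0.6 * D + 1e-9)
    lum <- mesh$vessel_id == v & mesh$region == "VESSEL_LUMEN"
    # lumen area equals the inscribed polygon of the circular boundary
    expect_equal(sum(mesh$area[lum]), pi * (D / 2)^2, tolerance = 0.1)
  }
  expect_true(all(mesh$area > 0))
})

test_that("mesh statistics partition the element count and flag fine wall bands", {
  mesh <- coarse_phantom()
  st <- suppressWarnings(mesh_statistics(mesh))
  tot <- st$n_elements[st$region == "TOTAL"]
  expect_equal(sum(st$n_elements[st$region != "TOTAL"]), tot)
  expect_equal(tot, nrow(mesh$elem))
  # uniform grid: all sizes equal
  g <- grid_mesh(10, 10, 10, 10)
  sg <- mesh_statistics(g)
  expect_equal(sg$n_elements[sg$region == "TOTAL"], 100L)
  expect_equal(sg$min_size, sg$max_size)
  # vascular mesh: smallest elements sit in the wall bands
  mv <- vascular_mesh()
  sv <- suppressWarnings(mesh_statistics(mv))
  size <- sqrt(mv$area)
  wall <- mv$vessel_id > 0 & mv$region != "VESSEL_LUMEN"
  expect_equal(min(size), min(size[wall]))
})

test_that("infeasible parameters are rejected naming the violated contract", {
  expect_error(build_head_geometry(geometry_params(target_element_size = 5,
                                                   sulcal_width = 2)),
               "resolution contract")
  expect_error(geometry_params(sulcal_depth = 80), "sulcal_depth")
  expect_error(geometry_params(skull_thickness = -1), "positive")
  expect_error(vessel_array_spec(geometry_params(target_element_size = 6)),
               "resolution contract")
  # vessel outside white matter
  expect_error(build_head_geometry(coarse_params(
    vessel_spec = list(list(diameter = 0.6, position = 1, center = c(0, 92))))),
    "white")
})

test_that("boundary faces cover the skull exterior with outward normals", {
  mesh <- coarse_phantom()
  bf <- mesh$boundary_faces
  # outward: normal points away from the origin
  expect_true(all(bf$nx * bf$cx + bf$ny * bf$cy > 0))
  expect_equal(sqrt(bf$nx^2 + bf$ny^2), rep(1, nrow(bf)))
  # closed loop: each boundary node appears exactly twice
  expect_true(all(table(c(bf$n1, bf$n2)) == 2))
})
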