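test_that("running maxima: translation, equibiaxial, simple shear rate", {
  mx <- matrix(0, 3, 4)
  # rigid translation: zero strain everywhere
  mx1 <- update_running_maxima(mx, matrix(0, 3, 3), matrix(0, 3, 3), 1e-6)
  expect_equal(mx1, matrix(0, 3, 4))
  # equibiaxial strain 0.01: dilatation 0.02, zero shear
  eps <- matrix(rep(c(0.01, 0.01, 0), each = 3), 3, 3)
  mx2 <- update_running_maxima(mx, eps, eps, 1)
  expect_equal(mx2[, 1], rep(0, 3))
  expect_equal(mx2[, 2], rep(0.02, 3))
  # simple shear increment gamma = 0.002 over 1 us: rate 1000 1/s
  d <- matrix(rep(c(0, 0, 0.001), each = 1), 1, 3)
  mx3 <- update_running_maxima(matrix(0, 1, 4), d, d, 1e-6)
  expect_equal(mx3[1, 3], 1000)
  # maxima are monotone under further updates
  mx4 <- update_running_maxima(mx3, d * 0.5, d * 0.1, 1e-6)
  expect_true(all(mx4 >= mx3 - 1e-15 | mx4 == mx3))
})

test_that("interface bands: precedence, emptiness, subpial coverage", {
  expect_error(classify_interface_bands(coarse_phantom(), band_width = 0),
               "band_width")
  lab <- classify_interface_bands(coarse_phantom(), band_width = 1)
  # no vessels in this mesh: no perivascular band
  expect_equal(sum(lab == "perivascular"), 0L)
  expect_gt(sum(lab == "subpial"), 0L)
  expect_gt(sum(lab == "periventricular"), 0L)
  expect_gt(sum(lab == "gray-white"), 0L)
  # non-tissue elements unlabeled
  expect_true(all(lab[as.character(coarse_phantom()$region) %in%
                        c("SKULL", "CSF", "VENTRICLE")] == ""))
  # vascular mesh: wall-band tissue is perivascular (precedence over bulk)
  labv <- classify_interface_bands(vascular_mesh(), band_width = 1)
  wall <- vascular_mesh()$vessel_id > 0 &
    vascular_mesh()$region != "VESSEL_LUMEN"
  expect_true(all(labv[wall] == "perivascular"))
})

test_that("vessel cavitation summary: zeros, exact half-lumen fraction, ordering", {
  # synthetic lumen: uniform 4 x 2 grid labeled as one vessel
  g <- grid_mesh(4, 2, 4, 2)
  g$region <- factor(rep("VESSEL_LUMEN", 8),
                     levels = levels(coarse_phantom()$region))
  g$vessel_id <- rep(1L, 8)
  g$params <- list(vessel_spec = list(list(diameter = 0.6, position = 1,
                                           center = c(2, 1))))
  none <- list(mesh = g, maxima = data.frame(
    ever_cavitated = rep(FALSE, 8), max_shear_rate = rep(0, 8)))
  s0 <- vessel_cavitation_summary(none)
  expect_equal(s0$cavitated_area_mm2, 0)
  expect_equal(s0$cavitated_fraction, 0)
  # exactly half of the (equal-area) lumen flagged -> fraction 0.5
  half <- none
  half$maxima$ever_cavitated[1:4] <- TRUE
  s1 <- vessel_cavitation_summary(half)
  expect_equal(s1$cavitated_fraction, 0.5)
  expect_equal(s1$cavitated_area_mm2, s1$lumen_area_mm2 / 2)
})

test_that("pattern report: empty field, ventricle-only fixture, permutation invariance", {
  mesh <- coarse_phantom()
  sc <- scenario_preset("front-250")
  blank <- list(mesh = mesh, config = list(scenario = sc),
                maxima = data.frame(ever_cavitated = rep(FALSE, nrow(mesh$elem))))
  r0 <- cavitation_pattern_report(blank)
  expect_false(r0$sulcal_cavitation)
  expect_false(r0$ventricular_cavitation)
  expect_equal(r0$asymmetry_index, 0)
  expect_equal(r0$total_cavitated_area, 0)
  # hand-built field: cavitation only inside the ventricles
  vent <- blank
  vent$maxima$ever_cavitated <- as.character(mesh$region) == "VENTRICLE"
  r1 <- cavitation_pattern_report(vent)
  expect_true(r1$ventricular_cavitation)
  expect_false(r1$sulcal_cavitation)
  expect_equal(r1$region_cavitated_area$VENTRICLE,
               sum(mesh$area[mesh$region == "VENTRICLE"]))
  # summaries are invariant to element ordering
  perm <- sample.int(nrow(mesh$elem))
  shuf <- vent
  shuf$mesh$elem <- mesh$elem[perm, ]
  shuf$mesh$region <- mesh$region[perm]
  shuf$mesh$area <- mesh$area[perm]
  shuf$mesh$vessel_id <- mesh$vessel_id[perm]
  shuf$maxima <- vent$maxima[perm, , drop = FALSE]
  r2 <- cavitation_pattern_report(shuf)
  expect_equal(r2$total_cavitated_area, r1$total_cavitated_area)
  expect_equal(r2$region_cavitated_area$VENTRICLE,
               r1$region_cavitated_area$VENTRICLE)
})

test_that("strain rates co-localize with cavitated CSF (canonical 250 kPa run)", {
  sim <- front_run(250)
  mesh <- sim$mesh
  cent <- cbind(rowMeans(matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)),
                rowMeans(matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)))
  cavcsf <- sim$maxima$ever_cavitated &
    as.character(mesh$region) %in% c("CSF", "VENTRICLE")
  tissue <- as.character(mesh$region) %in% c("GRAY", "WHITE")
  # tissue elements within ~1 element of cavitated CSF
  d <- rep(Inf, nrow(cent))
  cc <- cent[cavcsf, , drop = FALSE]
  ts <- which(tissue)
  for (k in ts) {
    d[k] <- min((cc[, 1] - cent[k, 1])^2 + (cc[, 2] - cent[k, 2])^2)
  }
  near <- tissue & sqrt(d) <= 2 * sqrt(stats::median(mesh$area[tissue]))
  p95_near <- stats::quantile(sim$maxima$max_shear_rate[near], 0.95)
  p95_bulk <- stats::quantile(sim$maxima$max_shear_rate[tissue & !near], 0.95)
  expect_gt(p95_near, p95_bulk)
})
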