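test_that("Friedlander waveform: peak, causality, zero crossing, impulse", {
  for (peak in c(150, 250, 500)) {
    sc <- scenario_preset(sprintf("front-%d", peak))
    w <- friedlander_waveform(sc)
    expect_equal(w(0), peak)
    expect_equal(w(c(-1, -1e-9)), c(0, 0))
    expect_equal(stats::uniroot(w, c(0.5, 1.5), tol = 1e-12)$root, 1,
                 tolerance = 1e-8)
  }
  sc <- scenario_preset("front-150")
  w <- friedlander_waveform(sc)
  imp <- stats::integrate(w, 0, 1, rel.tol = 1e-10)$value
  expect_equal(imp, 150 * exp(-1), tolerance = 1e-8)   # ~55.18 kPa ms
  # negative phase permitted, floored at -P0
  expect_lt(w(1.5), 0)
  expect_gte(min(w(seq(0, 50, by = 0.1))), -sc$P0)
})

test_that("Rankine-Hugoniot reflection: acoustic limit, direct value, monotonicity", {
  expect_equal(reflection_factor(1e-10), 2, tolerance = 1e-9)
  # 150 kPa, normal incidence: 2 dPi + (g+1) dPi^2 / ((g-1) dPi + 2 g P0)
  expected <- 2 * 150 + 2.4 * 150^2 / (0.4 * 150 + 2 * 1.4 * 101.325)
  expect_equal(150 * reflection_factor(150), expected)  # ~457.1 kPa
  f <- reflection_factor(c(10, 50, 150, 500, 1000))
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 2 - 1e-12))
  expect_equal(reflection_factor(150, incidence_cosine = 0), 1)  # grazing
  expect_error(reflection_factor(-1), "overpressure")
})

test_that("shock front speed and the sweeping arrival front", {
  sc <- scenario_preset("front-150")
  expect_equal(shock_front_speed(sc),
               340 * sqrt(1 + (2.4 / 2.8) * 150 / 101.325))  # ~512 m/s
  mesh <- grid_mesh(10, 2, 100, 10)
  sc2 <- blast_scenario(150, direction = c(1, 0))
  arr <- arrival_times(mesh, sc2)
  expect_equal(min(arr$t_arrival), 0)
  # two faces 10 mm apart along the direction: dt = 10 / U
  bot <- arr[mesh$boundary_faces$ny < -0.5, ][1:10, ]
  expect_equal(diff(bot$t_arrival), rep(10 / shock_front_speed(sc2), 9))
})

test_that("boundary tractions: causality, reflected peak, grazing, symmetry", {
  mesh <- grid_mesh(4, 4, 40, 40, origin = c(-20, -20))
  sc <- blast_scenario(150, direction = c(0, -1))
  arr <- arrival_times(mesh, sc)
  expect_equal(boundary_traction(mesh, sc, t = -0.01, arr),
               rep(0, nrow(mesh$boundary_faces)))
  # face with normal anti-parallel to the direction at its arrival instant
  top <- which(mesh$boundary_faces$ny > 0.5)
  tr <- boundary_traction(mesh, sc, t = 1e-12, arr)
  expect_equal(max(tr[top]), 150 * reflection_factor(150),
               tolerance = 1e-6)
  # grazing faces receive side-on incident pressure
  side <- which(abs(mesh$boundary_faces$nx) > 0.5)
  t_side <- arr$t_arrival[arr$face == side[1] & arr$front == "direct"]
  expect_equal(boundary_traction(mesh, sc, t_side + 1e-12, arr)[side[1]],
               friedlander_waveform(sc)(1e-12), tolerance = 1e-6)
  # mirror symmetry in x for a front blast
  bf <- mesh$boundary_faces
  tmid <- 0.05
  trm <- boundary_traction(mesh, sc, tmid, arr)
  for (f in seq_len(nrow(bf))) {
    match <- which(abs(bf$cx + bf$cx[f]) < 1e-9 & abs(bf$cy - bf$cy[f]) < 1e-9)
    expect_equal(trm[f], trm[match[1]], tolerance = 1e-12)
  }
})

test_that("wall reflector: image front exists, arrives later, vanishes at infinity", {
  mesh <- coarse_phantom()
  sc <- blast_scenario(250, direction = c(0, -1),
                       wall = list(distance = 6.3, angle = 26.5, side = "left"))
  arr <- arrival_times(mesh, sc)
  expect_setequal(unique(arr$front), c("direct", "image"))
  nf <- nrow(mesh$boundary_faces)
  expect_equal(nrow(arr), 2L * nf)
  dir <- arr[arr$front == "direct", ]; img <- arr[arr$front == "image", ]
  img <- img[order(img$face), ]; dir <- dir[order(dir$face), ]
  # image front is strictly later on the wall-facing (left) side
  left <- mesh$boundary_faces$nx < -0.5
  expect_true(all(img$t_arrival[left] > dir$t_arrival[left]))
  # image carries the wall-reflected amplitude
  expect_gt(img$peak[1], sc$peak_overpressure)
  # wall at infinity: tractions match the pure front scenario
  sc_inf <- blast_scenario(250, direction = c(0, -1),
                           wall = list(distance = 1e7))
  sc_front <- blast_scenario(250, direction = c(0, -1))
  expect_equal(boundary_traction(mesh, sc_inf, 0.4),
               boundary_traction(mesh, sc_front, 0.4))
})

test_that("scenario presets and waveform dump", {
  sc <- scenario_preset("side-500")
  expect_equal(sc$peak_overpressure, 500)
  expect_equal(sc$direction, c(1, 0))
  expect_error(scenario_preset("front-999"), "preset")
  f <- tempfile(fileext = ".csv")
  df <- dump_waveform(scenario_preset("front-150"), f)
  back <- utils::read.csv(f)
  expect_equal(back$overpressure_kPa, df$overpressure_kPa)
  expect_equal(back$overpressure_kPa[1], 150)
})
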