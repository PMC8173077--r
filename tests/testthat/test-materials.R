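test_that("step shear realizes the short-term modulus and the closed-form relaxation curve", {
  mats <- material_library()
  for (reg in c("WHITE", "GRAY")) {
    m <- mats[[reg]]
    rel <- relaxation_test(m, gamma = 0.01, dt = 1e-6, t_end = 5e-6)
    expect_equal(rel$stress[1] / 0.01, m$G0, tolerance = 1e-4)
  }
  # held step relaxes exactly on G(t) = Ginf + (G0-Ginf) exp(-beta t)
  # (the exponential integrator places the step at the half-step)
  m <- mats$WHITE
  rel <- relaxation_test(m, gamma = 0.01, dt = 1e-4, t_end = 0.1)
  expected <- 0.01 * (m$Ginf + (m$G0 - m$Ginf) * exp(-m$beta * (rel$time - 0.5e-4)))
  expect_equal(rel$stress, expected, tolerance = 1e-10)
})

test_that("least-squares recovery of the Prony parameters is within 1%", {
  m <- material_library()$WHITE
  rel <- relaxation_test(m, gamma = 0.01, dt = 1e-4, t_end = 0.15)
  p <- recover_prony(rel$time, rel$stress, gamma = 0.01)
  expect_lt(abs(p["G0"] - m$G0) / m$G0, 0.01)
  expect_lt(abs(p["Ginf"] - m$Ginf) / m$Ginf, 0.01)
  expect_lt(abs(p["beta"] - m$beta) / m$beta, 0.01)
})

test_that("equal short- and long-term moduli give a time-independent response", {
  m <- hb_material("tissue", rho0 = 1040, A = 2.18e9, B = 13.25e9,
                   P_cav = -3e5, G0 = 10e3, Ginf = 10e3, beta = 40)
  rel <- relaxation_test(m, gamma = 0.01, dt = 1e-4, t_end = 0.05)
  expect_equal(rel$stress, rep(rel$stress[1], nrow(rel)), tolerance = 1e-12)
  up <- viscoelastic_deviatoric_update(c(xx = 0, yy = 0, zz = 0, xy = 0.005),
                                       dt = 1e-4, m)
  expect_equal(unname(up$state$h), c(0, 0, 0, 0))
})

test_that("EOS pressure, cavitation clamp, rebound, and history independence", {
  mats <- material_library()
  expect_equal(eos_pressure(0.01, mats$WHITE)$pressure, 23125e3)
  expect_equal(eos_pressure(0, mats$WHITE)$pressure, 0)
  expect_error(eos_pressure(-1.0001, mats$WHITE), "non-physical")

  # stretch so the trial pressure would be -500 kPa: clamped at -200 (CSF)
  mu_500 <- -500e3 / mats$CSF$A
  v <- volumetric_test(mats$CSF, c(0, mu_500, 0, -0.5e-4))
  expect_equal(v$pressure[2], -200e3)
  expect_true(v$cavitating_now[2] && v$ever_cavitated[2])
  # rebound clears the instantaneous flag, history is monotone
  expect_false(v$cavitating_now[3])
  expect_true(v$ever_cavitated[3])
  # post-rebound response identical to never-cavitated material
  fresh <- eos_pressure(-0.5e-4, mats$CSF)$pressure
  expect_identical(v$pressure[4], fresh)
})

test_that("elastic increments reproduce the constrained and bulk moduli", {
  sk <- material_library()$SKULL
  M <- sk$E * (1 - sk$nu) / ((1 + sk$nu) * (1 - 2 * sk$nu))
  d <- elastic_stress_update(c(xx = 1e-3, yy = 0, xy = 0), sk)
  expect_equal(unname(d["xx"]), M * 1e-3)
  expect_equal(unname(elastic_stress_update(c(xx = 0, yy = 0, xy = 0), sk)),
               c(0, 0, 0, 0))
  K <- sk$E / (3 * (1 - 2 * sk$nu))
  dh <- elastic_stress_update(c(xx = 1e-3, yy = 1e-3, xy = 0), sk)
  # plane strain hydrostatic in-plane increment: mean 3D stress = K tr
  expect_equal((dh[["xx"]] + dh[["yy"]] + dh[["zz"]]) / 3, K * 2e-3)
})

test_that("sound speeds follow the closed forms and density scaling", {
  mats <- material_library()
  expect_equal(sound_speed(mats$SKULL), sqrt(2000e6 * 0.6 / (1.4 * 0.2) / 1210))
  expect_equal(sound_speed(mats$CSF), sqrt(2.18e9 / 1040))
  heavy <- mats$CSF; heavy$rho0 <- 2 * 1040
  expect_equal(sound_speed(mats$CSF) / sound_speed(heavy), sqrt(2))
})

test_that("material presets carry the study parameter variations", {
  soft <- material_library("softened")
  norm <- material_library("normal")
  expect_equal(soft$WHITE$G0, norm$WHITE$G0 / 10)
  expect_equal(soft$GRAY$Ginf, norm$GRAY$Ginf / 10)
  expect_equal(soft$WHITE$A, norm$WHITE$A)  # EOS untouched
  sk8 <- material_library("skull-8GPa")
  expect_equal(sk8$SKULL$E, 8e9)
  expect_equal(sk8$SKULL$nu, 0.22)
  # CSF, ventricle and vessel content share the fluid model
  expect_identical(norm$CSF, norm$VENTRICLE)
  expect_identical(norm$CSF, norm$VESSEL_LUMEN)
  expect_equal(norm$CSF$G0, 0)
})
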