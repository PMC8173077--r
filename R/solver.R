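#' Lumped nodal masses
#'
#' Row-sum lumping of the consistent mass matrix: each node receives
#' \eqn{\int \rho N_i \, dA} over its attached elements (2x2 Gauss).
#' Masses are per unit out-of-plane thickness (kg/m).
#'
#' @param mesh a `"phantom_mesh"`.
#' @param materials a [material_library()] set.
#' @return numeric vector of nodal masses (kg/m).
#' @export
lumped_mass <- function(mesh, materials) {
  X <- mesh$nodes / 1000
  el <- mesh$elem
  rho <- vapply(as.character(mesh$region), function(r) materials[[r]]$rho0, 0)
  gp <- 1 / sqrt(3)
  gxy <- cbind(c(-gp, gp, gp, -gp), c(-gp, -gp, gp, gp))
  xm <- matrix(X[el, 1], nrow(el), 4)
  ym <- matrix(X[el, 2], nrow(el), 4)
  mass <- numeric(nrow(X))
  contrib <- matrix(0, nrow(el), 4)
  for (g in 1:4) {
    xi <- gxy[g, 1]; et <- gxy[g, 2]
    dNxi <- c(-(1 - et), (1 - et), (1 + et), -(1 + et)) / 4
    dNet <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    N <- c((1 - xi) * (1 - et), (1 + xi) * (1 - et),
           (1 + xi) * (1 + et), (1 - xi) * (1 + et)) / 4
    j11 <- xm %*% dNxi; j12 <- ym %*% dNxi
    j21 <- xm %*% dNet; j22 <- ym %*% dNet
    det <- as.numeric(j11 * j22 - j12 * j21)
    for (a in 1:4) contrib[, a] <- contrib[, a] + rho * N[a] * det
  }
  for (a in 1:4) {
    s <- rowsum(contrib[, a], el[, a])
    mass[as.integer(rownames(s))] <- mass[as.integer(rownames(s))] + s[, 1]
  }
  if (any(mass[sort(unique(as.vector(el)))] <= 0)) stop("zero-mass node")
  mass
}

#' CFL-stable time step
#'
#' \eqn{\Delta t = f_{CFL} \min_e (\ell_e / c_e)} with the characteristic
#' length area/longest-edge and the material sound speed.
#'
#' @param mesh a `"phantom_mesh"`.
#' @param materials a [material_library()] set.
#' @param cfl_factor safety factor in (0, 1], default 0.5.
#' @return time step (s).
#' @export
stable_timestep <- function(mesh, materials, cfl_factor = 0.5) {
  stopifnot(cfl_factor > 0, cfl_factor <= 1)
  cs <- vapply(as.character(mesh$region), function(r) sound_speed(materials[[r]]), 0)
  h <- element_char_length(mesh) / 1000
  cfl_factor * min(h / cs)
}

# assemble per-element material parameter table for the kernel
material_arrays <- function(mesh, materials) {
  regs <- as.character(mesh$region)
  typ <- integer(length(regs))
  mp <- matrix(0, length(regs), 10)
  colnames(mp) <- c("rho0", "A", "B", "Pcav", "G0", "Ginf", "beta",
                    "lam", "mue", "csnd")
  for (r in unique(regs)) {
    m <- materials[[r]]
    sel <- regs == r
    if (m$type == "elastic") {
      typ[sel] <- 0L
      mp[sel, "lam"] <- m$E * m$nu / ((1 + m$nu) * (1 - 2 * m$nu))
      mp[sel, "mue"] <- m$E / (2 * (1 + m$nu))
    } else if (m$type == "tissue") {
      typ[sel] <- 1L
      mp[sel, c("A", "B", "Pcav")] <- rep(c(m$A, m$B, m$P_cav), each = sum(sel))
      mp[sel, c("G0", "Ginf", "beta")] <- rep(c(m$G0, m$Ginf, m$beta), each = sum(sel))
    } else {
      typ[sel] <- 2L
      mp[sel, c("A", "B", "Pcav")] <- rep(c(m$A, m$B, m$P_cav), each = sum(sel))
      mp[sel, "beta"] <- 1
    }
    mp[sel, "rho0"] <- m$rho0
    mp[sel, "csnd"] <- sound_speed(m)
  }
  list(type = typ, pars = mp)
}

#' Initial field state
#'
#' Zero-displacement, zero-velocity state holding nodal kinematics, lumped
#' masses, per-Gauss-point material state, per-element pressure, cavitation
#' flags and running maxima, all in SI units.
#'
#' @param mesh a `"phantom_mesh"`.
#' @param materials a [material_library()] set.
#' @param fixed optional n x 2 logical matrix of constrained dofs.
#' @return an environment of class `"field_state"` (mutated in place by the
#'   solver kernel).
#' @export
field_state <- function(mesh, materials, fixed = NULL) {
  ne <- nrow(mesh$elem)
  nn <- nrow(mesh$nodes)
  ma <- material_arrays(mesh, materials)
  st <- new.env(parent = emptyenv())
  st$X <- mesh$nodes / 1000
  st$V <- matrix(0, nn, 2)
  st$mass <- lumped_mass(mesh, materials)
  st$fixed <- if (is.null(fixed)) matrix(0L, nn, 2) else (fixed) * 1L
  storage.mode(st$fixed) <- "integer"
  st$conn <- mesh$elem - 1L
  storage.mode(st$conn) <- "integer"
  st$mtype <- ma$type
  st$mpar <- ma$pars
  # reference areas via the kernel's own quadrature so an undeformed mesh
  # is exactly stress-free
  st$A0 <- cpp_areas(st$X, st$conn)
  st$h_gp <- matrix(0, ne, 12)
  st$e_gp <- matrix(0, ne, 12)
  st$sig_gp <- matrix(0, ne, 16)
  st$eps_acc <- matrix(0, ne, 3)
  st$maxima <- matrix(0, ne, 4)
  st$Pel <- numeric(ne)
  st$cavNow <- integer(ne)
  st$everCav <- integer(ne)
  st$maxP <- numeric(ne)
  st$minP <- numeric(ne)
  # freshly allocated (not a compiler constant): the kernel updates it in place
  st$energy <- stats::setNames(numeric(3), c("wext", "wint", "wvisc"))
  st$t <- 0
  st$kinetic <- 0
  st$mesh <- mesh
  class(st) <- "field_state"
  st
}

# kernel front tables from a scenario (SI units)
front_tables <- function(mesh, scenario) {
  arr <- arrival_times(mesh, scenario)
  fronts <- unique(arr$front)
  nf <- nrow(mesh$boundary_faces)
  arrM <- matrix(0, nf, length(fronts))
  cosM <- matrix(0, nf, length(fronts))
  peaks <- numeric(length(fronts))
  for (k in seq_along(fronts)) {
    a <- arr[arr$front == fronts[k], ]
    a <- a[order(a$face), ]
    arrM[, k] <- a$t_arrival / 1000          # ms -> s
    cosM[, k] <- a$cos_inc
    peaks[k] <- a$peak[1] * 1000             # kPa -> Pa
  }
  list(arrM = arrM, cosM = cosM, peaks = peaks,
       td = scenario$duration / 1000, b = scenario$decay,
       P0 = scenario$P0 * 1000, gamma = scenario$gamma_air,
       floorP = scenario$negative_floor * 1000,
       bfn = as.matrix(mesh$boundary_faces[, c("n1", "n2")]) - 1L)
}

kernel_call <- function(st, ft, dt, nsteps, bulk_viscosity, forces_only = FALSE) {
  bfn <- ft$bfn; storage.mode(bfn) <- "integer"
  cpp_advance(st$X, st$V, st$mass, st$fixed, st$conn, st$mtype, st$mpar,
              st$A0, st$h_gp, st$e_gp, st$sig_gp, st$eps_acc, st$maxima,
              st$Pel, st$cavNow, st$everCav, st$maxP, st$minP,
              bfn, ft$arrM, ft$cosM, ft$peaks,
              ft$td, ft$b, ft$P0, ft$gamma, ft$floorP,
              st$t, dt, as.integer(nsteps),
              bulk_viscosity[["linear"]], bulk_viscosity[["quadratic"]],
              st$energy, forces_only)
}

#' Internal nodal forces
#'
#' Assembles internal (and boundary, at the state's current time) nodal
#' forces from the current field state without advancing it: plane-strain
#' quads with mean-dilatation volumetric treatment, deviatoric terms from
#' the material models, artificial bulk viscosity in compression.
#'
#' @param state a [field_state()].
#' @param scenario optional [blast_scenario()]; omit for internal forces
#'   only (zero external load).
#' @param bulk_viscosity linear/quadratic coefficients.
#' @return n x 2 matrix of nodal forces (N per meter thickness).
#' @export
internal_forces <- function(state, scenario = NULL,
                            bulk_viscosity = c(linear = 0.06, quadratic = 1.5)) {
  ft <- if (is.null(scenario)) {
    nf <- nrow(state$mesh$boundary_faces)
    list(arrM = matrix(0, nf, 1), cosM = matrix(0, nf, 1), peaks = 0,
         td = 1, b = 1, P0 = 101325, gamma = 1.4, floorP = 0,
         bfn = as.matrix(state$mesh$boundary_faces[, c("n1", "n2")]) - 1L)
  } else front_tables(state$mesh, scenario)
  res <- kernel_call(state, ft, dt = 1e-9, nsteps = 0L, bulk_viscosity,
                     forces_only = TRUE)
  if (res$status != 0) stop("force assembly failed (inverted element?)")
  res$forces
}

#' Advance a field state
#'
#' Central-difference explicit steps: half-step velocity update from the
#' assembled forces, coordinate update, strain increments from velocity
#' gradients, material state update, running maxima and energy ledger.
#'
#' @param state a [field_state()], mutated in place.
#' @param dt time step (s), at most the CFL-stable step.
#' @param nsteps number of steps.
#' @param scenario optional [blast_scenario()] providing boundary loading.
#' @param bulk_viscosity linear/quadratic artificial viscosity coefficients.
#' @return the state, invisibly; aborts on NaN/inverted elements.
#' @export
advance <- function(state, dt, nsteps = 1L, scenario = NULL,
                    bulk_viscosity = c(linear = 0.06, quadratic = 1.5)) {
  ft <- if (is.null(scenario)) {
    nf <- nrow(state$mesh$boundary_faces)
    list(arrM = matrix(1e30, nf, 1), cosM = matrix(0, nf, 1), peaks = 0,
         td = 1, b = 1, P0 = 101325, gamma = 1.4, floorP = 0,
         bfn = as.matrix(state$mesh$boundary_faces[, c("n1", "n2")]) - 1L)
  } else front_tables(state$mesh, scenario)
  res <- kernel_call(state, ft, dt, nsteps, bulk_viscosity)
  if (res$status == 2)
    stop(sprintf("inverted element %d at t = %.4g ms", res$bad_element,
                 res$t * 1000))
  if (res$status != 0)
    stop(sprintf("numerical abort (NaN/non-physical state) at t = %.4g ms",
                 res$t * 1000))
  state$t <- res$t
  state$kinetic <- res$kinetic
  invisible(state)
}

#' Simulation configuration
#'
#' @param scenario a [blast_scenario()] or preset name.
#' @param geometry a [geometry_params()] or a prebuilt `"phantom_mesh"`.
#' @param materials a [material_library()] set or preset name.
#' @param end_time simulated time (ms); 6 ms is the non-vascular study
#'   duration, 2.5 ms the vascular one.
#' @param cfl_factor CFL safety factor (default 0.5).
#' @param bulk_viscosity linear/quadratic artificial viscosity coefficients
#'   (defaults 0.06, 1.5 - standard shock-physics values).
#' @param output_interval snapshot interval (ms).
#' @param probes optional list/matrix of probe positions (mm).
#' @param seed integer seed (forwarded to the geometry jitter; the solver
#'   itself is deterministic).
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(scenario = scenario_preset("front-250"),
                              geometry = geometry_params(),
                              materials = material_library("normal"),
                              end_time = 6, cfl_factor = 0.5,
                              bulk_viscosity = c(linear = 0.06, quadratic = 1.5),
                              output_interval = 0.5, probes = NULL,
                              seed = 1L) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  if (is.character(materials)) materials <- material_library(materials)
  stopifnot(end_time > 0, cfl_factor > 0, cfl_factor <= 1)
  structure(list(scenario = scenario, geometry = geometry,
                 materials = materials, end_time = end_time,
                 cfl_factor = cfl_factor, bulk_viscosity = bulk_viscosity,
                 output_interval = output_interval, probes = probes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Run a blast simulation
#'
#' Builds (or reuses) the phantom mesh, sweeps the blast front over the
#' skull exterior and advances the explicit solver to the configured end
#' time, storing field snapshots at the output interval and the final
#' element-wise running maxima. Deterministic given the configuration.
#'
#' @param config a [simulation_config()].
#' @param verbose print progress lines.
#' @return object of class `"blast_sim"`: mesh, config, `dt` (s),
#'   `snapshots` (list of time (ms), pressure (kPa), cavitating flags),
#'   `maxima` data.frame (max |shear strain|, max |dilatational strain|,
#'   their rates (1/s), ever_cavitated, max/min pressure kPa), `energy`
#'   ledger data.frame, and the final `"field_state"`.
#' @export
run_simulation <- function(config, verbose = FALSE) {
  mesh <- if (inherits(config$geometry, "phantom_mesh")) config$geometry
          else build_head_geometry(config$geometry)
  materials <- config$materials
  st <- field_state(mesh, materials)
  ft <- front_tables(mesh, config$scenario)
  dt <- stable_timestep(mesh, materials, config$cfl_factor)
  t_end <- config$end_time / 1000
  n_out <- max(1L, ceiling(config$end_time / config$output_interval))
  snap_t <- seq_len(n_out) * t_end / n_out
  probe_el <- NULL
  if (!is.null(config$probes)) {
    pm <- matrix(unlist(config$probes), ncol = 2, byrow = !is.matrix(config$probes))
    if (is.matrix(config$probes)) pm <- config$probes
    cx <- rowMeans(matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4))
    cy <- rowMeans(matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4))
    probe_el <- apply(pm, 1, function(p) which.min((cx - p[1])^2 + (cy - p[2])^2))
  }
  snapshots <- vector("list", n_out)
  energy <- data.frame()
  probe_rows <- list()
  t_prev <- 0
  for (k in seq_len(n_out)) {
    nsub <- max(1L, ceiling((snap_t[k] - st$t) / dt - 1e-9))
    res <- kernel_call(st, ft, dt, nsub, config$bulk_viscosity)
    if (res$status == 2)
      stop(sprintf("inverted element %d at t = %.4g ms", res$bad_element, res$t * 1000))
    if (res$status != 0)
      stop(sprintf("numerical abort at t = %.4g ms", res$t * 1000))
    st$t <- res$t
    st$kinetic <- res$kinetic
    snapshots[[k]] <- list(time = st$t * 1000,
                           pressure = st$Pel / 1000,
                           cavitating = st$cavNow == 1L)
    bal <- st$energy[["wext"]] -
      (res$kinetic + st$energy[["wint"]] + st$energy[["wvisc"]])
    energy <- rbind(energy, data.frame(
      time = st$t * 1000, w_ext = st$energy[["wext"]], kinetic = res$kinetic,
      w_int = st$energy[["wint"]], w_visc = st$energy[["wvisc"]],
      imbalance = bal,
      momentum_x = sum(st$mass * st$V[, 1]),
      momentum_y = sum(st$mass * st$V[, 2])))
    if (!is.null(probe_el))
      probe_rows[[k]] <- data.frame(time = st$t * 1000,
                                    probe = seq_along(probe_el),
                                    pressure = st$Pel[probe_el] / 1000)
    if (verbose)
      message(sprintf("t = %.3f ms (%d/%d), cavitating %d, dt = %.3g us",
                      st$t * 1000, k, n_out, sum(st$cavNow), dt * 1e6))
  }
  maxima <- data.frame(
    max_shear_strain = st$maxima[, 1],
    max_dil_strain = st$maxima[, 2],
    max_shear_rate = st$maxima[, 3],
    max_dil_rate = st$maxima[, 4],
    ever_cavitated = st$everCav == 1L,
    max_pressure = st$maxP / 1000,
    min_pressure = st$minP / 1000)
  structure(list(mesh = mesh, config = config, dt = dt,
                 snapshots = snapshots, maxima = maxima, energy = energy,
                 probes = if (length(probe_rows)) do.call(rbind, probe_rows),
                 probe_elements = probe_el,
                 state = st, n_steps = round(st$t / dt)),
            class = "blast_sim")
}

#' @export
print.blast_sim <- function(x, ...) {
  cat(sprintf("<blast_sim> %g kPa blast, %d elements, t = %.3g ms (%d steps, dt %.3g us)\n",
              x$config$scenario$peak_overpressure, nrow(x$mesh$elem),
              x$state$t * 1000, x$n_steps, x$dt * 1e6))
  cat(sprintf("  cavitated elements: %d (%.2f mm^2)\n",
              sum(x$maxima$ever_cavitated),
              sum(x$mesh$area[x$maxima$ever_cavitated])))
  e <- x$energy[nrow(x$energy), ]
  cat(sprintf("  energy: W_ext %.4g J/m, KE %.4g, W_int %.4g, W_visc %.4g (imbalance %.2g%%)\n",
              e$w_ext, e$kinetic, e$w_int, e$w_visc,
              100 * abs(e$imbalance) / max(abs(e$w_ext), 1e-30)))
  invisible(x)
}

#' @export
summary.blast_sim <- function(object, ...) {
  m <- object$maxima
  reg <- object$mesh$region
  out <- do.call(rbind, lapply(levels(reg), function(r) {
    sel <- reg == r
    if (!any(sel)) return(NULL)
    data.frame(region = r,
               cavitated_area_mm2 = sum(object$mesh$area[sel & m$ever_cavitated]),
               p95_shear_strain = stats::quantile(m$max_shear_strain[sel], 0.95),
               p95_shear_rate = stats::quantile(m$max_shear_rate[sel], 0.95),
               max_pressure_kPa = max(m$max_pressure[sel]),
               min_pressure_kPa = min(m$min_pressure[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.blast_sim <- function(x, what = c("cavitation", "shear_strain",
                                       "shear_rate", "pressure"), ...) {
  what <- match.arg(what)
  f <- switch(what,
              cavitation = as.numeric(x$maxima$ever_cavitated),
              shear_strain = x$maxima$max_shear_strain,
              shear_rate = x$maxima$max_shear_rate,
              pressure = x$maxima$max_pressure)
  plot(x$mesh, field = f, main = what, ...)
}
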