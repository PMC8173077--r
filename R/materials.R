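#' Constitutive models for the head phantom
#'
#' The phantom uses three constitutive classes, one per tissue type:
#' \describe{
#'   \item{elastic}{linear (corotational hypoelastic) solid for the skull,
#'     parameterized by Young's modulus and Poisson's ratio;}
#'   \item{tissue}{gray/white matter: Tillotson-Brundage volumetric response
#'     \eqn{P = A\mu + B\mu^2} (linear in tension) with a pressure-cutoff
#'     cavitation floor, plus a single-term Prony viscoelastic deviatoric
#'     response \eqn{G(t) = G_\infty + (G_0 - G_\infty)e^{-\beta t}};}
#'   \item{fluid}{CSF and blood: same volumetric equation of state and
#'     cavitation floor, zero deviatoric strength.}
#' }
#' All quantities are SI internally: Pa, kg/m^3, s. Pressure is gauge, with
#' compression positive; cavitation thresholds are negative (tension).
#'
#' @param type one of `"elastic"`, `"tissue"`, `"fluid"`.
#' @param rho0 reference density (kg/m^3).
#' @param E,nu Young's modulus (Pa) and Poisson ratio (elastic only).
#' @param A,B bulk and quadratic equation-of-state stiffness (Pa).
#' @param P_cav cavitation threshold, gauge pressure (Pa, negative).
#' @param G0,Ginf short- and long-term shear moduli (Pa).
#' @param beta shear relaxation decay constant (1/s).
#' @param name material label.
#' @return an object of class `"hb_material"`.
#' @export
hb_material <- function(type = c("elastic", "tissue", "fluid"), rho0,
                        E = NULL, nu = NULL,
                        A = NULL, B = NULL, P_cav = NULL,
                        G0 = NULL, Ginf = NULL, beta = NULL,
                        name = type) {
  type <- match.arg(type)
  stopifnot(rho0 > 0)
  m <- list(type = type, rho0 = rho0, name = name)
  if (type == "elastic") {
    stopifnot(E > 0, nu > 0, nu < 0.5)
    m$E <- E; m$nu <- nu
  } else {
    stopifnot(A > 0, B >= 0, P_cav < 0)
    m$A <- A; m$B <- B; m$P_cav <- P_cav
    if (type == "tissue") {
      stopifnot(G0 >= Ginf, Ginf > 0, beta > 0)
      m$G0 <- G0; m$Ginf <- Ginf; m$beta <- beta
    } else {
      m$G0 <- 0; m$Ginf <- 0; m$beta <- 1  # strengthless
    }
  }
  class(m) <- "hb_material"
  m
}

#' @export
print.hb_material <- function(x, ...) {
  cat(sprintf("<hb_material> %s (%s), rho0 = %g kg/m^3\n", x$name, x$type, x$rho0))
  if (x$type == "elastic") {
    cat(sprintf("  E = %g MPa, nu = %g\n", x$E / 1e6, x$nu))
  } else {
    cat(sprintf("  A = %g kPa, B = %g kPa, P_cav = %g kPa\n",
                x$A / 1e3, x$B / 1e3, x$P_cav / 1e3))
    if (x$type == "tissue")
      cat(sprintf("  G0 = %g kPa, Ginf = %g kPa, beta = %g 1/s\n",
                  x$G0 / 1e3, x$Ginf / 1e3, x$beta))
  }
  invisible(x)
}

#' Material library for the head phantom
#'
#' Returns the per-region material set. The default ("normal") parameter set
#' is: elastic skull (density 1210 kg/m^3, E = 2000 MPa, nu = 0.40);
#' gray/white matter with Tillotson-Brundage A = 2.18e6 kPa, B = 13.25e6 kPa,
#' cavitation threshold -300 kPa and Prony shear (white: G0 = 33.2 kPa,
#' Ginf = 7.8 kPa; gray: G0 = 27.6 kPa, Ginf = 6.4 kPa; beta = 40 1/s);
#' CSF/blood as a strengthless fluid with the same equation of state and a
#' -200 kPa threshold. Ventricular fluid and vessel lumen content share the
#' CSF model (CSF and blood are treated as mechanically indistinguishable).
#'
#' Presets:
#' \describe{
#'   \item{"normal"}{the defaults above;}
#'   \item{"softened"}{brain shear moduli (G0, Ginf) divided by 10;}
#'   \item{"skull-8GPa"}{skull E = 8.0 GPa, nu = 0.22, all else as normal.}
#' }
#'
#' @param preset `"normal"`, `"softened"` or `"skull-8GPa"`.
#' @return named list of [hb_material] objects, class `"material_set"`, with
#'   one entry per mesh region label.
#' @export
material_library <- function(preset = c("normal", "softened", "skull-8GPa")) {
  preset <- match.arg(preset)
  kPa <- 1e3
  shear_div <- if (preset == "softened") 10 else 1
  skull <- if (preset == "skull-8GPa") {
    hb_material("elastic", rho0 = 1210, E = 8.0e9, nu = 0.22, name = "skull")
  } else {
    hb_material("elastic", rho0 = 1210, E = 2000e6, nu = 0.40, name = "skull")
  }
  white <- hb_material("tissue", rho0 = 1040,
                       A = 2.18e6 * kPa, B = 13.25e6 * kPa, P_cav = -300 * kPa,
                       G0 = 33.2 * kPa / shear_div, Ginf = 7.8 * kPa / shear_div,
                       beta = 40, name = "white")
  gray <- hb_material("tissue", rho0 = 1040,
                      A = 2.18e6 * kPa, B = 13.25e6 * kPa, P_cav = -300 * kPa,
                      G0 = 27.6 * kPa / shear_div, Ginf = 6.4 * kPa / shear_div,
                      beta = 40, name = "gray")
  csf <- hb_material("fluid", rho0 = 1040,
                     A = 2.18e6 * kPa, B = 13.25e6 * kPa, P_cav = -200 * kPa,
                     name = "csf")
  out <- list(SKULL = skull, GRAY = gray, WHITE = white, CSF = csf,
              VENTRICLE = csf, VESSEL_LUMEN = csf)
  attr(out, "preset") <- preset
  class(out) <- "material_set"
  out
}

#' @export
print.material_set <- function(x, ...) {
  cat(sprintf("<material_set> preset '%s'\n", attr(x, "preset")))
  for (r in names(x)) cat(sprintf("  %-12s -> %s (%s)\n", r, x[[r]]$name, x[[r]]$type))
  invisible(x)
}

#' Fresh equation-of-state / cavitation state
#'
#' @param n number of elements.
#' @return list with logical vectors `cavitating_now`, `ever_cavitated`.
#' @export
material_state <- function(n = 1L) {
  list(cavitating_now = rep(FALSE, n), ever_cavitated = rep(FALSE, n))
}

#' Tillotson-Brundage pressure with cavitation clamp
#'
#' Computes the volumetric (gauge) pressure from compression
#' \eqn{\mu = \rho/\rho_0 - 1}: trial pressure \eqn{A\mu + B\mu^2} in
#' compression (\eqn{\mu \ge 0}) and \eqn{A\mu} in tension, clamped from
#' below at the cavitation threshold `P_cav`. When the clamp engages the
#' element is flagged as cavitating (and permanently as ever-cavitated);
#' cavitation rebound clears the instantaneous flag as soon as the trial
#' pressure recovers above the threshold. Cavitation history does not alter
#' the constitutive response.
#'
#' @param mu compression (dimensionless), vectorized; must exceed -1.
#' @param params an `"hb_material"` with an equation of state, or a list with
#'   fields `A`, `B`, `P_cav`.
#' @param state optional state from [material_state()]; defaults to fresh.
#' @return list with `pressure` (same units as `A`) and updated `state`.
#' @export
eos_pressure <- function(mu, params, state = material_state(length(mu))) {
  if (any(mu <= -1)) stop("non-physical density: mu <= -1")
  p_trial <- ifelse(mu >= 0, params$A * mu + params$B * mu^2, params$A * mu)
  cav <- p_trial < params$P_cav
  list(pressure = ifelse(cav, params$P_cav, p_trial),
       state = list(cavitating_now = cav,
                    ever_cavitated = state$ever_cavitated | cav))
}

#' Prony viscoelastic state
#'
#' @param zero named tensor template.
#' @return list with internal variable `h` and accumulated deviatoric strain `e`.
#' @export
visco_state <- function(zero = c(xx = 0, yy = 0, zz = 0, xy = 0)) {
  list(h = zero, e = zero)
}

#' Prony-series deviatoric stress update
#'
#' Exact exponential integrator for the single-term Prony shear relaxation
#' \eqn{G(t) = G_\infty + (G_0-G_\infty)e^{-\beta t}}. The internal deviatoric
#' variable advances as
#' \deqn{h_{n+1} = e^{-\beta\Delta t} h_n + 2 (G_0-G_\infty)
#'       e^{-\beta\Delta t/2} \Delta e,}
#' and the total deviatoric stress is \eqn{s = 2 G_\infty e + h}. The update
#' is exact for piecewise-constant strain rate, reduces to an elastic response
#' with modulus \eqn{G_0} as \eqn{\beta\Delta t \to 0}, and to \eqn{G_\infty}
#' at equilibrium.
#'
#' @param de deviatoric strain increment, named numeric `(xx, yy, zz, xy)`
#'   (tensor shear component, i.e. half the engineering shear).
#' @param dt time step (s), positive.
#' @param params an `"hb_material"` with shear parameters `G0`, `Ginf`, `beta`.
#' @param state state from [visco_state()].
#' @return list with `stress` (deviatoric, same layout as `de`) and `state`.
#' @export
viscoelastic_deviatoric_update <- function(de, dt, params, state = visco_state(de * 0)) {
  stopifnot(dt > 0)
  f <- exp(-params$beta * dt)
  fh <- exp(-params$beta * dt / 2)
  h <- f * state$h + 2 * (params$G0 - params$Ginf) * fh * de
  e <- state$e + de
  list(stress = 2 * params$Ginf * e + h, state = list(h = h, e = e))
}

#' Incremental linear-elastic stress update (plane strain)
#'
#' Isotropic hypoelastic increment \eqn{\Delta\sigma = \lambda
#' \mathrm{tr}(\Delta\varepsilon) I + 2\mu_e \Delta\varepsilon} with the Lame
#' parameters derived from `(E, nu)`. Plane-strain kinematics: the in-plane
#' increment carries `zz = 0` strain but a nonzero `zz` stress.
#'
#' @param deps strain increment, named numeric `(xx, yy, xy)` (tensor shear).
#' @param params an `"hb_material"` of type elastic.
#' @return stress increment, named numeric `(xx, yy, zz, xy)`.
#' @export
elastic_stress_update <- function(deps, params) {
  lam <- params$E * params$nu / ((1 + params$nu) * (1 - 2 * params$nu))
  mu_e <- params$E / (2 * (1 + params$nu))
  tr <- deps[["xx"]] + deps[["yy"]]
  c(xx = lam * tr + 2 * mu_e * deps[["xx"]],
    yy = lam * tr + 2 * mu_e * deps[["yy"]],
    zz = lam * tr,
    xy = 2 * mu_e * deps[["xy"]])
}

#' Material sound speed
#'
#' Longitudinal wave speed used for CFL control and the arrival-front sweep:
#' \eqn{\sqrt{M/\rho}} with the constrained modulus
#' \eqn{M = E(1-\nu)/((1+\nu)(1-2\nu))} for the elastic skull, and
#' \eqn{\sqrt{(A + 4G_0/3)/\rho_0}} for equation-of-state materials (the
#' shear contribution is negligible for brain tissue).
#'
#' @param params an `"hb_material"`.
#' @return speed (m/s).
#' @export
sound_speed <- function(params) {
  if (params$type == "elastic") {
    M <- params$E * (1 - params$nu) / ((1 + params$nu) * (1 - 2 * params$nu))
    sqrt(M / params$rho0)
  } else {
    sqrt((params$A + 4 * params$G0 / 3) / params$rho0)
  }
}

#' Single-element shear relaxation test
#'
#' Applies a step engineering shear strain at t = 0 to one element of the
#' given material, holds it, and advances the deviatoric update to `t_end`.
#' The realized relaxation curve is the standard characterization test for
#' the Prony parameters: stress/strain equals G0 immediately after the step
#' and G-infinity at equilibrium.
#'
#' @param params an `"hb_material"` of type tissue (or fluid, trivially zero).
#' @param gamma engineering shear strain of the step (default 0.01).
#' @param dt time step (s).
#' @param t_end hold duration (s).
#' @return data.frame with columns `time` (s) and `stress` (shear stress,
#'   Pa), sampled at every step, first row at `time = dt`.
#' @export
relaxation_test <- function(params, gamma = 0.01, dt = 1e-6, t_end = 0.1) {
  n <- ceiling(t_end / dt)
  de <- c(xx = 0, yy = 0, zz = 0, xy = gamma / 2)
  st <- visco_state(de * 0)
  stress <- numeric(n)
  for (i in seq_len(n)) {
    up <- viscoelastic_deviatoric_update(if (i == 1L) de else de * 0, dt, params, st)
    st <- up$state
    stress[i] <- up$stress[["xy"]]
  }
  data.frame(time = dt * seq_len(n), stress = stress)
}

#' Single-element volumetric tension/compression test
#'
#' Drives an element of the given material through a prescribed compression
#' history and records the clamped pressure and cavitation flags.
#'
#' @param params an `"hb_material"` with an equation of state.
#' @param mu_history numeric vector of compression values.
#' @return data.frame with `mu`, `pressure` (Pa), `cavitating_now`,
#'   `ever_cavitated`.
#' @export
volumetric_test <- function(params, mu_history) {
  st <- material_state(1L)
  out <- data.frame(mu = mu_history, pressure = NA_real_,
                    cavitating_now = NA, ever_cavitated = NA)
  for (i in seq_along(mu_history)) {
    r <- eos_pressure(mu_history[i], params, st)
    st <- r$state
    out$pressure[i] <- r$pressure
    out$cavitating_now[i] <- st$cavitating_now
    out$ever_cavitated[i] <- st$ever_cavitated
  }
  out
}

#' Fit the Prony decay constant from a relaxation curve
#'
#' Ordinary least squares on \eqn{\log(\tau(t) - \tau_\infty)} versus time;
#' the negated slope estimates the decay constant beta.
#'
#' @param time,stress relaxation samples (s, Pa).
#' @param equilibrium_stress long-term stress \eqn{G_\infty \gamma} (Pa).
#' @return estimated beta (1/s).
#' @export
fit_prony_beta <- function(time, stress, equilibrium_stress) {
  y <- stress - equilibrium_stress
  keep <- y > 0
  -unname(stats::coef(stats::lm(log(y[keep]) ~ time[keep]))[2])
}

#' Recover all three Prony parameters from a relaxation curve
#'
#' Nonlinear least squares of \eqn{\tau(t)/\gamma = G_\infty +
#' (G_0-G_\infty)e^{-\beta t}} to a simulated relaxation curve, started from
#' a log-linear fit.
#'
#' @param time,stress relaxation samples (s, Pa).
#' @param gamma engineering shear strain of the step.
#' @return named numeric `(G0, Ginf, beta)` (Pa, Pa, 1/s).
#' @export
recover_prony <- function(time, stress, gamma = 0.01) {
  g <- stress / gamma
  ginf0 <- min(g)
  b0 <- fit_prony_beta(time, g, ginf0 * 0.999)
  # scaleOffset keeps nls stable on (near-)zero-residual synthetic curves
  fit <- stats::nls(g ~ Ginf + (G0 - Ginf) * exp(-beta * time),
                    start = list(G0 = max(g), Ginf = ginf0, beta = b0),
                    control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  p <- stats::coef(fit)
  c(G0 = unname(p["G0"]), Ginf = unname(p["Ginf"]), beta = unname(p["beta"]))
}
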