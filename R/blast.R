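#' Blast exposure scenario
#'
#' Describes the incident blast: a Friedlander-shaped overpressure waveform,
#' its propagation direction, ambient air state, and an optional reflecting
#' wall modeled by an image source. Units follow field convention: kPa for
#' pressures, ms for times, m/s for speeds, mm for mesh coordinates (note
#' 1 m/s = 1 mm/ms, so speeds combine with mesh units directly).
#'
#' @param peak_overpressure incident peak overpressure (kPa, gauge). The
#'   study set is 150, 250 and 500 kPa.
#' @param duration positive-phase duration t_d (ms, default 1).
#' @param decay dimensionless Friedlander decay constant b (default 1).
#' @param direction unit propagation vector in mesh coordinates. Presets:
#'   front = c(0, -1) (anterior to posterior), side = c(1, 0) (left to
#'   right).
#' @param P0 ambient absolute pressure (kPa, default 101.325).
#' @param c0 ambient sound speed (m/s, default 340).
#' @param gamma_air ratio of specific heats (default 1.4).
#' @param wall optional list `(distance, angle, side)`: a reflecting surface
#'   `distance` cm from the given side of the head, rotated `angle` degrees
#'   off the blast direction (defaults 6.3 cm, 26.5 deg, "left").
#' @param negative_floor lower clip for the gauge waveform (kPa, default
#'   -P0, the absolute-vacuum limit).
#' @return object of class `"blast_scenario"`.
#' @export
blast_scenario <- function(peak_overpressure = 250, duration = 1, decay = 1,
                           direction = c(0, -1), P0 = 101.325, c0 = 340,
                           gamma_air = 1.4, wall = NULL,
                           negative_floor = -P0) {
  stopifnot(peak_overpressure > 0, duration > 0, gamma_air > 0, P0 > 0, c0 > 0)
  direction <- direction / sqrt(sum(direction^2))
  if (!is.null(wall)) {
    wall <- utils::modifyList(list(distance = 6.3, angle = 26.5, side = "left"), wall)
    stopifnot(wall$distance > 0, wall$side %in% c("left", "right"))
  }
  structure(list(peak_overpressure = peak_overpressure, duration = duration,
                 decay = decay, direction = direction, P0 = P0, c0 = c0,
                 gamma_air = gamma_air, wall = wall,
                 negative_floor = negative_floor),
            class = "blast_scenario")
}

#' @export
print.blast_scenario <- function(x, ...) {
  cat(sprintf("<blast_scenario> %g kPa peak, t_d = %g ms, b = %g, direction (%.2f, %.2f)\n",
              x$peak_overpressure, x$duration, x$decay,
              x$direction[1], x$direction[2]))
  if (!is.null(x$wall))
    cat(sprintf("  wall reflector: %g cm, %g deg, %s side\n",
                x$wall$distance, x$wall$angle, x$wall$side))
  invisible(x)
}

#' Named scenario presets
#'
#' `"front-150"`, `"front-250"`, `"front-500"`, `"side-*"` and `"wall-*"`
#' expand to the corresponding [blast_scenario()]. The wall scenarios are
#' front blasts with the default reflecting surface (6.3 cm from the left
#' side of the head at 26.5 degrees off the blast direction).
#'
#' @param name preset name, e.g. `"wall-500"`.
#' @return a `"blast_scenario"`.
#' @export
scenario_preset <- function(name) {
  m <- regmatches(name, regexec("^(front|side|wall)-(150|250|500)$", name))[[1]]
  if (length(m) == 0) stop("unknown scenario preset: ", name)
  peak <- as.numeric(m[3])
  switch(m[2],
         front = blast_scenario(peak, direction = c(0, -1)),
         side  = blast_scenario(peak, direction = c(1, 0)),
         wall  = blast_scenario(peak, direction = c(0, -1), wall = list()))
}

#' Friedlander incident waveform
#'
#' Modified Friedlander profile
#' \eqn{p(t) = P_{peak} (1 - t/t_d) e^{-b t / t_d}} for \eqn{t \ge 0},
#' zero before arrival, clipped below at the scenario's negative-phase
#' floor. The first zero crossing after onset is exactly t_d.
#'
#' @param scenario a [blast_scenario()].
#' @return a function `p(t)` (t in ms since arrival, result gauge kPa) of
#'   class `"pressure_waveform"`.
#' @export
friedlander_waveform <- function(scenario) {
  P <- scenario$peak_overpressure
  td <- scenario$duration
  b <- scenario$decay
  floor_p <- scenario$negative_floor
  f <- function(t) {
    p <- ifelse(t < 0, 0, P * (1 - t / td) * exp(-b * t / td))
    pmax(p, floor_p)
  }
  structure(f, scenario = scenario, class = c("pressure_waveform", "function"))
}

#' @export
print.pressure_waveform <- function(x, ...) {
  s <- attr(x, "scenario")
  cat(sprintf("<pressure_waveform> Friedlander, peak %g kPa, t_d %g ms, b %g\n",
              s$peak_overpressure, s$duration, s$decay))
  invisible(x)
}

#' @export
plot.pressure_waveform <- function(x, t_max = NULL, ...) {
  s <- attr(x, "scenario")
  if (is.null(t_max)) t_max <- 3 * s$duration
  t <- seq(-0.1 * s$duration, t_max, length.out = 400)
  graphics::plot(t, x(t), type = "l", xlab = "time since arrival (ms)",
                 ylab = "overpressure (kPa)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Rankine-Hugoniot reflection amplification
#'
#' Normal-incidence reflected overpressure from the ideal-gas relation
#' \deqn{\Delta P_r = 2 \Delta P_i +
#'   \frac{(\gamma+1)\,\Delta P_i^2}{(\gamma-1)\Delta P_i + 2\gamma P_0},}
#' interpolated with the incidence cosine between side-on (grazing,
#' cosine 0, factor 1) and face-on (cosine 1, full reflection). In the
#' acoustic limit the normal factor tends to 2.
#'
#' @param incident_overpressure incident overpressure (kPa, >= 0), vectorized.
#' @param P0 ambient absolute pressure (kPa).
#' @param gamma ratio of specific heats.
#' @param incidence_cosine cosine of the incidence angle in `[0, 1]`
#'   (1 = head-on).
#' @return dimensionless multiplier: applied overpressure / incident.
#' @export
reflection_factor <- function(incident_overpressure, P0 = 101.325,
                              gamma = 1.4, incidence_cosine = 1) {
  if (any(incident_overpressure < 0)) stop("incident overpressure must be >= 0")
  stopifnot(all(incidence_cosine >= 0), all(incidence_cosine <= 1))
  # ratio dP_r / dP_i, finite limit 2 as dP_i -> 0
  cr <- 2 + (gamma + 1) * incident_overpressure /
    ((gamma - 1) * incident_overpressure + 2 * gamma * P0)
  1 + (cr - 1) * incidence_cosine
}

#' Shock front propagation speed
#'
#' Ideal-gas shock speed
#' \eqn{U = c_0 \sqrt{1 + \frac{\gamma+1}{2\gamma}\,\Delta P_i / P_0}}
#' used to sweep the arrival front across the skull exterior.
#'
#' @param scenario a [blast_scenario()].
#' @param peak optional overpressure override (kPa).
#' @return speed (m/s = mm/ms).
#' @export
shock_front_speed <- function(scenario, peak = scenario$peak_overpressure) {
  scenario$c0 * sqrt(1 + (scenario$gamma_air + 1) / (2 * scenario$gamma_air) *
                       peak / scenario$P0)
}

# Wall reflector line in mesh coordinates: returns list(point, normal) with
# the unit normal pointing toward the head, or NULL when no wall is set.
wall_line <- function(mesh, scenario) {
  w <- scenario$wall
  if (is.null(w)) return(NULL)
  d <- scenario$direction
  lat <- if (w$side == "left") c(-1, 0) else c(1, 0)
  # wall direction: blast direction rotated by +/- angle toward the head side
  ang <- w$angle * pi / 180 * if (w$side == "left") 1 else -1
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  wdir <- as.numeric(rot %*% d)
  n <- c(-wdir[2], wdir[1])
  if (sum(n * lat) > 0) n <- -n       # normal points away from the wall side
  ext <- mesh$nodes[which.max(mesh$nodes %*% (-n)), ]  # head extreme toward wall
  list(point = as.numeric(ext) - n * (w$distance * 10), normal = n)
}

mirror_across_line <- function(p, line) {
  # p: n x 2 matrix
  v <- sweep(p, 2, line$point)
  dist <- as.numeric(v %*% line$normal)
  p - 2 * outer(dist, line$normal)
}

#' Blast front arrival times on the skull exterior
#'
#' A planar front sweeps the mesh along the scenario direction at the shock
#' speed; the earliest-struck boundary face has arrival time zero. With a
#' wall reflector, a second front from the image source (the direct front
#' mirrored across the wall plane, carrying the wall-reflected amplitude)
#' is added with its own arrival times.
#'
#' @param mesh a `"phantom_mesh"`.
#' @param scenario a [blast_scenario()].
#' @return data.frame with one row per (boundary face, front): columns
#'   `face`, `front` ("direct"/"image"), `t_arrival` (ms), `cos_inc`
#'   (clipped incidence cosine of the face against that front), `peak`
#'   (front peak overpressure, kPa), `dir_x`, `dir_y`.
#' @export
arrival_times <- function(mesh, scenario) {
  bf <- mesh$boundary_faces
  stopifnot(!is.null(bf))
  d <- scenario$direction
  U <- shock_front_speed(scenario)
  cent <- cbind(bf$cx, bf$cy)
  s <- cent %*% d
  s0 <- min(s)
  cosd <- pmax(0, -(bf$nx * d[1] + bf$ny * d[2]))
  out <- data.frame(face = seq_len(nrow(bf)), front = "direct",
                    t_arrival = as.numeric(s - s0) / U, cos_inc = cosd,
                    peak = scenario$peak_overpressure,
                    dir_x = d[1], dir_y = d[2])
  wl <- wall_line(mesh, scenario)
  if (!is.null(wl)) {
    # image front: arrival at x equals direct-front arrival at mirror(x)
    mc <- mirror_across_line(cent, wl)
    t_img <- as.numeric(mc %*% d - s0) / U
    dimg <- as.numeric(d - 2 * sum(d * wl$normal) * wl$normal)
    cosw <- abs(sum(d * wl$normal))
    peak_img <- scenario$peak_overpressure *
      reflection_factor(scenario$peak_overpressure, scenario$P0,
                        scenario$gamma_air, cosw)
    cosi <- pmax(0, -(bf$nx * dimg[1] + bf$ny * dimg[2]))
    out <- rbind(out, data.frame(face = seq_len(nrow(bf)), front = "image",
                                 t_arrival = t_img, cos_inc = cosi,
                                 peak = peak_img,
                                 dir_x = dimg[1], dir_y = dimg[2]))
  }
  out
}

#' Boundary tractions at a given time
#'
#' Normal (compressive-positive) traction on every exterior face: the sum
#' over fronts of the Friedlander waveform delayed by the face arrival time,
#' amplified by the Rankine-Hugoniot reflection factor evaluated at the
#' instantaneous overpressure and the face's clipped incidence cosine.
#' Faces facing away from a front (cosine clipped to 0) receive side-on
#' loading. The summed gauge traction is floored at the scenario's
#' negative-phase floor.
#'
#' @param mesh a `"phantom_mesh"`.
#' @param scenario a [blast_scenario()].
#' @param t time (ms).
#' @param arrivals optional precomputed [arrival_times()] table.
#' @return numeric vector, traction per boundary face (kPa).
#' @export
boundary_traction <- function(mesh, scenario, t,
                              arrivals = arrival_times(mesh, scenario)) {
  nb <- nrow(mesh$boundary_faces)
  total <- numeric(nb)
  for (fr in unique(arrivals$front)) {
    a <- arrivals[arrivals$front == fr, ]
    sc <- scenario
    sc$peak_overpressure <- a$peak[1]
    w <- friedlander_waveform(sc)
    p <- w(t - a$t_arrival)
    fac <- ifelse(p > 0,
                  reflection_factor(pmax(p, 0), scenario$P0,
                                    scenario$gamma_air, a$cos_inc),
                  1 + a$cos_inc)   # acoustic limit for the negative phase
    total[a$face] <- total[a$face] + p * fac
  }
  pmax(total, scenario$negative_floor)
}

#' Dump a waveform as a two-column table
#'
#' @param scenario a [blast_scenario()].
#' @param path output CSV path (time ms, overpressure kPa).
#' @param t_max last sample time (ms), default 3 durations.
#' @param dt sample interval (ms).
#' @return the data.frame, invisibly.
#' @export
dump_waveform <- function(scenario, path, t_max = 3 * scenario$duration,
                          dt = 0.001) {
  w <- friedlander_waveform(scenario)
  t <- seq(0, t_max, by = dt)
  df <- data.frame(time_ms = t, overpressure_kPa = w(t))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
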