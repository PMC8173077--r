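# Shared fixtures. Heavy simulations are cached per test session so the
# acceptance checks and the invariant tests reuse the same runs.

.hb_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.hb_cache[[name]])) .hb_cache[[name]] <- force(expr)
  .hb_cache[[name]]
}

# coarse study phantom used by all full-head dynamics tests: sulci widened
# so the gyral boundary stays resolvable at this element size
coarse_params <- function(...) {
  args <- utils::modifyList(list(target_element_size = 5, n_gyri_per_side = 5,
                                 sulcal_width = 10), list(...))
  do.call(geometry_params, args)
}

coarse_phantom <- function() cached("mesh", build_head_geometry(coarse_params()))

# full blast run on the coarse phantom (6 ms study duration)
front_run <- function(peak, materials = "normal") {
  cached(sprintf("run-%d-%s", peak, materials), {
    run_simulation(simulation_config(
      scenario = scenario_preset(sprintf("front-%d", peak)),
      geometry = coarse_phantom(),
      materials = material_library(materials),
      end_time = 6, output_interval = 1))
  })
}

# vascular fixture: one 0.6 mm channel near the loaded crown
vascular_mesh <- function() {
  cached("vascular-mesh", {
    vs <- list(list(diameter = 0.6, position = 1, center = c(0, 50)))
    build_head_geometry(geometry_params(
      target_element_size = 6, n_gyri_per_side = 5, sulcal_width = 11,
      vessel_spec = vs))
  })
}

# vascular run: early-time window of the 150 kPa front blast
vascular_run <- function() {
  cached("vascular", {
    run_simulation(simulation_config(
      scenario = scenario_preset("front-150"), geometry = vascular_mesh(),
      end_time = 1.4, cfl_factor = 0.6, output_interval = 0.35))
  })
}

# element mirror map x -> -x (NA where unmatched)
mirror_map <- function(mesh, tol = 1e-4) {
  cent <- cbind(rowMeans(matrix(mesh$nodes[mesh$elem, 1], nrow(mesh$elem), 4)),
                rowMeans(matrix(mesh$nodes[mesh$elem, 2], nrow(mesh$elem), 4)))
  map <- integer(nrow(cent))
  for (e in seq_len(nrow(cent))) {
    d2 <- (cent[, 1] + cent[e, 1])^2 + (cent[, 2] - cent[e, 2])^2
    j <- which.min(d2)
    map[e] <- if (d2[j] < tol^2) j else NA_integer_
  }
  map
}
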