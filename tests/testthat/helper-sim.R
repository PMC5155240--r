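# shared simulation objects, built lazily once per test run

.sim_cache <- new.env(parent = emptyenv())

# the default paperlike ensemble with its forcing (8 sites, 1851-2009)
paperlike_setup <- function() {
  if (is.null(.sim_cache$setup)) {
    sites <- make_ensemble(8, seed = 1)
    forcing <- generate_forcing_ensemble(sites, 1851:2009, seed = 1)
    .sim_cache$setup <- list(sites = sites, forcing = forcing)
  }
  .sim_cache$setup
}

# full six-scenario suite on the paperlike ensemble (expensive; shared)
paperlike_suite <- function() {
  if (is.null(.sim_cache$suite)) {
    su <- paperlike_setup()
    .sim_cache$suite <- run_scenarios(su$sites, su$forcing)
  }
  .sim_cache$suite
}

# a small constant-driver setup for cheap single-site model tests
demo_drivers <- function(dep = 0.05) {
  list(temperature = 12, precipitation = 900, co2 = 296, n_deposition = dep)
}

demo_params <- function(...) {
  p <- nsat_params(...)
  p$alloc_base <- c(leaf = 0.3, wood = 0.4, root = 0.3)
  p
}

demo_curve <- function(n_ms = 10, ...) modifier_curve(n_ms, ...)

# per-site means over the 1970-2009 window of a run variable
site_window_mean <- function(run, variable, years = 1970:2009) {
  d <- run$data[run$data$year %in% years, ]
  tapply(d[[variable]], d$site_id, mean)
}
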