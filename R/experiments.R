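#' The six-scenario factorial design
#'
#' One fully dynamic simulation (NCC) plus four runs in which a single
#' driver is held at its 1970 value from 1970 onwards (NNC: nitrogen
#' deposition; CNC: CO2; TNC: temperature; PNC: precipitation) and one run
#' (NNS) in which the three nitrogen-control modifiers are set to 1 in
#' site-years whose deposition exceeds the critical load, removing the
#' saturation effect.
#'
#' @return data.frame with one row per scenario.
#' @export
scenario_table <- function() {
  data.frame(
    no = 1:6,
    name = c("NCC", "NNC", "CNC", "TNC", "PNC", "NNS"),
    full_name = c("Nitrogen CO2 Climate", "No Nitrogen Change",
                  "CO2 No Change", "Temperature No Change",
                  "Precipitation No Change", "No N Saturation effect"),
    temperature = c("dynamic", "dynamic", "dynamic", "1970", "dynamic",
                    "dynamic"),
    precipitation = c("dynamic", "dynamic", "dynamic", "dynamic", "1970",
                      "dynamic"),
    co2 = c("dynamic", "dynamic", "1970", "dynamic", "dynamic", "dynamic"),
    n_deposition = c("dynamic", "1970", "dynamic", "dynamic", "dynamic",
                     "dynamic"),
    saturation_active = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Scenario configuration
#'
#' @param name scenario name (`NCC`, `NNC`, `CNC`, `TNC`, `PNC`, `NNS`).
#' @param freeze_year year at which frozen drivers are held (default 1970).
#' @return an object of class `scenario_config` with elements `name`,
#'   `full_name`, `frozen_driver` (or `NULL`), `freeze_year`,
#'   `saturation_active`.
#' @examples
#' scenario_config("NNC")$frozen_driver
#' @export
scenario_config <- function(name, freeze_year = 1970) {
  tab <- scenario_table()
  if (inherits(name, "scenario_config")) return(name)
  if (!name %in% tab$name)
    stop("unknown scenario '", name, "'; known: ",
         paste(tab$name, collapse = ", "))
  row <- tab[tab$name == name, ]
  drivers <- c("temperature", "precipitation", "co2", "n_deposition")
  frozen <- drivers[vapply(drivers, function(d) row[[d]] == "1970",
                           logical(1))]
  structure(list(name = row$name, full_name = row$full_name,
                 frozen_driver = if (length(frozen)) frozen else NULL,
                 freeze_year = freeze_year,
                 saturation_active = row$saturation_active),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %s (%s)\n", x$name, x$full_name))
  cat(sprintf("  frozen driver    : %s\n",
              x$frozen_driver %||% "none"))
  cat(sprintf("  saturation active: %s\n", x$saturation_active))
  invisible(x)
}

# stage-1/stage-2 state shared across scenarios: threshold derivation plus
# spin-up to carbon equilibrium under climatological forcing
prepare_site <- function(site, forcing, params, cl_table,
                         climatology_window, baseline_ndep, pin_stage1) {
  clim <- spinup_climatology(forcing, climatology_window)
  cl <- lookup_cl(cl_table, site$vegetation_type, site$region)
  n_ms <- derive_nms(site, cl_table, params, clim, cl = cl)
  curve <- modifier_curve(as.numeric(n_ms),
                          n_mmax = params$n_mmax_factor * as.numeric(n_ms),
                          kp_floor = params$kp_floor,
                          k1_floor = params$k1_floor,
                          km_floor = params$km_floor,
                          k0 = params$k0,
                          legacy_ceiling = params$legacy_ceiling)
  drv <- climatology_drivers(clim)
  drv$n_deposition <- baseline_ndep
  sp <- params_for_veg(params, site$vegetation_type)
  eq <- run_to_equilibrium(ecosystem_state(), drv, sp, curve,
                           mode = "saturation",
                           pin_modifiers = pin_stage1, criterion = "nep")
  list(cl = cl, n_ms = as.numeric(n_ms), curve = curve, state = eq$state,
       spinup_years = eq$years, spinup_nep = eq$nep, params = sp)
}

#' Run the three-stage simulation protocol for one scenario
#'
#' Stage 1 (spin-up): climatological forcing with deposition at a baseline
#' of 0.05 g N m-2 yr-1, run to carbon equilibrium. Stage 2 (1901-1969):
#' transient climate and CO2 with deposition fixed at its 1970 value.
#' Stage 3 (1970-2009): fully dynamic drivers, with the scenario's frozen
#' driver (if any) held at its 1970 value and, in the no-saturation
#' scenario, the nitrogen-control modifiers pinned to 1 in site-years
#' whose deposition exceeds the critical load. The saturation threshold of
#' each site is derived from its critical load before the run. The whole
#' protocol is deterministic given the forcing.
#'
#' @param sites a `site_ensemble` (see [make_ensemble()]).
#' @param forcing named list of `forcing_series`, one per site (see
#'   [generate_forcing_ensemble()]).
#' @param scenario scenario name or [scenario_config()].
#' @param params parameter list from [nsat_params()].
#' @param cl_table a [critical_load_table()].
#' @param climatology_window years averaged for the spin-up climatology
#'   (default: the first 50 years of the forcing).
#' @param baseline_ndep spin-up deposition, g N m-2 yr-1.
#' @param .cache optional environment reused across scenarios to share the
#'   (scenario-independent) threshold derivation and spin-up per site.
#' @return an object of class `nsat_run`: scenario, sites, annual results
#'   (`$data`, one row per site-year with carbon fluxes, nitrogen pools,
#'   modifiers and stage markers) and spin-up diagnostics (`$spinup`).
#' @export
run_protocol <- function(sites, forcing, scenario, params = nsat_params(),
                         cl_table = critical_load_table(),
                         climatology_window = NULL, baseline_ndep = 0.05,
                         .cache = NULL) {
  stopifnot(inherits(sites, "site_ensemble"))
  scenario <- scenario_config(scenario)
  missing_f <- setdiff(sites$site_id, names(forcing))
  if (length(missing_f))
    stop("forcing missing for site(s): ", paste(missing_f, collapse = ", "))
  rows <- vector("list", nrow(sites))
  spin <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    site <- as.list(sites[i, ])
    f <- forcing[[site$site_id]]
    window <- climatology_window %||%
      f$years[f$years <= min(f$years) + 49]
    cl_i <- lookup_cl(cl_table, site$vegetation_type, site$region)
    pin_stage1 <- !scenario$saturation_active && baseline_ndep > cl_i
    key <- paste(site$site_id, pin_stage1, sep = "|")
    prep <- if (!is.null(.cache) && !is.null(.cache[[key]])) .cache[[key]]
    else {
      p <- prepare_site(site, f, params, cl_table, window, baseline_ndep,
                        pin_stage1)
      if (!is.null(.cache)) .cache[[key]] <- p
      p
    }
    sp <- prep$params
    state <- prep$state

    # scenario driver freezing applies from the freeze year onwards
    f_run <- f
    if (!is.null(scenario$frozen_driver) &&
        scenario$freeze_year %in% f$years)
      for (d in scenario$frozen_driver)
        f_run <- freeze_driver(f_run, d, scenario$freeze_year)
    ann <- annual_drivers(f_run)
    dep_1970 <- if (1970 %in% f$years)
      as.numeric(f$n_deposition[as.character(1970)])
    else ann$n_deposition[1]
    transient <- ann$year >= max(1901L, min(f$years))
    ann <- ann[transient, , drop = FALSE]
    ny <- nrow(ann)
    out <- matrix(NA_real_, ny, 18)
    colnames(out) <- c("gpp", "npp", "rh", "nep", "n_deposition",
                       "n_mineral", "n_organic", "n_plant", "leaf", "wood",
                       "root", "litter", "soc", "kp", "k1", "km",
                       "saturation_degree", "pinned")
    for (j in seq_len(ny)) {
      yr <- ann$year[j]
      dep <- if (yr < 1970) dep_1970 else ann$n_deposition[j]
      drv <- list(temperature = ann$temperature[j],
                  precipitation = ann$precipitation[j],
                  co2 = ann$co2[j], n_deposition = dep)
      pin <- !scenario$saturation_active && dep > prep$cl
      res <- step_year(state, drv, sp, prep$curve,
                       mode = "saturation", pin_modifiers = pin)
      state <- res$state
      out[j, ] <- c(res$cflux$gpp, res$cflux$npp, res$cflux$rh,
                    res$cflux$nep, dep,
                    state[["n_mineral"]], state[["n_organic"]],
                    state[["n_plant"]], state[["leaf"]], state[["wood"]],
                    state[["root"]], state[["litter"]], state[["soc"]],
                    res$modifiers[["kp"]], res$modifiers[["k1"]],
                    res$modifiers[["km"]], res$saturation_degree,
                    as.numeric(pin))
    }
    df <- data.frame(site_id = site$site_id, year = ann$year,
                     stage = ifelse(ann$year < 1970, "1901-1969",
                                    "1970-2009"),
                     as.data.frame(out), stringsAsFactors = FALSE)
    df$saturated <- df$n_deposition > prep$cl
    rows[[i]] <- df
    spin[[i]] <- data.frame(site_id = site$site_id, cl = prep$cl,
                            n_ms = prep$n_ms,
                            spinup_years = prep$spinup_years,
                            spinup_nep = prep$spinup_nep,
                            stringsAsFactors = FALSE)
  }
  structure(list(scenario = scenario, sites = sites,
                 data = do.call(rbind, rows),
                 spinup = do.call(rbind, spin)),
            class = "nsat_run")
}

#' Run several scenarios with a shared spin-up
#'
#' Runs [run_protocol()] for each requested scenario, reusing the
#' per-site threshold derivation and spin-up (which do not depend on the
#' scenario) across runs.
#'
#' @inheritParams run_protocol
#' @param scenarios character vector of scenario names.
#' @return named list of `nsat_run` objects, class `nsat_runs`.
#' @export
run_scenarios <- function(sites, forcing,
                          scenarios = c("NCC", "NNC", "CNC", "TNC", "PNC",
                                        "NNS"),
                          params = nsat_params(),
                          cl_table = critical_load_table(), ...) {
  cache <- new.env(parent = emptyenv())
  runs <- lapply(scenarios, function(s)
    run_protocol(sites, forcing, s, params, cl_table, .cache = cache, ...))
  structure(stats::setNames(runs, scenarios), class = "nsat_runs")
}

# area-weighted ensemble-mean flux per year
global_series <- function(run, variable) {
  stopifnot(inherits(run, "nsat_run"))
  if (!variable %in% names(run$data)) stop("unknown variable: ", variable)
  w <- run$sites$area[match(run$data$site_id, run$sites$site_id)]
  wx <- run$data[[variable]] * w
  num <- tapply(wx, run$data$year, sum)
  den <- tapply(w, run$data$year, sum)
  yrs <- as.integer(names(num))
  data.frame(year = yrs,
             stage = ifelse(yrs < 1970, "1901-1969", "1970-2009"),
             value = as.numeric(num / den))
}

#' Difference two scenario runs
#'
#' Element-wise per-site-year difference `a - b` of a flux or pool
#' variable, together with the area-weighted ensemble series of both runs,
#' and summary statistics over the 1970-2009 analysis window: mean
#' difference, interannual standard deviation of the difference, and the
#' mean expressed as a percentage of run `b`'s mean.
#'
#' @param a,b `nsat_run` objects over the same sites and years.
#' @param variable column of `$data` to difference (default `"npp"`).
#' @return an object of class `scenario_diff` with elements `per_site`
#'   (site-year differences), `global` (per-year ensemble means of both
#'   runs and their difference), `mean`, `sd`, `pct`.
#' @export
diff_scenarios <- function(a, b, variable = "npp") {
  stopifnot(inherits(a, "nsat_run"), inherits(b, "nsat_run"))
  if (!identical(a$data$site_id, b$data$site_id) ||
      !identical(a$data$year, b$data$year))
    stop("runs do not share the same sites and years")
  per_site <- data.frame(site_id = a$data$site_id, year = a$data$year,
                         stage = a$data$stage,
                         diff = a$data[[variable]] - b$data[[variable]],
                         stringsAsFactors = FALSE)
  ga <- global_series(a, variable)
  gb <- global_series(b, variable)
  global <- data.frame(year = ga$year, stage = ga$stage, a = ga$value,
                       b = gb$value, diff = ga$value - gb$value)
  s3 <- global$stage == "1970-2009"
  m <- mean(global$diff[s3])
  structure(list(variable = variable,
                 scenario_a = a$scenario$name, scenario_b = b$scenario$name,
                 per_site = per_site, global = global,
                 mean = m, sd = stats::sd(global$diff[s3]),
                 pct = 100 * m / mean(global$b[s3])),
            class = "scenario_diff")
}

#' @export
print.scenario_diff <- function(x, ...) {
  cat(sprintf("Scenario difference %s - %s, variable %s (1970-2009)\n",
              x$scenario_a, x$scenario_b, x$variable))
  cat(sprintf("  mean  : %+.4g\n  sd    : %.4g\n  pct of %s mean: %+.3g%%\n",
              x$mean, x$sd, x$scenario_b, x$pct))
  invisible(x)
}

#' Aggregate a run by biome
#'
#' Area-weighted totals of a flux variable per biome class, with each
#' biome's percentage share of the ensemble total. Fluxes (g m-2 yr-1)
#' are multiplied by site area (m2), so totals are in g yr-1.
#'
#' @param result an `nsat_run`.
#' @param sites site ensemble (defaults to the run's own).
#' @param weights per-site areas in m2 (> 0; defaults to `sites$area`).
#' @param variable flux column to aggregate.
#' @param years years to average over (default: the 1970-2009 stage).
#' @return data.frame with `biome_label`, `total` (g yr-1) and `share`
#'   (percent; shares sum to 100).
#' @export
aggregate_by_biome <- function(result, sites = result$sites,
                               weights = sites$area, variable = "npp",
                               years = NULL) {
  stopifnot(inherits(result, "nsat_run"))
  if (any(weights <= 0)) stop("weights must be positive")
  if (!all(sites$biome_label %in% biome_labels()))
    stop("unknown biome label(s): ",
         paste(setdiff(sites$biome_label, biome_labels()), collapse = ", "))
  d <- result$data
  if (is.null(years)) years <- d$year[d$stage == "1970-2009"]
  d <- d[d$year %in% years, ]
  site_mean <- tapply(d[[variable]], d$site_id, mean)
  i <- match(names(site_mean), sites$site_id)
  totals <- as.numeric(site_mean) * weights[i]
  biome <- sites$biome_label[i]
  agg <- tapply(totals, biome, sum)
  out <- data.frame(biome_label = names(agg), total = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$share <- 100 * out$total / sum(out$total)
  out[order(-out$share), ]
}

#' Factorial driver attribution
#'
#' Summarizes the contribution of each driver to the ensemble NPP and NEP
#' over 1970-2009: for CO2, temperature, precipitation and nitrogen
#' deposition the contribution is the fully dynamic run minus the run
#' with that driver frozen at 1970 (NCC - CNC, NCC - TNC, NCC - PNC,
#' NCC - NNC); for nitrogen saturation it is the no-saturation run minus
#' the dynamic run (NNS - NCC), i.e. the production lost to saturation.
#' Each contribution is reported as mean, interannual SD, and percent of
#' the dynamic run's mean.
#'
#' @param runs named list of `nsat_run` objects containing all six
#'   scenarios (see [run_scenarios()]).
#' @param variables flux columns to attribute.
#' @return data.frame with `driver`, `variable`, `mean`, `sd`, `pct`.
#' @export
attribution_summary <- function(runs, variables = c("npp", "nep")) {
  need <- c("NCC", "NNC", "CNC", "TNC", "PNC", "NNS")
  miss <- setdiff(need, names(runs))
  if (length(miss)) stop("missing scenario run(s): ",
                         paste(miss, collapse = ", "))
  pairs <- list(co2 = c("NCC", "CNC"), temperature = c("NCC", "TNC"),
                precipitation = c("NCC", "PNC"),
                n_deposition = c("NCC", "NNC"),
                n_saturation = c("NNS", "NCC"))
  out <- list()
  for (v in variables) {
    ncc_mean <- {
      g <- global_series(runs$NCC, v)
      mean(g$value[g$stage == "1970-2009"])
    }
    for (d in names(pairs)) {
      dd <- diff_scenarios(runs[[pairs[[d]][1]]], runs[[pairs[[d]][2]]], v)
      out[[length(out) + 1]] <- data.frame(
        driver = d, variable = v, mean = dd$mean, sd = dd$sd,
        pct = 100 * dd$mean / ncc_mean, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.nsat_run <- function(x, ...) {
  cat(sprintf("Simulation run: scenario %s (%s)\n", x$scenario$name,
              x$scenario$full_name))
  cat(sprintf("  sites : %d   years: %d-%d\n", nrow(x$sites),
              min(x$data$year), max(x$data$year)))
  g <- global_series(x, "npp")
  s3 <- g$stage == "1970-2009"
  cat(sprintf("  ensemble NPP 1970-2009: %.1f g C m-2 yr-1 (mean)\n",
              mean(g$value[s3])))
  cat(sprintf("  spin-up: %d-%d years to |NEP| < tolerance\n",
              min(x$spinup$spinup_years), max(x$spinup$spinup_years)))
  invisible(x)
}

#' @export
summary.nsat_run <- function(object, ...) {
  d <- object$data[object$data$stage == "1970-2009", ]
  agg <- aggregate(d[, c("npp", "nep", "rh", "n_mineral")],
                   by = list(site_id = d$site_id), FUN = mean)
  agg$saturated_years <- tapply(d$saturated, d$site_id, sum)[agg$site_id]
  cat(sprintf("Scenario %s, per-site means over 1970-2009\n",
              object$scenario$name))
  print(agg, row.names = FALSE, digits = 4)
  invisible(agg)
}

#' @export
plot.nsat_run <- function(x, variable = "npp", ...) {
  g <- global_series(x, variable)
  graphics::plot(g$year, g$value, type = "l", lwd = 2,
                 xlab = "year", ylab = paste(variable, "(g m-2 yr-1)"),
                 main = sprintf("Scenario %s", x$scenario$name), ...)
  graphics::abline(v = 1970, col = "grey70", lty = 3)
  invisible(g)
}

#' @export
print.nsat_runs <- function(x, ...) {
  cat(sprintf("Scenario suite: %s\n", paste(names(x), collapse = ", ")))
  for (r in x) {
    g <- global_series(r, "npp")
    s3 <- g$stage == "1970-2009"
    cat(sprintf("  %-4s NPP %.1f  NEP %+.2f g C m-2 yr-1 (1970-2009 mean)\n",
                r$scenario$name, mean(g$value[s3]),
                mean(global_series(r, "nep")$value[s3])))
  }
  invisible(x)
}
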