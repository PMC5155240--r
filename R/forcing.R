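#' Nitrogen-deposition trajectory profiles
#'
#' Region-typed annual nitrogen-deposition trajectory shapes used by the
#' synthetic forcing generator:
#' \describe{
#'   \item{us_temperate_forest}{a persistently high plateau, emulating
#'     eastern US temperate forests where deposition has exceeded the
#'     critical load throughout the record.}
#'   \item{europe_forest}{a hump that peaks in the mid 1980s and declines
#'     afterwards, emulating European forests where deposition fell
#'     between 1970 and 2009 to near the critical load.}
#'   \item{asia_grassland}{an accelerating rise after 1970 built from
#'     non-negative yearly increments, emulating rapidly industrializing
#'     Chinese/Indian grassland regions; the trajectory is non-decreasing
#'     over 1970-2009 for every seed.}
#'   \item{background}{a flat low background level.}
#' }
#'
#' @param name profile name (see above).
#' @param start_level baseline deposition, g N m-2 yr-1 (profile-specific
#'   default).
#' @param noise_sd interannual noise amplitude (additive g N m-2 yr-1 for
#'   plateau/hump/background; multiplicative log-sd on yearly increments
#'   for the accelerating profile). Zero gives a deterministic trajectory.
#' @return an object of class `ndep_profile`.
#' @examples
#' ndep_profile("europe_forest")
#' @export
ndep_profile <- function(name = c("us_temperate_forest", "europe_forest",
                                  "asia_grassland", "background"),
                         start_level = NULL, noise_sd = NULL) {
  if (!is.character(name) || length(name) != 1)
    stop("profile name must be a single string")
  known <- c("us_temperate_forest", "europe_forest", "asia_grassland",
             "background")
  if (!name %in% known)
    stop("unknown N-deposition profile: '", name, "'")
  defaults <- switch(name,
    us_temperate_forest = list(start_level = 1.8,  noise_sd = 0.05),
    europe_forest       = list(start_level = 0.7,  noise_sd = 0.01,
                               peak_amp = 2.0, peak_year = 1985,
                               peak_width = 15),
    asia_grassland      = list(start_level = 0.8,  noise_sd = 0.1,
                               rise_amp = 3.2, rise_start = 1970,
                               rise_end = 2009),
    background          = list(start_level = 0.1,  noise_sd = 0.01))
  prof <- defaults
  prof$name <- name
  if (!is.null(start_level)) prof$start_level <- start_level
  if (!is.null(noise_sd)) prof$noise_sd <- noise_sd
  if (prof$start_level < 0) stop("start_level must be non-negative")
  if (prof$noise_sd < 0) stop("noise_sd must be non-negative")
  structure(prof, class = "ndep_profile")
}

# deterministic annual deposition shape (before noise), vectorized on years
ndep_shape <- function(profile, years) {
  s <- profile$start_level
  switch(profile$name,
    us_temperate_forest = rep(s, length(years)),
    background          = rep(s, length(years)),
    europe_forest       = s + profile$peak_amp *
      exp(-0.5 * ((years - profile$peak_year) / profile$peak_width)^2),
    asia_grassland      = {
      t0 <- profile$rise_start
      span <- profile$rise_end - t0
      rel <- pmax(0, pmin(years - t0, span)) / span
      s + profile$rise_amp * rel^2
    })
}

# deterministic per-substream seed: master seed fans out by site id and
# variable so adding sites or variables never perturbs existing streams
substream_seed <- function(seed, site_id, variable) {
  h <- sum(utf8ToInt(as.character(site_id)) *
             seq_along(utf8ToInt(as.character(site_id))))
  v <- sum(utf8ToInt(variable))
  (as.integer(seed) %% 100000L) * 20011L + (h %% 10007L) * 97L + v * 13L
}

# draw from a substream without disturbing the caller's RNG state
with_substream <- function(seed, site_id, variable, fun) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, site_id, variable))
  fun()
}

#' Default atmospheric CO2 trajectory
#'
#' A flat pre-industrial plateau (296 ppm) up to 1901 followed by a smooth
#' accelerating ramp reaching about 387 ppm in 2009.
#'
#' @param years integer vector of years.
#' @param co2_pre plateau concentration, ppm.
#' @param co2_end concentration reached in `end_year`, ppm.
#' @param ramp_start,end_year ramp endpoints.
#' @return numeric vector of annual CO2, ppm.
#' @export
co2_trajectory <- function(years, co2_pre = 296, co2_end = 387,
                           ramp_start = 1901, end_year = 2009) {
  rel <- pmax(0, (years - ramp_start) / (end_year - ramp_start))
  co2_pre + (co2_end - co2_pre) * rel^2
}

#' Generate seeded synthetic forcing for one site
#'
#' Produces a complete monthly climate plus annual CO2 and
#' nitrogen-deposition forcing series for one site. The climate is a
#' sinusoidal seasonal cycle around the site's mean temperature with
#' seeded AR(1) interannual anomalies, a configurable warming trend after
#' 1970, lognormal monthly precipitation noise, and bounded cloud
#' fraction, wind speed, wet days and relative humidity. The output is a
#' pure function of `(site_spec, years, profile, seed)`: the same call
#' returns bit-identical series, and per-site, per-variable random
#' substreams mean that adding sites to an ensemble never changes
#' existing ones.
#'
#' @param site_spec a list or one-row data.frame with at least `site_id`;
#'   optional climate fields `temp_mean` (deg C), `temp_amp` (seasonal
#'   half-amplitude, deg C), `precip_ann` (mm yr-1).
#' @param years integer year range within 1851-2009.
#' @param profile an [ndep_profile()].
#' @param seed integer master seed.
#' @param noise logical; `FALSE` suppresses all stochastic components
#'   (useful for deterministic tests).
#' @param trend warming trend applied after 1970, deg C yr-1.
#' @return an object of class `forcing_series` with monthly matrices
#'   (years x 12) `temperature`, `precipitation`, `cloud_fraction`,
#'   `wind_speed`, `wet_days`, `relative_humidity`, and annual vectors
#'   `co2` and `n_deposition`.
#' @examples
#' site <- list(site_id = "demo", temp_mean = 9, temp_amp = 10,
#'              precip_ann = 1000)
#' f <- generate_forcing(site, 1970:2009, ndep_profile("background"), seed = 1)
#' range(f$n_deposition)
#' @export
generate_forcing <- function(site_spec, years, profile, seed,
                             noise = TRUE, trend = 0.02) {
  if (is.data.frame(site_spec)) site_spec <- as.list(site_spec[1, ])
  if (is.null(site_spec$site_id)) stop("site_spec must contain a site_id")
  if (!inherits(profile, "ndep_profile"))
    stop("profile must be an ndep_profile object")
  years <- as.integer(years)
  if (length(years) == 0) stop("empty year range")
  if (any(years < 1851) || any(years > 2009))
    stop("years must lie within 1851-2009")
  if (any(diff(years) != 1)) stop("years must be contiguous")
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed))
    stop("seed must be a single integer")
  id <- site_spec$site_id
  tm <- site_spec$temp_mean %||% 10
  ta <- site_spec$temp_amp %||% 10
  pa <- site_spec$precip_ann %||% 900
  ny <- length(years)
  months <- 1:12
  seasonal <- cos(2 * pi * (months - 7) / 12) * -1  # peak in July (NH)

  # interannual temperature anomaly: AR(1), sd 0.6, rho 0.3, trend post-1970
  anom <- numeric(ny)
  if (noise) {
    z <- with_substream(seed, id, "temp_anom", function() stats::rnorm(ny))
    sd_i <- 0.6 * sqrt(1 - 0.3^2)
    for (i in seq_len(ny))
      anom[i] <- if (i == 1) z[1] * 0.6 else 0.3 * anom[i - 1] + sd_i * z[i]
  }
  warming <- pmax(0, years - 1970) * trend
  mnoise <- if (noise)
    with_substream(seed, id, "temp_month",
                   function() matrix(stats::rnorm(ny * 12, sd = 0.3), ny, 12))
  else matrix(0, ny, 12)
  temperature <- matrix(tm + ta * rep(seasonal, each = ny), ny, 12) +
    (anom + warming) + mnoise
  dimnames(temperature) <- list(years, month.abb)

  # precipitation: mild summer maximum, lognormal monthly noise
  pshape <- 1 + 0.3 * seasonal
  pmean <- pa / 12 * pshape / mean(pshape)
  pn <- if (noise)
    with_substream(seed, id, "precip",
                   function() matrix(stats::rnorm(ny * 12, sd = 0.25), ny, 12))
  else matrix(0, ny, 12)
  precipitation <- matrix(rep(pmean, each = ny), ny, 12) *
    exp(pn - 0.5 * 0.25^2 * noise)
  dimnames(precipitation) <- list(years, month.abb)

  bounded <- function(var, center, sd, lo, hi) {
    n <- if (noise)
      with_substream(seed, id, var,
                     function() matrix(stats::rnorm(ny * 12, sd = sd), ny, 12))
    else matrix(0, ny, 12)
    m <- pmin(pmax(center + n, lo), hi)
    dimnames(m) <- list(years, month.abb)
    m
  }
  cloud_fraction <- bounded("cloud", 0.55, 0.08, 0, 1)
  relative_humidity <- bounded("rh", 72, 4, 0, 100)
  wet_days <- bounded("wetdays", 10 + 4 * rep(seasonal, each = ny), 1.5, 0, 31)
  wn <- if (noise)
    with_substream(seed, id, "wind",
                   function() matrix(stats::rnorm(ny * 12, sd = 0.2), ny, 12))
  else matrix(0, ny, 12)
  wind_speed <- 3.2 * exp(wn - 0.5 * 0.2^2 * noise)
  dimnames(wind_speed) <- list(years, month.abb)

  co2 <- co2_trajectory(years)
  names(co2) <- years

  # nitrogen deposition
  shape <- ndep_shape(profile, years)
  if (profile$name == "asia_grassland") {
    inc <- c(shape[1], diff(shape))
    if (noise && profile$noise_sd > 0) {
      e <- with_substream(seed, id, "ndep",
                          function() stats::rnorm(ny, sd = profile$noise_sd))
      inc[-1] <- inc[-1] * exp(e[-1] - 0.5 * profile$noise_sd^2)
    }
    n_deposition <- cumsum(inc)
  } else {
    e <- if (noise && profile$noise_sd > 0)
      with_substream(seed, id, "ndep",
                     function() stats::rnorm(ny, sd = profile$noise_sd))
    else numeric(ny)
    n_deposition <- pmax(0, shape + e)
  }
  names(n_deposition) <- years

  structure(list(site_id = id, years = years,
                 temperature = temperature, precipitation = precipitation,
                 cloud_fraction = cloud_fraction, wind_speed = wind_speed,
                 wet_days = wet_days, relative_humidity = relative_humidity,
                 co2 = co2, n_deposition = n_deposition,
                 profile = profile$name, seed = as.integer(seed)),
            class = "forcing_series")
}

#' Collapse a forcing series to a repeating climatology
#'
#' Each calendar month of the output equals the multi-year mean of that
#' month in the input (optionally restricted to a window of years); CO2 is
#' held at the series' first-year value and nitrogen deposition at its
#' climatological mean (simulation protocols typically override deposition
#' with a prescribed baseline). The output spans the same years as the
#' input, every year identical, so it can drive a spin-up directly.
#'
#' @param forcing a `forcing_series`.
#' @param window optional integer years to average over (default: all).
#' @return a `forcing_series` of repeated climatological years.
#' @export
spinup_climatology <- function(forcing, window = NULL) {
  stopifnot(inherits(forcing, "forcing_series"))
  yrs <- forcing$years
  if (is.null(window)) window <- yrs
  keep <- yrs %in% window
  if (!any(keep)) stop("climatology window does not overlap series years")
  out <- forcing
  ny <- length(yrs)
  for (v in c("temperature", "precipitation", "cloud_fraction",
              "wind_speed", "wet_days", "relative_humidity")) {
    mo <- colMeans(forcing[[v]][keep, , drop = FALSE])
    out[[v]] <- matrix(rep(mo, each = ny), ny, 12,
                       dimnames = list(yrs, month.abb))
  }
  out$co2 <- stats::setNames(rep(forcing$co2[1], ny), yrs)
  out$n_deposition <- stats::setNames(rep(mean(forcing$n_deposition[keep]), ny),
                                      yrs)
  out
}

#' Freeze one driver of a forcing series at a given year
#'
#' Replaces the named driver's values with its `freeze_year` values for
#' every year at or after `freeze_year`, leaving all other drivers and all
#' earlier years untouched. This implements the single-driver-held-constant
#' construction of factorial attribution experiments.
#'
#' @param forcing a `forcing_series`.
#' @param driver one of `"temperature"`, `"precipitation"`, `"co2"`,
#'   `"n_deposition"`.
#' @param freeze_year year whose values are repeated (default 1970).
#' @return the modified `forcing_series`.
#' @examples
#' site <- list(site_id = "s", temp_mean = 9)
#' f <- generate_forcing(site, 1960:2009, ndep_profile("asia_grassland"), 1)
#' f2 <- freeze_driver(f, "n_deposition", 1970)
#' stopifnot(all(f2$n_deposition[as.character(1970:2009)] ==
#'               f$n_deposition["1970"]))
#' @export
freeze_driver <- function(forcing, driver, freeze_year = 1970) {
  stopifnot(inherits(forcing, "forcing_series"))
  known <- c("temperature", "precipitation", "co2", "n_deposition")
  if (!is.character(driver) || length(driver) != 1 || !driver %in% known)
    stop("unknown driver: must be one of ",
         paste(known, collapse = ", "))
  yrs <- forcing$years
  if (!freeze_year %in% yrs) stop("freeze_year outside the series range")
  i0 <- match(freeze_year, yrs)
  later <- which(yrs >= freeze_year)
  if (driver %in% c("temperature", "precipitation")) {
    forcing[[driver]][later, ] <- matrix(rep(forcing[[driver]][i0, ],
                                             each = length(later)),
                                         length(later), 12)
  } else {
    forcing[[driver]][later] <- forcing[[driver]][i0]
  }
  forcing
}

# annual drivers used by the (annual-step) carbon-nitrogen core
annual_drivers <- function(forcing) {
  data.frame(year = forcing$years,
             temperature = rowMeans(forcing$temperature),
             precipitation = rowSums(forcing$precipitation),
             co2 = as.numeric(forcing$co2),
             n_deposition = as.numeric(forcing$n_deposition))
}

#' @export
print.forcing_series <- function(x, ...) {
  cat(sprintf("Synthetic forcing series for site '%s'\n", x$site_id))
  cat(sprintf("  years     : %d-%d (%d)\n", min(x$years), max(x$years),
              length(x$years)))
  cat(sprintf("  MAT       : %.1f degC   MAP: %.0f mm yr-1\n",
              mean(x$temperature), mean(rowSums(x$precipitation))))
  cat(sprintf("  CO2       : %.1f -> %.1f ppm\n", x$co2[1],
              x$co2[length(x$co2)]))
  cat(sprintf("  N dep     : %.2f -> %.2f g N m-2 yr-1 (profile %s)\n",
              x$n_deposition[1], x$n_deposition[length(x$n_deposition)],
              x$profile %||% "?"))
  invisible(x)
}

#' Convert a forcing series to tidy data frames
#'
#' @param x a `forcing_series`.
#' @param which `"climate"` for one row per site-year-month, `"annual"`
#'   for one row per site-year (CO2 and N deposition).
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.forcing_series <- function(x, ..., which = c("climate",
                                                           "annual")) {
  which <- match.arg(which)
  if (which == "annual") {
    return(data.frame(site_id = x$site_id, year = x$years,
                      co2 = as.numeric(x$co2),
                      n_deposition = as.numeric(x$n_deposition)))
  }
  ny <- length(x$years)
  data.frame(site_id = x$site_id,
             year = rep(x$years, times = 12),
             month = rep(1:12, each = ny),
             temperature = as.vector(x$temperature),
             precipitation = as.vector(x$precipitation),
             cloud_fraction = as.vector(x$cloud_fraction),
             wind_speed = as.vector(x$wind_speed),
             wet_days = as.vector(x$wet_days),
             relative_humidity = as.vector(x$relative_humidity))
}

#' Write / read forcing as tidy CSV
#'
#' The climate file holds one row per site-year-month; the annual file one
#' row per site-year with CO2 and nitrogen deposition.
#'
#' @param forcing a `forcing_series`.
#' @param climate_file,annual_file output/input paths.
#' @return `read_forcing_csv` returns a `forcing_series`.
#' @export
write_forcing_csv <- function(forcing, climate_file, annual_file) {
  utils::write.csv(as.data.frame(forcing, which = "climate"), climate_file,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(forcing, which = "annual"), annual_file,
                   row.names = FALSE)
  invisible(forcing)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(climate_file, annual_file) {
  cl <- utils::read.csv(climate_file, stringsAsFactors = FALSE)
  an <- utils::read.csv(annual_file, stringsAsFactors = FALSE)
  yrs <- sort(unique(cl$year))
  ny <- length(yrs)
  grab <- function(v) {
    m <- matrix(NA_real_, ny, 12, dimnames = list(yrs, month.abb))
    m[cbind(match(cl$year, yrs), cl$month)] <- cl[[v]]
    m
  }
  an <- an[order(an$year), ]
  structure(list(site_id = cl$site_id[1], years = as.integer(yrs),
                 temperature = grab("temperature"),
                 precipitation = grab("precipitation"),
                 cloud_fraction = grab("cloud_fraction"),
                 wind_speed = grab("wind_speed"),
                 wet_days = grab("wet_days"),
                 relative_humidity = grab("relative_humidity"),
                 co2 = stats::setNames(an$co2, an$year),
                 n_deposition = stats::setNames(an$n_deposition, an$year)),
            class = "forcing_series")
}

# invariant checks used by tests and on read
validate_forcing <- function(x) {
  stopifnot(inherits(x, "forcing_series"))
  ok <- all(diff(x$years) == 1) &&
    all(x$precipitation >= 0) && all(x$wet_days >= 0) &&
    all(x$n_deposition >= 0) && all(x$co2 >= 0) &&
    all(x$cloud_fraction >= 0 & x$cloud_fraction <= 1) &&
    all(x$relative_humidity >= 0 & x$relative_humidity <= 100) &&
    all(vapply(list(x$temperature, x$precipitation, x$co2, x$n_deposition),
               function(v) length(v) > 0, logical(1)))
  if (!ok) stop("forcing series violates physical bounds or continuity")
  invisible(TRUE)
}
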