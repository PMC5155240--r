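#' Nitrogen pool state
#'
#' @param soil_mineral_n,soil_organic_n,plant_n pools in g N m-2 (>= 0).
#' @return named numeric vector of class `n_pool_state`.
#' @export
n_pool_state <- function(soil_mineral_n = 0.5, soil_organic_n = 100,
                         plant_n = 5) {
  v <- c(soil_mineral_n = soil_mineral_n, soil_organic_n = soil_organic_n,
         plant_n = plant_n)
  if (any(!is.finite(v)) || any(v < 0))
    stop("nitrogen pools must be finite and non-negative")
  structure(v, class = "n_pool_state")
}

#' Advance the nitrogen pools by one step
#'
#' Book-keeping update of the three nitrogen pools from a record of
#' non-negative fluxes:
#' mineral N gains deposition and mineralization and loses immobilization,
#' plant uptake and leaching; organic N gains immobilization and loses
#' mineralization; plant N gains uptake. Total nitrogen therefore changes
#' by exactly `(deposition - leaching) * dt` when no clipping occurs. A
#' pool that would go negative is clipped at zero and the clipped deficit
#' recorded in the `"clipped"` attribute of the result (never fatal).
#'
#' @param state an [n_pool_state()] (or named vector with the same names).
#' @param fluxes named list/vector with `deposition`, `mineralization`,
#'   `immobilization`, `plant_uptake`, `leaching`, all g N m-2 yr-1, >= 0.
#' @param dt time step in years (> 0).
#' @return updated `n_pool_state`; attribute `clipped` gives the total
#'   clipped deficit (0 when mass balance is exact).
#' @examples
#' s <- n_pool_state(1, 100, 5)
#' step_n_pools(s, list(deposition = 1, mineralization = 0,
#'                      immobilization = 0, plant_uptake = 0, leaching = 0))
#' @export
step_n_pools <- function(state, fluxes, dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  fx <- unlist(fluxes)
  need <- c("deposition", "mineralization", "immobilization",
            "plant_uptake", "leaching")
  if (!all(need %in% names(fx)))
    stop("fluxes must include ", paste(need, collapse = ", "))
  if (any(fx[need] < 0)) stop("fluxes must be non-negative")
  s <- unclass(state)
  s["soil_mineral_n"] <- s["soil_mineral_n"] +
    (fx["deposition"] + fx["mineralization"] - fx["immobilization"] -
       fx["plant_uptake"] - fx["leaching"]) * dt
  s["soil_organic_n"] <- s["soil_organic_n"] +
    (fx["immobilization"] - fx["mineralization"]) * dt
  s["plant_n"] <- s["plant_n"] + fx["plant_uptake"] * dt
  clipped <- sum(pmin(s, 0))
  s <- pmax(s, 0)
  structure(s, class = "n_pool_state", clipped = -clipped)
}
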