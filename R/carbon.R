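#' Ecosystem state vector
#'
#' Carbon pools (leaf, wood, root, litter, soil organic carbon; g C m-2)
#' and nitrogen pools (soil mineral N, soil organic N, plant N; g N m-2)
#' of the point-scale model.
#'
#' @param leaf,wood,root,litter,soc carbon pools, g C m-2.
#' @param n_mineral,n_organic,n_plant nitrogen pools, g N m-2.
#' @return named numeric vector of class `ecosystem_state`.
#' @export
ecosystem_state <- function(leaf = 10, wood = 100, root = 10,
                            litter = 50, soc = 1000,
                            n_mineral = 0.5, n_organic = 100, n_plant = 5) {
  v <- c(leaf = leaf, wood = wood, root = root, litter = litter, soc = soc,
         n_mineral = n_mineral, n_organic = n_organic, n_plant = n_plant)
  if (any(!is.finite(v)) || any(v < 0))
    stop("ecosystem state must be finite and non-negative")
  structure(v, class = "ecosystem_state")
}

c_pool_names <- c("leaf", "wood", "root", "litter", "soc")

#' Potential net primary productivity
#'
#' Climate- and CO2-responsive potential NPP before nitrogen control:
#' \deqn{NPP_{pot} = NPP_{ref} \; f_T(T) \; f_W(P) \; f_C(CO_2)}
#' with an exponential temperature response
#' \eqn{f_T = e^{k_T (T - T_{ref})}}, a saturating moisture response
#' \eqn{f_W = \frac{P/(P + P_{1/2})}{P_{ref}/(P_{ref} + P_{1/2})}} and a
#' logarithmic CO2 fertilization (beta-factor) response
#' \eqn{f_C = 1 + \beta \ln(CO_2 / CO_{2,ref})}, floored at a small
#' positive value. All three factors equal 1 at the reference climate and
#' reference CO2, so `npp_ref` is recovered there.
#'
#' @param annual_forcing list with `temperature` (annual mean, deg C) and
#'   `precipitation` (annual total, mm).
#' @param co2 atmospheric CO2, ppm (> 0).
#' @param params parameter list from [nsat_params()] (uses `npp_ref`,
#'   `t_ref`, `k_t`, `p_ref`, `p_half`, `co2_ref`, `beta_co2`).
#' @return potential NPP, g C m-2 yr-1.
#' @examples
#' p <- nsat_params()
#' npp_potential(list(temperature = 15, precipitation = 1000), 296, p)
#' @export
npp_potential <- function(annual_forcing, co2, params = nsat_params()) {
  if (any(co2 <= 0)) stop("co2 must be positive")
  t <- annual_forcing$temperature
  pr <- annual_forcing$precipitation
  f_t <- exp(params$k_t * (t - params$t_ref))
  f_w <- (pr / (pr + params$p_half)) /
    (params$p_ref / (params$p_ref + params$p_half))
  f_c <- pmax(1 + params$beta_co2 * log(co2 / params$co2_ref), 0.05)
  params$npp_ref * f_t * f_w * f_c
}

#' Realized NPP under nitrogen control
#'
#' Linear scaling of potential NPP by the plant-production modifier
#' \eqn{K_P}, so that the modifier floor maps exactly onto the
#' parameterized maximum saturation effect (a floor of 0.824 gives a
#' 17.6% NPP reduction).
#'
#' @param npp_pot potential NPP, g C m-2 yr-1.
#' @param kp production modifier in (0, 1].
#' @return realized NPP, g C m-2 yr-1.
#' @export
realized_npp <- function(npp_pot, kp) {
  if (any(kp <= 0) || any(kp > 1)) stop("kp must lie in (0, 1]")
  npp_pot * kp
}

#' Allocate NPP to leaf, wood and root
#'
#' Base allocation fractions are shifted towards aboveground tissue as
#' nitrogen saturation develops: at full saturation the leaf, wood and
#' root fractions are multiplied by 1.10, 1.25 and 0.65 (i.e. +10%, +25%,
#' -35%) before renormalization; the effective multiplier interpolates
#' linearly with `saturation_degree` between 1 and those endpoints. The
#' returned fluxes always sum to `npp` exactly.
#'
#' @param npp realized NPP, g C m-2 yr-1 (>= 0).
#' @param alloc_base named fractions `c(leaf=, wood=, root=)` summing to 1.
#' @param alloc_mult full-saturation multipliers (defaults
#'   `c(leaf = 1.10, wood = 1.25, root = 0.65)`).
#' @param saturation_degree in `[0, 1]`; 0 below the saturation threshold,
#'   rising linearly to 1 at the maximum available mineral N.
#' @return named vector `c(leaf=, wood=, root=)` summing to `npp`.
#' @examples
#' allocate_npp(900, c(leaf = 1, wood = 1, root = 1) / 3,
#'              saturation_degree = 1)
#' @export
allocate_npp <- function(npp, alloc_base,
                         alloc_mult = c(leaf = 1.10, wood = 1.25,
                                        root = 0.65),
                         saturation_degree = 0) {
  if (npp < 0) stop("npp must be non-negative")
  if (abs(sum(alloc_base) - 1) > 1e-8)
    stop("base allocation fractions must sum to 1")
  if (any(alloc_base <= 0) || any(alloc_base >= 1))
    stop("base allocation fractions must lie in (0, 1)")
  s <- saturation_degree
  if (s < 0 || s > 1) stop("saturation_degree must lie in [0, 1]")
  ord <- c("leaf", "wood", "root")
  m <- 1 + s * (alloc_mult[ord] - 1)
  raw <- alloc_base[ord] * m
  frac <- raw / sum(raw)
  stats::setNames(npp * as.numeric(frac), ord)
}

# temperature / moisture scalars shared by decomposition
climate_scalars <- function(temperature, precipitation,
                            params = nsat_params()) {
  list(g_t = params$q10^((temperature - params$t_ref) / 10),
       g_w = (precipitation / (precipitation + params$p_half)) /
         (params$p_ref / (params$p_ref + params$p_half)))
}

#' Decomposition of litter and soil organic carbon
#'
#' First-order decay of the litter and SOC pools with base rate constants
#' scaled by temperature (Q10) and moisture scalars and by the
#' mineralization modifier \eqn{K_M}; the fraction `humify` of decomposed
#' litter carbon is transferred to SOC and the remainder, plus all SOC
#' decay, is respired heterotrophically. Because every respired term is
#' proportional to \eqn{K_M}, the modifier floor translates exactly into
#' the parameterized decomposition reduction (0.85 gives -15% Rh for an
#' identical state). Nitrogen mineralization follows decomposed organic
#' carbon at the current organic-pool N:C ratio, and immobilization is
#' the nitrogen demand of humification (humified C over the SOC C:N
#' ratio) scaled by \eqn{K_1}.
#'
#' Annual fractional losses are capped at `max_decay` to keep pools
#' non-negative under extreme climate scalars; within the cap all
#' respiration terms remain strictly linear in \eqn{K_M}.
#'
#' @param state an [ecosystem_state()].
#' @param km,k1 mineralization and immobilization modifiers in (0, 1].
#' @param scalars list with `g_t`, `g_w` (see defaults of 1 for reference
#'   climate).
#' @param params parameter list from [nsat_params()].
#' @return list with `rh` (g C m-2 yr-1), `mineralized_n`,
#'   `immobilized_n` (g N m-2 yr-1), plus component fluxes
#'   `litter_decomp`, `soc_decomp`, `humified_c`.
#' @export
decompose_pools <- function(state, km, k1,
                            scalars = list(g_t = 1, g_w = 1),
                            params = nsat_params()) {
  if (any(c(km, k1) <= 0) || any(c(km, k1) > 1))
    stop("km and k1 must lie in (0, 1]")
  g <- scalars$g_t * scalars$g_w
  litter_rate <- min(params$k_litter * g * km, params$max_decay)
  soc_rate <- min(params$k_soc * g * km, params$max_decay)
  litter_decomp <- litter_rate * state[["litter"]]
  soc_decomp <- soc_rate * state[["soc"]]
  humified <- params$humify * litter_decomp
  rh <- (litter_decomp - humified) + soc_decomp
  org_c <- state[["litter"]] + state[["soc"]]
  q <- if (org_c > 0) state[["n_organic"]] / org_c else 0
  mineralized <- rh * q
  immobilized <- k1 * humified / params$cn[["soc"]]
  list(rh = rh, mineralized_n = mineralized, immobilized_n = immobilized,
       litter_decomp = litter_decomp, soc_decomp = soc_decomp,
       humified_c = humified)
}

#' One coupled annual step of the carbon-nitrogen model
#'
#' Order of operations within a year: nitrogen-control modifiers are
#' evaluated at the current soil mineral N; potential NPP is computed from
#' the year's climate and CO2 and scaled by \eqn{K_P}; NPP is allocated
#' (with the saturation-dependent shift); litterfall removes tissue at
#' fixed turnover rates; litter and SOC decompose under \eqn{K_M} and
#' \eqn{K_1}; and the nitrogen pools are updated from deposition,
#' mineralization, immobilization, plant uptake (demand set by new-tissue
#' C:N ratios, limited by available mineral N) and first-order leaching.
#' Carbon is conserved exactly: the change in total carbon equals
#' NPP - Rh each step, and NEP is recorded as NPP - Rh.
#'
#' @param state an [ecosystem_state()].
#' @param forcing_year list (or one-row data.frame) with `temperature`
#'   (annual mean, deg C), `precipitation` (annual total, mm), `co2`
#'   (ppm), `n_deposition` (g N m-2 yr-1).
#' @param params parameter list from [nsat_params()]; must contain
#'   `alloc_base` (added by the protocol from [veg_params()], or supply
#'   your own).
#' @param curve a [modifier_curve()]; may be `NULL` when
#'   `pin_modifiers = TRUE`.
#' @param mode `"saturation"` or `"legacy"` modifier mode.
#' @param pin_modifiers if `TRUE` all three modifiers are fixed at 1
#'   (used in the no-saturation scenario and in threshold derivation).
#' @param n_m_override optional mineral-N value at which to evaluate the
#'   modifiers instead of the state's pool (diagnostic use).
#' @return list with `state` (updated), `cflux` (gpp, npp, rh, nep,
#'   litterfall per pool), `nflux` (deposition, mineralization,
#'   immobilization, plant_uptake, leaching), `modifiers` (kp, k1, km),
#'   `saturation_degree` and `clipped` (logged clipping deficit).
#' @export
step_year <- function(state, forcing_year, params, curve = NULL,
                      mode = c("saturation", "legacy"),
                      pin_modifiers = FALSE, n_m_override = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(unclass(state))))
    stop("non-finite ecosystem state: ",
         paste(sprintf("%s=%g", names(state), state), collapse = ", "))
  if (is.data.frame(forcing_year)) forcing_year <- as.list(forcing_year[1, ])
  if (is.null(params$alloc_base))
    params$alloc_base <- c(leaf = 1, wood = 1, root = 1) / 3
  if (!pin_modifiers && is.null(curve))
    stop("a modifier_curve is required unless modifiers are pinned")

  npp_pot <- npp_potential(forcing_year, forcing_year$co2, params)
  sc <- climate_scalars(forcing_year$temperature, forcing_year$precipitation,
                        params)
  cn <- params$cn
  dep <- forcing_year$n_deposition
  g <- sc$g_t * sc$g_w
  litter_rate <- min(params$k_litter * g, params$max_decay)
  soc_rate <- min(params$k_soc * g, params$max_decay)
  org_c <- state[["litter"]] + state[["soc"]]
  q <- if (org_c > 0) state[["n_organic"]] / org_c else 0

  # The mineral-nitrogen pool is fast and its controls are steep, so the
  # mineral pool, the modifiers and plant uptake are integrated on a
  # monthly substep inside the annual carbon step; carbon pools and the
  # organic/plant nitrogen pools are held at their start-of-year values
  # within the substep loop. Decomposition and NPP accumulate with the
  # substep modifiers, which keeps every respired term linear in the
  # mineralization modifier.
  nsub <- 12L
  dtm <- 1 / nsub
  n_m <- state[["n_mineral"]]
  npp <- rh_tot <- min_tot <- imm_tot <- upt_tot <- leach_tot <- 0
  humif_tot <- litter_tot <- soc_tot <- 0
  alloc <- c(leaf = 0, wood = 0, root = 0)
  kp_bar <- k1_bar <- km_bar <- sat_bar <- 0
  clipped <- 0
  for (m in seq_len(nsub)) {
    n_m_eff <- n_m_override %||% n_m
    if (pin_modifiers) {
      kp <- k1 <- km <- 1
      sat_deg <- 0
    } else {
      kp <- modifier_kp(n_m_eff, curve, mode)
      k1 <- modifier_k1(n_m_eff, curve, mode)
      km <- modifier_km(n_m_eff, curve, mode)
      sat_deg <- if (mode == "saturation")
        min(max((n_m_eff - curve$n_ms) / (curve$n_mmax - curve$n_ms), 0), 1)
      else 0
    }
    npp_m <- realized_npp(npp_pot, kp) * dtm
    alloc_m <- allocate_npp(npp_m, params$alloc_base, params$alloc_mult,
                            sat_deg)
    litter_m <- min(litter_rate * km, params$max_decay) *
      state[["litter"]] * dtm
    soc_m <- min(soc_rate * km, params$max_decay) * state[["soc"]] * dtm
    humif_m <- params$humify * litter_m
    rh_m <- (litter_m - humif_m) + soc_m
    min_m <- rh_m * q
    imm_m <- k1 * humif_m / cn[["soc"]]
    leach_m <- params$k_leach * n_m * dtm
    demand_m <- alloc_m[["leaf"]] / cn[["leaf"]] +
      alloc_m[["wood"]] / cn[["wood"]] + alloc_m[["root"]] / cn[["root"]]
    avail_m <- n_m + dep * dtm + min_m - imm_m - leach_m
    upt_m <- min(demand_m, max(0, params$uptake_cap * avail_m))
    n_m_new <- avail_m - upt_m
    if (n_m_new < 0) {
      clipped <- clipped - n_m_new
      n_m_new <- 0
    }
    n_m <- n_m_new
    npp <- npp + npp_m
    alloc <- alloc + alloc_m
    rh_tot <- rh_tot + rh_m
    litter_tot <- litter_tot + litter_m
    soc_tot <- soc_tot + soc_m
    humif_tot <- humif_tot + humif_m
    min_tot <- min_tot + min_m
    imm_tot <- imm_tot + imm_m
    upt_tot <- upt_tot + upt_m
    leach_tot <- leach_tot + leach_m
    kp_bar <- kp_bar + kp / nsub
    k1_bar <- k1_bar + k1 / nsub
    km_bar <- km_bar + km / nsub
    sat_bar <- sat_bar + sat_deg / nsub
  }
  kp <- kp_bar; k1 <- k1_bar; km <- km_bar; sat_deg <- sat_bar
  dec <- list(rh = rh_tot, mineralized_n = min_tot, immobilized_n = imm_tot,
              litter_decomp = litter_tot, soc_decomp = soc_tot,
              humified_c = humif_tot)

  tv <- params$turnover
  falls <- c(leaf = tv[["leaf"]] * state[["leaf"]],
             wood = tv[["wood"]] * state[["wood"]],
             root = tv[["root"]] * state[["root"]])

  new_c <- c(
    leaf = state[["leaf"]] + (alloc[["leaf"]] - falls[["leaf"]]),
    wood = state[["wood"]] + (alloc[["wood"]] - falls[["wood"]]),
    root = state[["root"]] + (alloc[["root"]] - falls[["root"]]),
    litter = state[["litter"]] + (sum(falls) - dec$litter_decomp),
    soc = state[["soc"]] + (dec$humified_c - dec$soc_decomp))

  nflux <- list(deposition = dep, mineralization = dec$mineralized_n,
                immobilization = dec$immobilized_n, plant_uptake = upt_tot,
                leaching = leach_tot)
  ns <- step_n_pools(n_pool_state(state[["n_mineral"]],
                                  state[["n_organic"]],
                                  state[["n_plant"]]),
                     nflux, 1)
  clipped <- clipped + attr(ns, "clipped")
  # the substepped mineral trajectory is authoritative (identical to the
  # aggregate bookkeeping unless clipping occurred within a substep)
  ns[["soil_mineral_n"]] <- n_m
  dt <- 1

  # internal plant -> soil organic transfer of litterfall nitrogen
  litterfall_n <- falls[["leaf"]] / cn[["leaf"]] +
    falls[["wood"]] / cn[["wood"]] + falls[["root"]] / cn[["root"]]
  transfer <- min(litterfall_n * dt, ns[["plant_n"]])
  clipped <- clipped + (litterfall_n * dt - transfer)
  ns[["plant_n"]] <- ns[["plant_n"]] - transfer
  ns[["soil_organic_n"]] <- ns[["soil_organic_n"]] + transfer

  new_state <- structure(
    c(new_c, n_mineral = ns[["soil_mineral_n"]],
      n_organic = ns[["soil_organic_n"]], n_plant = ns[["plant_n"]]),
    class = "ecosystem_state")

  cflux <- list(gpp = npp / params$npp_gpp_ratio, npp = npp, rh = dec$rh,
                nep = npp - dec$rh,
                litterfall_leaf = falls[["leaf"]],
                litterfall_wood = falls[["wood"]],
                litterfall_root = falls[["root"]],
                litter_decomp = dec$litter_decomp,
                soc_decomp = dec$soc_decomp,
                humified_c = dec$humified_c)

  list(state = new_state, cflux = cflux, nflux = nflux, alloc = alloc,
       modifiers = c(kp = kp, k1 = k1, km = km),
       saturation_degree = sat_deg, clipped = clipped)
}

#' Run the model to equilibrium under constant drivers
#'
#' Repeats [step_year()] under fixed annual drivers until either the net
#' ecosystem productivity stays within a tolerance for a run of
#' consecutive years (`criterion = "nep"`, the spin-up convention) or the
#' relative change of every pool falls below a tolerance
#' (`criterion = "pools"`, used when deriving the saturation threshold).
#'
#' @param state starting [ecosystem_state()].
#' @param drivers list with `temperature`, `precipitation`, `co2`,
#'   `n_deposition` held constant.
#' @param params parameter list.
#' @param curve [modifier_curve()] or `NULL` with `pin_modifiers = TRUE`.
#' @param mode modifier mode.
#' @param pin_modifiers fix all modifiers at 1.
#' @param criterion `"nep"` or `"pools"`.
#' @param tol tolerance: g C m-2 yr-1 on |NEP|, or relative pool change.
#' @param max_years iteration cap; exceeding it is an error reporting the
#'   final residual.
#' @param consec consecutive years required under the NEP criterion.
#' @param accelerate use semi-analytic equilibrium acceleration: at a few
#'   fixed early years the slow pools (tissue carbon, litter, SOC, organic
#'   and plant nitrogen) are jumped to the steady state implied by the
#'   current fluxes, after which normal integration resumes. The jumps
#'   leave the model's fixed point unchanged; convergence is only declared
#'   from ordinary integration years.
#' @return list with `state`, `years` used, `nep` (final), `residual`
#'   (final max relative pool change), `converged`.
#' @export
run_to_equilibrium <- function(state, drivers, params, curve = NULL,
                               mode = "saturation", pin_modifiers = FALSE,
                               criterion = c("nep", "pools"),
                               tol = NULL, max_years = NULL, consec = NULL,
                               accelerate = TRUE) {
  criterion <- match.arg(criterion)
  if (is.null(tol))
    tol <- if (criterion == "nep") params$spinup$nep_tol else params$equil$tol
  if (is.null(max_years))
    max_years <- if (criterion == "nep") params$spinup$max_years
                 else params$equil$max_years
  if (is.null(consec)) consec <- params$spinup$nep_years %||% 10
  # acceleration is used for the NEP spin-up only: the pinned-modifier
  # pools criterion converges rapidly on its own, and post-jump states can
  # sit on tiny uptake-switching cycles that the strict residual rejects
  accel_at <- if (accelerate && criterion == "nep")
    c(100, 250, 450, 700, 1000, 1400, 1900, 2500, 3200, 4000, 5000, 6000,
      7500)
  else integer(0)
  streak <- 0
  nep <- NA_real_
  residual <- Inf
  for (yr in seq_len(max_years)) {
    prev <- unclass(state)
    res <- step_year(state, drivers, params, curve, mode, pin_modifiers)
    state <- res$state
    nep <- res$cflux$nep
    residual <- max(abs(unclass(state) - prev) / (1 + abs(prev)))
    if (yr %in% accel_at) {
      state <- accelerate_state(state, res, params)
      streak <- 0
      residual <- Inf
      next
    }
    if (criterion == "nep") {
      # a small |NEP| alone can occur transiently at an NEP zero-crossing
      # far from equilibrium, so the streak also requires near-stationary
      # pools
      ok <- abs(nep) < tol && residual < params$spinup$residual_tol %||% 1e-4
      streak <- if (ok) streak + 1 else 0
      if (streak >= consec)
        return(list(state = state, years = yr, nep = nep,
                    residual = residual, converged = TRUE))
    } else {
      if (residual < tol)
        return(list(state = state, years = yr, nep = nep,
                    residual = residual, converged = TRUE))
    }
  }
  stop(sprintf(
    "equilibrium not reached in %d years (criterion %s, tol %g): final NEP %.4g, max relative pool change %.4g",
    max_years, criterion, tol, nep, residual))
}

# semi-analytic equilibrium jump: set slow pools to the steady state
# implied by the most recent annual fluxes (pool = input / effective
# first-order rate), keeping the fast mineral pool untouched; invalid
# targets (zero rates, non-finite) leave the pool unchanged
accelerate_state <- function(state, res, params) {
  s <- unclass(state)
  tv <- params$turnover
  cn <- params$cn
  al <- res$alloc
  npp <- res$cflux$npp
  tgt <- function(input, pool, outflux) {
    if (!is.finite(input) || !is.finite(outflux) || outflux <= 0 ||
        pool <= 0) return(NA_real_)
    input * pool / outflux
  }
  new <- c(
    leaf = if (tv[["leaf"]] > 0) al[["leaf"]] / tv[["leaf"]] else NA,
    wood = if (tv[["wood"]] > 0) al[["wood"]] / tv[["wood"]] else NA,
    root = if (tv[["root"]] > 0) al[["root"]] / tv[["root"]] else NA,
    litter = tgt(npp, s[["litter"]], res$cflux$litter_decomp),
    soc = tgt(params$humify * npp, s[["soc"]], res$cflux$soc_decomp))
  new["n_plant"] <- new[["leaf"]] / cn[["leaf"]] +
    new[["wood"]] / cn[["wood"]] + new[["root"]] / cn[["root"]]
  litterfall_n_eq <- al[["leaf"]] / cn[["leaf"]] +
    al[["wood"]] / cn[["wood"]] + al[["root"]] / cn[["root"]]
  new["n_organic"] <- tgt(litterfall_n_eq + res$nflux$immobilization,
                          s[["n_organic"]], res$nflux$mineralization)
  ok <- names(new)[is.finite(new) & new >= 0]
  s[ok] <- new[ok]
  structure(s, class = "ecosystem_state")
}

#' @export
print.ecosystem_state <- function(x, ...) {
  cat("Ecosystem state (g C m-2 / g N m-2)\n")
  print(round(unclass(x), 3))
  invisible(x)
}
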