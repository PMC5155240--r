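#' Default model parameters
#'
#' Returns the full parameter list used by the carbon-nitrogen core. All
#' values are per square metre and per year unless stated otherwise. The
#' defaults describe a generic mid-latitude ecosystem; vegetation-specific
#' values (reference NPP, allocation fractions) come from [veg_params()] and
#' are merged in by the simulation protocol.
#'
#' Key groups:
#' \describe{
#'   \item{Production}{`npp_ref` (g C m-2 yr-1) is potential NPP under the
#'     reference climate (`t_ref` deg C, `p_ref` mm yr-1) and reference CO2
#'     (`co2_ref` ppm). The CO2 response is logarithmic with sensitivity
#'     `beta_co2` (the classic beta factor); the temperature response is
#'     exponential with rate `k_t` per deg C; the moisture response is a
#'     saturating Michaelis-Menten form with half-saturation `p_half` mm.}
#'   \item{Turnover and decomposition}{`turnover` gives tissue turnover
#'     rates (yr-1); `k_litter` and `k_soc` are base decay rates of the
#'     litter and soil organic carbon pools; `humify` is the fraction of
#'     decomposed litter carbon transferred to SOC (the rest is respired);
#'     `q10` controls the temperature sensitivity of decomposition.}
#'   \item{Nitrogen}{`cn` holds tissue and soil C:N ratios governing uptake
#'     demand and immobilization; `k_leach` (yr-1) is the first-order
#'     leaching rate of soil mineral N; `uptake_cap` is the fraction of the
#'     currently available mineral pool plants may take up in one year.}
#'   \item{Saturation modifiers}{`kp_floor`, `k1_floor`, `km_floor` are the
#'     modifier minima reached at the maximum available soil mineral N
#'     (a floor of 0.824 on the production modifier corresponds to a 17.6%
#'     NPP reduction at full saturation; 0.85 on the mineralization
#'     modifier to a 15% reduction of SOC decomposition); `alloc_mult`
#'     are the allocation multipliers applied at full saturation
#'     (leaf +10%, wood +25%, root -35%); `k0` is the modifier value at
#'     zero mineral N; `legacy_ceiling` (g N m-2) is the mineral-N level at
#'     which the legacy (N-limitation only) modifiers reach 1;
#'     `n_mmax_factor` sets the maximum available mineral N as a multiple
#'     of the saturation threshold.}
#'   \item{Numerics}{`spinup` and `equil` hold convergence tolerances and
#'     iteration caps for the spin-up to carbon equilibrium and for the
#'     threshold-derivation equilibrium.}
#' }
#'
#' @param ... named overrides of any default entry (nested lists such as
#'   `spinup` are replaced wholesale).
#' @return a named list of parameters.
#' @examples
#' p <- nsat_params(k_leach = 0.2)
#' p$k_leach
#' @export
nsat_params <- function(...) {
  p <- list(
    # production
    npp_ref    = 800,    # g C m-2 yr-1 at reference climate and CO2
    co2_ref    = 296,    # ppm, pre-industrial plateau of the default trajectory
    beta_co2   = 0.5,    # logarithmic CO2 fertilization sensitivity
    t_ref      = 15,     # deg C
    k_t        = 0.04,   # per deg C
    p_ref      = 1000,   # mm yr-1
    p_half     = 500,    # mm yr-1
    npp_gpp_ratio = 0.45,
    # turnover and decomposition
    turnover   = c(leaf = 1.0, root = 0.5, wood = 0.05),  # yr-1
    k_litter   = 0.5,    # yr-1 base litter decay
    k_soc      = 0.05,   # yr-1 base SOC decay
    humify     = 0.3,    # fraction of litter decay humified to SOC
    q10        = 2.0,
    max_decay  = 0.95,   # cap on any annual fractional pool loss
    # nitrogen cycle
    cn         = c(leaf = 30, wood = 150, root = 60, soc = 12),
    k_leach    = 0.03,   # yr-1 first-order mineral-N leaching
    uptake_cap = 0.95,
    # saturation parameterization
    kp_floor   = 0.824,
    k1_floor   = 0.85,
    km_floor   = 0.85,
    alloc_mult = c(leaf = 1.10, wood = 1.25, root = 0.65),
    k0         = 0.1,    # modifier value at zero mineral N
    legacy_ceiling = 2.0,  # g N m-2
    n_mmax_factor  = 2.0,  # n_mmax = factor * n_ms
    # numerics
    spinup = list(nep_tol = 0.05, nep_years = 10, residual_tol = 1e-4,
                  max_years = 20000),
    equil  = list(tol = 1e-6, max_years = 20000)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p
}

#' Vegetation-type parameter table
#'
#' Default per-vegetation-type parameters for the 15 plant functional
#' classes used by the critical-load table: reference potential NPP and
#' base carbon allocation fractions (leaf, wood, root; summing to 1).
#' These are generic literature-scale magnitudes, exposed so users can
#' substitute their own calibration.
#'
#' @return a data.frame with one row per vegetation type (index 1-15).
#' @examples
#' veg_params()[5, ]
#' @export
veg_params <- function() {
  data.frame(
    vegetation_type = 1:15,
    name = cl_vegetation_types(),
    npp_ref = c(1300, 1100, 800, 750, 800, 600, 550, 700,
                700, 550, 350, 250, 180, 80, 30),
    alloc_leaf = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.28, 0.28, 0.30,
                   0.35, 0.45, 0.35, 0.35, 0.40, 0.35, 0.40),
    alloc_wood = c(0.40, 0.40, 0.40, 0.40, 0.40, 0.42, 0.42, 0.40,
                   0.25, 0.05, 0.30, 0.30, 0.10, 0.15, 0.10),
    alloc_root = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30,
                   0.40, 0.50, 0.35, 0.35, 0.50, 0.50, 0.50),
    stringsAsFactors = FALSE
  )
}

# merge vegetation-specific entries into a parameter list
params_for_veg <- function(params, vegetation_type) {
  vt <- as.integer(vegetation_type)
  vp <- veg_params()
  if (!vt %in% vp$vegetation_type)
    stop("unknown vegetation type: ", vegetation_type)
  row <- vp[vp$vegetation_type == vt, ]
  params$npp_ref <- row$npp_ref
  params$alloc_base <- c(leaf = row$alloc_leaf, wood = row$alloc_wood,
                         root = row$alloc_root)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
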