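#' Nitrogen-control modifier curve
#'
#' Defines the response of the three multiplicative nitrogen-control
#' modifiers to soil mineral nitrogen \eqn{N_M}: \eqn{K_P} scales plant
#' biomass construction (NPP), \eqn{K_1} scales soil nitrogen
#' immobilization and \eqn{K_M} scales soil organic matter mineralization.
#'
#' Two modes are supported. In `legacy` mode (nitrogen limitation only) a
#' modifier rises from `k0` at \eqn{N_M = 0} to 1 at `legacy_ceiling`
#' (2 g N m-2 by default) and stays at 1 for any larger mineral pool. In
#' `saturation` mode the curve additionally declines once \eqn{N_M}
#' exceeds the saturation threshold `n_ms`, falling linearly to a
#' modifier-specific floor at the maximum available mineral nitrogen
#' `n_mmax` and staying at the floor beyond. The curve equals exactly 1 at
#' `n_ms`, so saturation onset is harmless by construction. When
#' `n_ms >= legacy_ceiling` (the usual case for thresholds derived from
#' critical loads) the two modes coincide for all
#' \eqn{N_M \le} `legacy_ceiling`; for smaller thresholds the rising limb
#' is compressed to peak at `n_ms`.
#'
#' @param n_ms soil mineral N at saturation onset, g N m-2 (> 0).
#' @param n_mmax maximum available soil mineral N, g N m-2 (> `n_ms`);
#'   defaults to twice `n_ms`.
#' @param kp_floor,k1_floor,km_floor modifier minima at `n_mmax`, in (0, 1].
#' @param k0 modifier value at zero mineral N, in (0, 1).
#' @param legacy_ceiling mineral N at which legacy-mode modifiers reach 1.
#' @return an object of class `modifier_curve`.
#' @seealso [modifier_kp()], [modifier_k1()], [modifier_km()]
#' @examples
#' cv <- modifier_curve(n_ms = 9)
#' modifier_kp(c(0, 2, 9, 18, 30), cv, mode = "saturation")
#' @export
modifier_curve <- function(n_ms, n_mmax = 2 * n_ms,
                           kp_floor = 0.824, k1_floor = 0.85,
                           km_floor = 0.85, k0 = 0.1,
                           legacy_ceiling = 2.0) {
  stopifnot(is.numeric(n_ms), length(n_ms) == 1, is.finite(n_ms))
  if (n_ms <= 0) stop("n_ms must be positive")
  if (n_mmax <= n_ms) stop("n_mmax must exceed n_ms")
  floors <- c(kp = kp_floor, k1 = k1_floor, km = km_floor)
  if (any(floors <= 0) || any(floors > 1))
    stop("modifier floors must lie in (0, 1]")
  if (k0 <= 0 || k0 >= 1) stop("k0 must lie in (0, 1)")
  if (legacy_ceiling <= 0) stop("legacy_ceiling must be positive")
  structure(list(n_ms = n_ms, n_mmax = n_mmax,
                 kp_floor = kp_floor, k1_floor = k1_floor,
                 km_floor = km_floor, k0 = k0,
                 legacy_ceiling = legacy_ceiling),
            class = "modifier_curve")
}

# shared evaluation of one modifier with a given floor
modifier_eval <- function(n_m, curve, floor, mode = c("saturation", "legacy")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_m)) stop("n_m must be numeric")
  if (any(!is.finite(n_m)) || any(n_m < 0))
    stop("n_m must be finite and non-negative")
  stopifnot(inherits(curve, "modifier_curve"))
  k0 <- curve$k0
  if (mode == "legacy") {
    rise_end <- curve$legacy_ceiling
    val <- ifelse(n_m >= rise_end, 1, k0 + (1 - k0) * n_m / rise_end)
    return(pmin(val, 1))
  }
  rise_end <- min(curve$legacy_ceiling, curve$n_ms)
  n_ms <- curve$n_ms
  n_mmax <- curve$n_mmax
  val <- numeric(length(n_m))
  lo <- n_m <= rise_end
  val[lo] <- k0 + (1 - k0) * n_m[lo] / rise_end
  mid <- n_m > rise_end & n_m <= n_ms
  val[mid] <- 1
  dec <- n_m > n_ms & n_m < n_mmax
  val[dec] <- 1 - (1 - floor) * (n_m[dec] - n_ms) / (n_mmax - n_ms)
  hi <- n_m >= n_mmax
  val[hi] <- floor
  val
}

#' Nitrogen-control modifiers
#'
#' Evaluate the plant-production modifier \eqn{K_P}, the immobilization
#' modifier \eqn{K_1} or the mineralization modifier \eqn{K_M} at a soil
#' mineral nitrogen level. See [modifier_curve()] for the functional form.
#'
#' @param n_m soil mineral nitrogen, g N m-2 (vectorized, non-negative).
#' @param curve a [modifier_curve()].
#' @param mode `"saturation"` (default; declines beyond the saturation
#'   threshold) or `"legacy"` (nitrogen limitation only, fixed at 1 above
#'   the 2 g N m-2 ceiling).
#' @return numeric vector of modifier values in (0, 1].
#' @examples
#' cv <- modifier_curve(n_ms = 10)
#' modifier_kp(3, cv, mode = "legacy")      # 1: above the legacy ceiling
#' modifier_kp(cv$n_mmax, cv)               # 0.824: full saturation
#' @export
modifier_kp <- function(n_m, curve, mode = c("saturation", "legacy")) {
  modifier_eval(n_m, curve, curve$kp_floor, mode)
}

#' @rdname modifier_kp
#' @export
modifier_k1 <- function(n_m, curve, mode = c("saturation", "legacy")) {
  modifier_eval(n_m, curve, curve$k1_floor, mode)
}

#' @rdname modifier_kp
#' @export
modifier_km <- function(n_m, curve, mode = c("saturation", "legacy")) {
  modifier_eval(n_m, curve, curve$km_floor, mode)
}

#' @export
print.modifier_curve <- function(x, ...) {
  cat("Nitrogen-control modifier curve\n")
  cat(sprintf("  saturation onset n_ms : %.3f g N m-2\n", x$n_ms))
  cat(sprintf("  maximum avail. n_mmax : %.3f g N m-2\n", x$n_mmax))
  cat(sprintf("  floors (K_P, K_1, K_M): %.3f, %.3f, %.3f\n",
              x$kp_floor, x$k1_floor, x$km_floor))
  cat(sprintf("  legacy ceiling        : %.1f g N m-2\n", x$legacy_ceiling))
  invisible(x)
}

#' Tabulate modifier curves on a mineral-N grid
#'
#' Returns the three modifiers evaluated in both modes over a grid of soil
#' mineral nitrogen values, suitable for export or plotting diagnostic
#' response curves.
#'
#' @param x a [modifier_curve()].
#' @param n_grid number of grid points.
#' @param n_max upper end of the grid (defaults to 1.25 `n_mmax`).
#' @param ... unused.
#' @return data.frame with columns `n_m`, `mode`, `kp`, `k1`, `km`.
#' @export
as.data.frame.modifier_curve <- function(x, ..., n_grid = 201,
                                         n_max = 1.25 * x$n_mmax) {
  g <- seq(0, n_max, length.out = n_grid)
  out <- lapply(c("legacy", "saturation"), function(m) {
    data.frame(n_m = g, mode = m,
               kp = modifier_kp(g, x, m),
               k1 = modifier_k1(g, x, m),
               km = modifier_km(g, x, m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
plot.modifier_curve <- function(x, mode = "saturation", ...) {
  df <- as.data.frame(x)
  df <- df[df$mode == mode, ]
  graphics::plot(df$n_m, df$kp, type = "l", ylim = c(0, 1.05),
                 xlab = expression(N[M] ~ (g ~ N ~ m^-2)),
                 ylab = "modifier", col = "forestgreen", lwd = 2, ...)
  graphics::lines(df$n_m, df$k1, col = "steelblue", lwd = 2, lty = 2)
  graphics::lines(df$n_m, df$km, col = "sienna", lwd = 2, lty = 3)
  graphics::abline(v = c(x$n_ms, x$n_mmax), col = "grey70", lty = 3)
  graphics::legend("bottomleft",
                   legend = c(expression(K[P]), expression(K[1]),
                              expression(K[M])),
                   col = c("forestgreen", "steelblue", "sienna"),
                   lwd = 2, lty = 1:3, bty = "n")
  invisible(df)
}
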