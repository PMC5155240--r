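test_that("potential NPP is normalized at the reference climate and CO2", {
  p <- demo_params()
  ref <- list(temperature = p$t_ref, precipitation = p$p_ref)
  expect_equal(npp_potential(ref, p$co2_ref, p), p$npp_ref)
  # closed-form CO2 response: doubling gives 1 + beta*ln(2)
  expect_equal(npp_potential(ref, 2 * p$co2_ref, p) / p$npp_ref,
               1 + p$beta_co2 * log(2))
  # monotone in CO2 across the plausible range
  sweep <- npp_potential(ref, seq(280, 800, by = 5), p)
  expect_true(all(diff(sweep) > 0))
  expect_error(npp_potential(ref, -1, p), "positive")
})

test_that("nitrogen control scales NPP linearly", {
  expect_equal(realized_npp(1000, 1), 1000)
  expect_equal(realized_npp(1000, 0.5), 500)
  expect_equal(realized_npp(1000, 0.824), 824)  # the 17.6% saturation floor
  expect_error(realized_npp(1000, 0), "0, 1")
  expect_error(realized_npp(1000, 1.2), "0, 1")
})

test_that("allocation shifts from roots to leaves and wood under saturation", {
  base <- c(leaf = 1, wood = 1, root = 1) / 3
  expect_equal(allocate_npp(600, base, saturation_degree = 0),
               600 * base, ignore_attr = TRUE)
  # full saturation with equal base fractions: multipliers 1.10/1.25/0.65
  # average exactly to 1, so no renormalization is needed
  out <- allocate_npp(900, base, saturation_degree = 1)
  expect_equal(unname(out), 900 * c(1.10, 1.25, 0.65) / 3)
  expect_equal(sum(out), 900)
  # the pre-renormalization root multiplier is a 35% reduction
  mult <- 1 + 1 * (c(leaf = 1.10, wood = 1.25, root = 0.65) - 1)
  expect_equal(unname(mult["root"]), 0.65)
  # outputs always sum to NPP after renormalization
  set.seed(21)
  for (i in 1:50) {
    b <- runif(3)
    b <- b / sum(b)
    names(b) <- c("leaf", "wood", "root")
    s <- runif(1)
    expect_equal(sum(allocate_npp(500, b, saturation_degree = s)), 500)
  }
  expect_error(allocate_npp(-1, base), "non-negative")
  expect_error(allocate_npp(1, c(leaf = 0.5, wood = 0.5, root = 0.5)),
               "sum to 1")
})

test_that("the mineralization modifier propagates linearly into Rh", {
  st <- ecosystem_state(litter = 500, soc = 8000, n_organic = 400)
  p <- demo_params()
  d1 <- decompose_pools(st, km = 1, k1 = 1, params = p)
  d085 <- decompose_pools(st, km = 0.85, k1 = 1, params = p)
  expect_equal(d085$rh / d1$rh, 0.85)
  expect_equal(d085$mineralized_n / d1$mineralized_n, 0.85)
  # empty pools give zero fluxes
  d0 <- decompose_pools(ecosystem_state(litter = 0, soc = 0), 1, 1,
                        params = p)
  expect_equal(d0$rh, 0)
  expect_equal(d0$mineralized_n, 0)
  expect_error(decompose_pools(st, km = 0, k1 = 1, params = p), "0, 1")
})

test_that("closed-system decomposition conserves carbon over a century", {
  p <- demo_params()
  litter <- 1200
  soc <- 9000
  rh_total <- 0
  for (i in 1:100) {
    st <- ecosystem_state(litter = litter, soc = soc, n_organic = 100)
    d <- decompose_pools(st, km = 0.9, k1 = 0.9, params = p)
    litter <- litter - d$litter_decomp
    soc <- soc + d$humified_c - d$soc_decomp
    rh_total <- rh_total + d$rh
  }
  expect_lt(abs((litter + soc + rh_total) - (1200 + 9000)), 1e-8)
})

test_that("zero forcing and zero pools give zero fluxes and an unchanged state", {
  p <- demo_params()
  st <- ecosystem_state(leaf = 0, wood = 0, root = 0, litter = 0, soc = 0,
                        n_mineral = 0, n_organic = 0, n_plant = 0)
  drv <- list(temperature = 12, precipitation = 0, co2 = 296,
              n_deposition = 0)
  res <- step_year(st, drv, p, demo_curve())
  expect_equal(res$cflux$npp, 0)
  expect_equal(res$cflux$rh, 0)
  expect_equal(unclass(res$state), unclass(st), ignore_attr = TRUE)
})

test_that("every annual step conserves carbon: change in total C equals NPP - Rh", {
  p <- demo_params()
  cv <- demo_curve(n_ms = 6)
  set.seed(31)
  for (i in 1:1000) {
    st <- ecosystem_state(leaf = runif(1, 0, 500), wood = runif(1, 0, 15000),
                          root = runif(1, 0, 1000),
                          litter = runif(1, 0, 3000),
                          soc = runif(1, 0, 20000),
                          n_mineral = runif(1, 0, 15),
                          n_organic = runif(1, 10, 800),
                          n_plant = runif(1, 0, 150))
    drv <- list(temperature = runif(1, -5, 28),
                precipitation = runif(1, 100, 2500),
                co2 = runif(1, 280, 600), n_deposition = runif(1, 0, 4))
    res <- step_year(st, drv, p, cv, mode = sample(c("saturation",
                                                     "legacy"), 1))
    dC <- sum(unclass(res$state)[c("leaf", "wood", "root", "litter",
                                   "soc")]) -
      sum(unclass(st)[c("leaf", "wood", "root", "litter", "soc")])
    expect_lt(abs(dC - (res$cflux$npp - res$cflux$rh)), 1e-8)
    expect_equal(res$cflux$nep, res$cflux$npp - res$cflux$rh)
    expect_true(res$cflux$npp <= res$cflux$gpp)
    expect_true(all(unclass(res$state) >= 0))
  }
})

test_that("pinning mineral N at the maximum reduces annual NPP by exactly 17.6%", {
  p <- demo_params()
  cv <- demo_curve(n_ms = 10)
  st <- ecosystem_state(leaf = 200, wood = 8000, root = 400, litter = 900,
                        soc = 9000, n_mineral = 5, n_organic = 500,
                        n_plant = 70)
  drv <- demo_drivers(dep = 1)
  sat <- step_year(st, drv, p, cv, mode = "saturation",
                   n_m_override = cv$n_mmax)
  ref <- step_year(st, drv, p, cv, pin_modifiers = TRUE)
  expect_equal(100 * (1 - sat$cflux$npp / ref$cflux$npp), 17.6)
})

test_that("a non-finite state is rejected with a diagnostic", {
  st <- ecosystem_state()
  st[["soc"]] <- NaN
  expect_error(step_year(st, demo_drivers(), demo_params(), demo_curve()),
               "non-finite")
})

test_that("constant forcing drives the model to the same fixed point from any start", {
  p <- demo_params()
  cv <- demo_curve(n_ms = 20)
  drv <- demo_drivers(dep = 0.3)
  set.seed(41)
  finals <- replicate(8, {
    st <- ecosystem_state(leaf = runif(1, 1, 400), wood = runif(1, 1, 9000),
                          root = runif(1, 1, 800),
                          litter = runif(1, 1, 2000),
                          soc = runif(1, 100, 15000),
                          n_mineral = runif(1, 0.01, 10),
                          n_organic = runif(1, 5, 600),
                          n_plant = runif(1, 0.5, 100))
    eq <- run_to_equilibrium(st, drv, p, cv, criterion = "nep")
    expect_lt(abs(eq$nep), p$spinup$nep_tol)
    unclass(eq$state)
  })
  spread <- apply(finals, 1, function(x) diff(range(x)) / (1 + mean(x)))
  expect_lt(max(spread), 0.02)
})

test_that("equilibrium failure reports the residual", {
  p <- demo_params()
  expect_error(
    run_to_equilibrium(ecosystem_state(), demo_drivers(), p, demo_curve(),
                       criterion = "pools", tol = 1e-14, max_years = 50,
                       accelerate = FALSE),
    "not reached")
})
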