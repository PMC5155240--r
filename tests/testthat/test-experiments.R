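test_that("the scenario table matches the factorial design exactly", {
  tab <- scenario_table()
  expect_equal(tab$name, c("NCC", "NNC", "CNC", "TNC", "PNC", "NNS"))
  frozen <- list(NCC = NULL, NNC = "n_deposition", CNC = "co2",
                 TNC = "temperature", PNC = "precipitation", NNS = NULL)
  for (nm in tab$name) {
    cfg <- scenario_config(nm)
    expect_identical(cfg$frozen_driver, frozen[[nm]])
    expect_equal(cfg$freeze_year, 1970)
    expect_identical(cfg$saturation_active, nm != "NNS")
  }
  expect_error(scenario_config("XYZ"), "unknown scenario")
})

test_that("the protocol freezes drivers and holds stage-2 deposition at 1970", {
  suite <- paperlike_suite()
  nnc <- suite$NNC$data
  for (s in unique(nnc$site_id)) {
    d <- nnc[nnc$site_id == s, ]
    dep70 <- d$n_deposition[d$year == 1970]
    # stage 2 and the frozen stage 3 both use the 1970 deposition
    expect_true(all(d$n_deposition == dep70))
  }
  # dynamic deposition differs in NCC at the grassland site
  ncc <- suite$NCC$data
  d <- ncc[ncc$site_id == "ASGR-1" & ncc$year >= 1990, ]
  expect_gt(min(d$n_deposition),
            ncc$n_deposition[ncc$site_id == "ASGR-1" & ncc$year == 1970])
})

test_that("spin-up reaches carbon equilibrium at every site", {
  suite <- paperlike_suite()
  expect_true(all(abs(suite$NCC$spinup$spinup_nep) < 0.1))
  # threshold derivation ties the saturation threshold to the load
  sp <- suite$NCC$spinup
  expect_true(all(sp$n_ms > 0))
  expect_true(all(diff(sp$n_ms[order(sp$cl)]) >= -0.01))
})

test_that("removing saturation never lowers NPP at persistently saturated sites", {
  suite <- paperlike_suite()
  dd <- diff_scenarios(suite$NNS, suite$NCC, "npp")
  us <- dd$per_site[grepl("^USTF", dd$per_site$site_id), ]
  expect_true(all(us$diff >= 0))
  # and the effect is a real productivity loss, not merely zero
  expect_gt(mean(us$diff[us$year >= 1990]), 1)
  nep <- diff_scenarios(suite$NNS, suite$NCC, "nep")
  expect_gt(nep$mean, 0)
})

test_that("dynamic and no-saturation runs are identical at never-saturated sites", {
  suite <- paperlike_suite()
  for (s in c("BOBG-1", "BOBG-2")) {
    a <- suite$NCC$data[suite$NCC$data$site_id == s, ]
    b <- suite$NNS$data[suite$NNS$data$site_id == s, ]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
})

test_that("the protocol is deterministic across repeated invocation", {
  sites <- make_ensemble(4, seed = 9)[1, , drop = FALSE]
  class(sites) <- c("site_ensemble", "data.frame")
  forc <- generate_forcing_ensemble(sites, 1970:2009, seed = 9)
  r1 <- run_protocol(sites, forc, "NCC")
  r2 <- run_protocol(sites, forc, "NCC")
  expect_identical(r1$data, r2$data)
  expect_identical(r1$spinup, r2$spinup)
})

test_that("scenario differencing matches an independent recomputation", {
  suite <- paperlike_suite()
  dd <- diff_scenarios(suite$NCC, suite$NNC, "npp")
  # identity: a run differenced with itself is exactly zero
  self <- diff_scenarios(suite$NCC, suite$NCC, "npp")
  expect_true(all(self$per_site$diff == 0))
  expect_equal(self$mean, 0)
  expect_equal(self$pct, 0)
  # oracle: recompute the global mean/sd by a naive loop over years
  a <- suite$NCC$data
  b <- suite$NNC$data
  w <- suite$NCC$sites$area[match(a$site_id, suite$NCC$sites$site_id)]
  yrs <- sort(unique(a$year[a$year >= 1970]))
  diffs <- numeric(length(yrs))
  for (i in seq_along(yrs)) {
    ia <- a$year == yrs[i]
    diffs[i] <- sum(a$npp[ia] * w[ia]) / sum(w[ia]) -
      sum(b$npp[ia] * w[ia]) / sum(w[ia])
  }
  expect_equal(dd$mean, mean(diffs))
  expect_equal(dd$sd, stats::sd(diffs))
  gb <- dd$global
  expect_equal(dd$pct, 100 * mean(diffs) / mean(gb$b[gb$stage == "1970-2009"]))
  # misaligned runs are rejected
  trunc <- suite$NNC
  trunc$data <- trunc$data[-1, ]
  expect_error(diff_scenarios(suite$NCC, trunc), "same sites")
})

test_that("biome aggregation produces exact area-weighted shares", {
  # hand-built two-site run: equal areas, equal fluxes, two biomes
  mk_run <- function(sites, flux) {
    data <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
      data.frame(site_id = sites$site_id[i], year = 2000:2009,
                 stage = "1970-2009", npp = flux[i])))
    structure(list(sites = sites, data = data,
                   scenario = scenario_config("NCC")), class = "nsat_run")
  }
  sites2 <- make_ensemble(4, seed = 1)[c(1, 4), ]
  class(sites2) <- c("site_ensemble", "data.frame")
  agg <- aggregate_by_biome(mk_run(sites2, c(100, 100)))
  expect_equal(sort(agg$share), c(50, 50))
  expect_equal(sum(agg$share), 100, tolerance = 1e-9)
  # single biome takes the full share
  one <- sites2[1, , drop = FALSE]
  class(one) <- c("site_ensemble", "data.frame")
  expect_equal(aggregate_by_biome(mk_run(one, 100))$share, 100)
  # oracle on the real suite: naive group-by loop
  suite <- paperlike_suite()
  agg <- aggregate_by_biome(suite$NCC, variable = "npp")
  d <- suite$NCC$data[suite$NCC$data$stage == "1970-2009", ]
  sites <- suite$NCC$sites
  man <- sapply(unique(sites$biome_label), function(b) {
    ids <- sites$site_id[sites$biome_label == b]
    tot <- 0
    for (s in ids)
      tot <- tot + mean(d$npp[d$site_id == s]) *
        sites$area[sites$site_id == s]
    tot
  })
  expect_equal(sort(agg$total), sort(unname(man)), tolerance = 1e-12)
  expect_error(aggregate_by_biome(suite$NCC, weights = rep(0, 8)),
               "positive")
})

test_that("driver attribution assembles the scenario differences", {
  suite <- paperlike_suite()
  at <- attribution_summary(suite)
  expect_setequal(unique(at$driver),
                  c("co2", "temperature", "precipitation", "n_deposition",
                    "n_saturation"))
  # oracle: each row equals the corresponding scenario difference
  expect_equal(at$mean[at$driver == "co2" & at$variable == "npp"],
               diff_scenarios(suite$NCC, suite$CNC, "npp")$mean)
  expect_equal(at$mean[at$driver == "n_saturation" & at$variable == "nep"],
               diff_scenarios(suite$NNS, suite$NCC, "nep")$mean)
  # rising CO2 promotes productivity on the synthetic ensemble
  expect_gt(at$mean[at$driver == "co2" & at$variable == "npp"], 0)
  expect_gt(at$mean[at$driver == "co2" & at$variable == "nep"], 0)
  expect_error(attribution_summary(suite[1:3]), "missing scenario")
})

test_that("soil mineral nitrogen is drawn down under rising CO2", {
  suite <- paperlike_suite()
  ncc <- suite$NCC$data
  cnc <- suite$CNC$data
  late <- ncc$year %in% 2000:2009
  # ensemble mean over the final decade: dynamic CO2 leaves less mineral N
  expect_lt(mean(ncc$n_mineral[late]), mean(cnc$n_mineral[late]))
  # and the drawdown holds at the never-saturated boreal sites too
  bo <- late & grepl("^BOBG", ncc$site_id)
  expect_lt(mean(ncc$n_mineral[bo]), mean(cnc$n_mineral[bo]))
})

test_that("raising deposition beyond the load does not raise NPP relative to the no-saturation run", {
  # one US-forest site, two deposition plateaus above the critical load
  base <- make_ensemble(4, seed = 13)[1, , drop = FALSE]
  class(base) <- c("site_ensemble", "data.frame")
  run_pair <- function(level) {
    prof <- ndep_profile("us_temperate_forest", start_level = level,
                         noise_sd = 0)
    forc <- list(generate_forcing(as.list(base[1, ]), 1851:2009, prof,
                                  seed = 13))
    names(forc) <- base$site_id
    runs <- run_scenarios(base, forc, scenarios = c("NCC", "NNS"))
    diff_scenarios(runs$NNS, runs$NCC, "npp")$mean
  }
  gap_lo <- run_pair(1.8)
  gap_hi <- run_pair(2.6)
  expect_gte(gap_lo, 0)
  # more excess deposition means at least as much saturation loss
  expect_gte(gap_hi, gap_lo)
})
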