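# Minimal multilayer host engine and its coupling to the salinity module.

test_that("phenology accumulates thermal time and caps at maturity", {
  host <- host_parameters()
  st <- crop_state(host)
  st2 <- advance_phenology(st, host$t_base - 2, host)
  expect_equal(st2$dvs, st$dvs)
  # constant temperature gives piecewise-linear DVS reaching 2
  st <- crop_state(host)
  tmean <- 25
  days_needed <- ceiling((host$tt_anthesis + host$tt_maturity) /
                           (tmean - host$t_base))
  dvs_path <- numeric(days_needed)
  for (d in seq_len(days_needed)) {
    st <- advance_phenology(st, tmean, host)
    dvs_path[d] <- st$dvs
  }
  expect_equal(st$dvs, 2)
  expect_true(all(diff(dvs_path) >= 0))
  pre_anthesis <- dvs_path[dvs_path < 1]
  expect_equal(diff(pre_anthesis),
               rep((tmean - host$t_base) / host$tt_anthesis,
                   length(pre_anthesis) - 1),
               tolerance = 1e-12)
})

test_that("neutral stress reproduces the host-only trajectory exactly", {
  w <- short_weather(60)
  a <- run_season(w, 0, salt_enabled = TRUE)
  b <- run_season(w, 0, salt_enabled = FALSE)
  expect_equal(a$daily, b$daily, tolerance = 1e-12)
  expect_identical(a$yield, b$yield)
  expect_equal(sum(a$daily$na_uptake), 0)
  expect_equal(total_na(a$final_pools) == 0, TRUE)
})

test_that("zero photosynthesis stress stops gross growth", {
  host <- host_parameters()
  st <- mid_state()
  env <- daily_environment(tmean = 24, radiation = 20, rh = 75, et0 = 4)
  sf <- neutral_stress(5)
  sf$rpn_by_layer <- rep(0, 5)
  g <- daily_growth(st, env, sf, host)
  expect_equal(g$carbon$gross, 0)
  g1 <- daily_growth(st, env, neutral_stress(5), host)
  expect_gt(g1$carbon$gross, 0)
})

test_that("daily carbon balance closes at every step", {
  host <- host_parameters()
  st <- crop_state(host)
  w <- short_weather(80, seed = 3)
  set.seed(42)
  for (d in seq_len(nrow(w))) {
    env <- daily_environment(w$tmean[d], w$radiation[d], w$rh[d], w$et0[d])
    st <- advance_phenology(st, env$tmean, host)
    sf <- neutral_stress(5)
    # exercise the stressed pathways too
    sf$cvs_stress <- runif(1, 0.3, 1)
    sf$sterility_f <- runif(1, 0, 0.2)
    sf$mresp_f <- runif(1, 0, 1)
    before <- list(leaf = sum(st$leaf_biomass_by_layer),
                   culm = st$culm_biomass, pan = st$panicle_biomass,
                   dead = st$dead_leaf_biomass)
    g <- daily_growth(st, env, sf, host)
    st <- g$state
    cb <- g$carbon
    expect_equal(host$growth_efficiency * (cb$gross - cb$maint),
                 cb$leaf_inc + cb$culm_inc + cb$pan_inc + cb$stress_loss,
                 tolerance = 1e-9 * max(1, cb$gross))
    # organ increments (plus internal remobilization) account for every
    # gram, net of senescence transfers to the dead pool
    total_delta <- sum(st$leaf_biomass_by_layer) + st$culm_biomass +
      st$panicle_biomass + st$dead_leaf_biomass -
      (before$leaf + before$culm + before$pan + before$dead)
    expect_equal(total_delta, cb$leaf_inc + cb$culm_inc + cb$pan_inc,
                 tolerance = 1e-9 * max(1, cb$gross))
    expect_true(all(st$leaf_biomass_by_layer >= 0))
  }
})

test_that("layer re-slicing conserves mass and transported sodium", {
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    m <- runif(k, 0, 100)
    x <- runif(k, 0, 50)
    n <- sample(2:6, 1)
    rs <- saltrice:::reslice_layers(m, x, n)
    expect_equal(sum(rs$m), sum(m), tolerance = 1e-12 * max(1, sum(m)))
    expect_equal(sum(rs$x), sum(x), tolerance = 1e-12 * max(1, sum(x)))
    expect_equal(diff(rs$m), rep(0, n - 1), tolerance = 1e-12)
  }
  empty <- saltrice:::reslice_layers(rep(0, 3), rep(0, 3), 3)
  expect_equal(empty$m, rep(0, 3))
})

test_that("a full season is deterministic and salt reduces biomass", {
  w <- make_weather(130, 2)
  s <- rep(50, 130)
  a <- run_season(w, s)
  b <- run_season(w, s)
  expect_identical(a$daily, b$daily)
  control <- run_season(w, 0)
  expect_lt(a$agb, control$agb)
  expect_lt(a$yield, control$yield)
  expect_lte(a$yield, a$daily$panicle_biomass[130])
  expect_true(all(a$daily$agb >= 0))
})

test_that("yield is monotone non-increasing in uniform salinity scaling", {
  w <- make_weather(130, 4)
  base <- make_salinity_series(salinity_scenario("gradual_ramp"), 130)
  yields <- vapply(c(0, 0.5, 1, 1.5),
                   function(f) run_season(w, f * base, daily = FALSE)$yield,
                   numeric(1))
  expect_true(all(diff(yields) <= 1e-9))
})

test_that("season length must match the salinity series", {
  w <- short_weather(30)
  expect_error(run_season(w, rep(1, 29)), "match")
  expect_error(run_season(w, rep(-1, 30)), ">= 0")
})

test_that("hydroponic forcing stays inside the chamber protocol", {
  hf <- hydroponic_forcing(90, 25)
  expect_equal(nrow(hf$weather), 90)
  expect_true(all(hf$weather$rh >= 58 & hf$weather$rh <= 92))
  expect_equal(unique(hf$salinity), 25)
  expect_equal(unique(hf$weather$tmean), (26 * 14 + 18 * 10) / 24)
})
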