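# Shoot Na+ uptake chain: bypass water share, suberin dynamics, relative
# bypass flow and the scaling from apoplastic to total uptake.

test_that("bypass water share follows the linear humidity response", {
  # independent arithmetic: -0.0275 * rh + 3.92
  for (rh in c(0, 58, 92, 100)) {
    expect_equal(relative_bypass_water(rh), max(0, -0.0275 * rh + 3.92))
  }
  expect_equal(relative_bypass_water(0), 3.92)
  expect_equal(relative_bypass_water(92), 1.39)
  expect_equal(relative_bypass_water(58), 2.325)
  expect_error(relative_bypass_water(101), "humidity")
  expect_error(relative_bypass_water(-1), "humidity")
})

test_that("apoplastic water flux is transpiration times its share", {
  expect_equal(bypass_water_flux(0, 2), 0)
  expect_equal(bypass_water_flux(5, 2), 0.1)
  expect_equal(bypass_water_flux(4, 1.39), 0.0556)
  expect_error(bypass_water_flux(-1, 2), ">= 0")
})

test_that("suberin deposition response rises with salinity and saturates", {
  expect_equal(suberin_deposition_response(0, 50, 0.62), 0)
  # literal value 1/(1-0.62) = 2.63 clamps to 1
  expect_equal(suberin_deposition_response(50, 50, 0.62), 1)
  expect_equal(suberin_deposition_response(25, 50, 0), 0.5)
  expect_error(suberin_deposition_response(10, 50, 1), "singular")
  expect_error(suberin_deposition_response(10, 0, 0.5), "max_na_ext")
})

test_that("suberin content respects age dynamics and bounds", {
  sc_max <- default_tp$sc_max
  expect_equal(suberin_content(1, 1, sc_max), sc_max)
  expect_equal(suberin_content(2, 0, sc_max), sc_max) # 2*1.5/3 = 1
  expect_equal(suberin_content(0, 0, sc_max), 0)
  expect_equal(suberin_content(0, 1, sc_max), 0)      # indeterminate corner
  # monotone in DVS at fixed F_sc, and in F_sc at fixed DVS > 0
  for (f in c(0, 0.3, 0.9)) {
    sc <- suberin_content(seq(0, 2, by = 0.05), f, sc_max)
    expect_true(all(diff(sc) >= -1e-12))
    expect_true(all(sc <= sc_max + 1e-12))
  }
  for (dvs in c(0.2, 1, 2)) {
    sc <- suberin_content(dvs, seq(0, 1, by = 0.05), sc_max)
    expect_true(all(diff(sc) >= -1e-12))
  }
})

test_that("relative bypass flow decreases from 1 to rrbf_min/100", {
  tp <- default_tp; ax <- default_ax
  expect_equal(relative_bypass_flow(tp$sc_max, tp, ax), 0.05)
  expect_equal(relative_bypass_flow(ax$sc_min, tp, ax), 1)
  expect_equal(relative_bypass_flow((ax$sc_min + tp$sc_max) / 2, tp, ax),
               0.05^0.5, tolerance = 1e-12)
  sc <- seq(ax$sc_min, tp$sc_max, length.out = 50)
  rrbf <- relative_bypass_flow(sc, tp, ax)
  expect_true(all(diff(rrbf) <= 0))
  expect_true(all(rrbf > 0 & rrbf <= 1))
  # out-of-range suberin is clamped
  expect_equal(relative_bypass_flow(tp$sc_max + 10, tp, ax), 0.05)
  expect_error(
    relative_bypass_flow(1, tp, auxiliary_constants(sc_min = 40)),
    "sc_max")
})

test_that("literal bypass-flow mode reproduces the published arrangement", {
  tp <- default_tp; ax <- default_ax
  frac <- 0.5
  sc <- ax$sc_min + frac * (tp$sc_max - ax$sc_min)
  expect_equal(relative_bypass_flow(sc, tp, ax, literal_mode = TRUE),
               0.01 * 5^0.5, tolerance = 1e-12)
  expect_equal(relative_bypass_flow(ax$sc_min, tp, ax, literal_mode = TRUE),
               0.01)
})

test_that("apoplastic uptake converts water flux and molarity to mass", {
  expect_equal(apoplastic_na_uptake(0.5, 0.3, 0), 0)
  expect_equal(apoplastic_na_uptake(0.5, 0, 10), 0)
  expect_equal(apoplastic_na_uptake(0.1, 1, 10), 0.1 * 1e4 * 10 * 22.98977)
  expect_error(apoplastic_na_uptake(-1, 1, 1), ">= 0")
})

test_that("total uptake scales apoplastic uptake by the bypass share", {
  expect_equal(total_na_uptake(0, 25), 0)
  expect_equal(total_na_uptake(100, 25), 400)
  expect_error(total_na_uptake(100, 0), "> 0")
  # default humidity relation keeps the bypass share inside the reported
  # 22-35% range over the experimental humidity band
  for (rh in c(58, 70, 92)) {
    share <- relative_na_uptake_ap(rh)
    expect_gte(share, 22 - 1e-9)
    expect_lte(share, 35 + 1e-9)
  }
  expect_equal(relative_na_uptake_ap(58), 35)
  expect_equal(relative_na_uptake_ap(92), 22)
})

test_that("one day of uptake matches a first-principles recomputation", {
  # brute-force dimensional oracle: litres transpired through the bypass
  # path times mg/L, divided by the bypass share of total uptake
  tp <- default_tp; ax <- default_ax
  cases <- expand.grid(tr = c(0, 1.5, 5), rh = c(58, 75, 92),
                       na = c(0, 12, 35), dvs = c(0.2, 1, 1.9))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- daily_na_uptake(cs$tr, cs$rh, cs$na, cs$dvs, tp, ax)
    litres_bypass <- cs$tr * (-0.0275 * cs$rh + 3.92) / 100 * 1e4
    mg_per_l <- cs$na * 22.98977
    f <- min(1, (cs$na / ax$max_na_ext) / (1 - tp$sub_dep_eff))
    sc <- if (cs$dvs == 0 && f == 1) 0 else
      tp$sc_max * cs$dvs * (0.5 * (1 - f) + 1) / ((1 - f) + cs$dvs)
    rr <- (tp$rrbf_min / 100)^(sc / tp$sc_max)
    share <- ax$rna_uptake_slope * cs$rh + ax$rna_uptake_intercept
    oracle <- litres_bypass * rr * mg_per_l * 100 / share
    expect_equal(got$uptake, oracle, tolerance = 1e-9)
    if (cs$na == 0 || cs$tr == 0) expect_equal(got$uptake, 0)
    expect_gte(got$uptake + 1e-12, got$uptake_ap)
  }
})
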