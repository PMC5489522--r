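# Allocation of daily shoot Na+ among culm, panicle and leaf layers.

test_that("relative sink size reflects remaining culm capacity", {
  expect_equal(relative_sink_size(0, 26), 1)
  expect_equal(relative_sink_size(26, 26), 0)
  expect_equal(relative_sink_size(13, 26), 0.5)
  expect_equal(relative_sink_size(30, 26), 0)   # clamped
  expect_error(relative_sink_size(1, 0), "na_culm_max")
})

test_that("culm sequestration follows the feedback curve with a floor", {
  # independent arithmetic for the brace term of the feedback
  feedback <- function(r) 1 - 0.08 * ((r + 0.1)^-1.13 - 0.08)
  expect_equal(feedback(1), 0.93457, tolerance = 1e-4)
  expect_equal(culm_sequestration_rate(1, 0.029, 1e6),
               0.029 * 1e6 * feedback(1), tolerance = 1e-12)
  # (0.1)^-1.13 = 13.49 makes the brace negative: floored at zero
  expect_lt(feedback(0), 0)
  expect_equal(culm_sequestration_rate(0, 0.029, 1e6), 0)
  expect_equal(culm_sequestration_rate(1, 0.029, 0), 0)
  expect_error(culm_sequestration_rate(1.2, 0.029, 1e6), "rel_sink")
})

test_that("panicle delivery opens with the reproductive window", {
  expect_equal(panicle_na_delivery(1000, 0, 0.5, 0.2, 0.5), 0)
  expect_equal(panicle_na_delivery(1000, 0, 0.5, 0.2, 1), 100)
  expect_equal(panicle_na_delivery(500, 500, 0.5, 0.2, 1), 0)
  # difference floored: sequestration can exceed uptake numerically
  expect_equal(panicle_na_delivery(100, 400, 0.5, 0.2, 1), 0)
})

test_that("leaf layers split Na+ by age with geometric weights", {
  expect_equal(leaf_layer_partition(7, 0.7, 1), 7)
  expect_equal(leaf_layer_partition(9, 0, 3), rep(3, 3))
  got <- leaf_layer_partition(1.8477, 0.7, 3)
  expect_equal(got, c(1.0, 0.5477, 0.3), tolerance = 1e-4)
  expect_equal(leaf_layer_partition(5, 1, 4), c(5, 0, 0, 0))
  # symbolic normalization oracle for small layer counts
  for (n in 1:4) {
    for (pc in c(0.1, 0.5, 0.9)) {
      w <- if (n == 1) 1 else (1 - pc)^((seq_len(n) - 1) / (n - 1))
      got <- leaf_layer_partition(10, pc, n)
      expect_equal(got, 10 * w / sum(w), tolerance = 1e-12)
      expect_true(all(diff(got) <= 1e-12))  # bottom-heavy
      expect_equal(sum(got), 10, tolerance = 1e-12)
    }
  }
})

test_that("daily allocation conserves mass exactly", {
  st <- mid_state()
  pools <- sodium_pools(5)
  for (uptake in c(0, 1e3, 5e5, 2e6)) {
    new <- allocate_day(uptake, pools, st, default_tp)
    delta <- (new$culm_na - pools$culm_na) +
      (new$panicle_na - pools$panicle_na) +
      sum(new$leaf_na_by_layer - pools$leaf_na_by_layer)
    expect_equal(delta, uptake, tolerance = 1e-9 * max(uptake, 1))
    pools <- new
  }
  expect_identical(allocate_day(0, pools, st, default_tp), pools)
})

test_that("a saturated culm sink routes everything to panicle and leaves", {
  st <- mid_state()
  tp <- default_tp
  culm_cap <- tp$na_culm_max * st$culm_biomass * 1000
  pools <- sodium_pools(5, culm_na = culm_cap)
  new <- allocate_day(1e6, pools, st, tp)
  expect_equal(new$culm_na, pools$culm_na)
  # hand-traced: panicle 0.5 * 0.2 * 1e6, leaves the residual
  expect_equal(new$panicle_na, 0.5 * 0.2 * 1e6)
  expect_equal(sum(new$leaf_na_by_layer), 0.9 * 1e6)
})

test_that("culm concentration never exceeds its maximum over a season", {
  w <- make_weather(130, 7)
  res <- run_season(w, make_salinity_series(salinity_scenario(), 130))
  conc <- res$daily$culm_na / (res$daily$culm_biomass * 1000)
  expect_true(all(conc <= default_tp$na_culm_max + 1e-9))
  # pools are cumulative except through senescence transfers
  expect_true(all(diff(res$daily$panicle_na) >= -1e-9))
  expect_true(all(res$daily$leaf_na >= 0))
})

test_that("senescent-leaf Na+ handling is configurable", {
  w <- make_weather(120, 13)
  s <- make_salinity_series(salinity_scenario("gradual_ramp"), 120)
  ledger <- run_season(w, s)
  retain <- run_season(w, s,
                       modes = default_modes(retain_senescent_na = TRUE))
  # default: dying tissue carries its Na+ into the dead ledger
  expect_gt(ledger$final_pools$dead_na, 0)
  # retained mode keeps leaf Na+ in living layers (dead pool only holds
  # the structurally fixed culm share) and still conserves mass
  expect_lt(retain$final_pools$dead_na, ledger$final_pools$dead_na)
  expect_gt(sum(retain$final_pools$leaf_na_by_layer),
            sum(ledger$final_pools$leaf_na_by_layer))
  expect_lt(retain$na_balance_error, 1e-9)
})
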