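# coarse grids keep these solves fast; the acceptance suite runs the
# full-resolution configuration
coarse <- function(...) oxygen_config(nx = 200, ny_gas = 8, ny_pdms = 40,
                                      dt_s = 2, ...)

small_field <- function() fixture("ox_small", function()
  simulate_oxygen(coarse()))

test_that("the initial condition is 21% everywhere", {
  f <- small_field()
  expect_equal(range(f$C_pct[, , 1]), c(21, 21))
  expect_equal(channel_profile(f, 0)$C_pct, rep(21, 200))
})

test_that("a partition-free uniform state is a fixed point of the scheme", {
  cfg <- coarse(C_inlet_pct = 21, partition_gas_to_pdms = 1, t_end_s = 120)
  f <- simulate_oxygen(cfg)
  expect_lt(max(abs(f$C_pct - 21)), 1e-8)
})

test_that("anoxic perfusion clears the small array within the observed bounds", {
  f <- small_field()
  expect_lte(channel_max(f, 60), 2)
  expect_lte(channel_max(f, 120), 0.1)
})

test_that("the field obeys the maximum principle under an anoxic inlet", {
  f <- small_field()
  expect_gte(min(f$C_pct), -1e-9)
  expect_lte(max(f$C_pct[, f$layer == "gas", ]), 21 + 1e-9)
  expect_lte(max(f$C_pct[, f$layer == "pdms", ]), 21 + 1e-9)
})

test_that("the large array clears more slowly than the small array everywhere in time", {
  fs <- small_field()
  fl <- fixture("ox_large", function()
    simulate_oxygen(coarse(channel_length_m = 0.55)))
  for (t in fs$times_s[-1])
    expect_gte(channel_max(fl, t), channel_max(fs, t))
  # and after ten minutes its along-channel spread remains far larger
  spread <- function(f) diff(range(channel_profile(f, 600)$C_pct))
  expect_gt(spread(fl), 5 * spread(fs))
})

test_that("closed-box runs conserve mass and equilibrate across the partition", {
  cfg <- oxygen_config(nx = 50, ny_gas = 8, ny_pdms = 30, dt_s = 5,
                       closed_box = TRUE, t_end_s = 600)
  f <- simulate_oxygen(cfg)
  m <- oxygen_total_mass(f)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-3)          # < 0.1% contract
  expect_lt(max(abs(m - m[1])) / m[1], 1e-9)          # direct solve: exact
  # refining the grid does not worsen conservation
  f2 <- simulate_oxygen(oxygen_config(nx = 100, ny_gas = 16, ny_pdms = 60,
                                      dt_s = 5, closed_box = TRUE,
                                      t_end_s = 600))
  m2 <- oxygen_total_mass(f2)
  expect_lte(max(abs(m2 - m2[1])) / m2[1],
             max(max(abs(m - m[1])) / m[1], 1e-9))
})

test_that("a two-level closed box relaxes to the partition-consistent equilibrium", {
  # long horizon so the 1 mm slab fully equilibrates
  cfg <- oxygen_config(nx = 8, ny_gas = 6, ny_pdms = 20, dt_s = 50,
                       t_end_s = 50000, output_dt_s = 10000,
                       closed_box = TRUE, pdms_thickness_m = 1e-3,
                       channel_length_m = 1e-3)
  f <- simulate_oxygen(cfg)
  # analytic equilibrium of the gas-equivalent potential from mass balance
  P <- 10
  V_gas <- cfg$channel_height_m
  V_pdms <- cfg$pdms_thickness_m
  phi0_gas <- 21; phi0_pdms <- 210
  phi_eq <- (V_gas * 1 * phi0_gas + V_pdms * (1 / P) * phi0_pdms) /
    (V_gas * 1 + V_pdms * (1 / P))
  last <- dim(f$C_pct)[3]
  gas_eq <- f$C_pct[, f$layer == "gas", last]
  pdms_eq <- f$C_pct[, f$layer == "pdms", last]
  expect_lt(max(abs(gas_eq - phi_eq)), 0.02 * phi_eq)
  # interface partition jump: C_gas = partition x C_pdms at equilibrium
  expect_lt(max(abs(gas_eq / mean(pdms_eq) - P)), 0.05 * P)
})

test_that("halving the grid spacing changes the 60-s channel maximum by < 10%", {
  a <- fixture("ox_conv_a", function()
    simulate_oxygen(oxygen_config(nx = 250, ny_gas = 8, ny_pdms = 50,
                                  dt_s = 2, t_end_s = 60)))
  b <- fixture("ox_conv_b", function()
    simulate_oxygen(oxygen_config(nx = 500, ny_gas = 16, ny_pdms = 100,
                                  dt_s = 2, t_end_s = 60)))
  ca <- channel_max(a, 60)
  cb <- channel_max(b, 60)
  expect_lt(abs(cb - ca) / ca, 0.10)
})

test_that("invalid configurations and profile queries are rejected", {
  expect_error(oxygen_config(D_pdms_m2s = -1), class = "embryokin_error")
  expect_error(oxygen_config(C_init_pct = 150), class = "embryokin_error")
  f <- small_field()
  expect_error(channel_profile(f, 61), class = "embryokin_error")
})
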