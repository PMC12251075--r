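test_that("junction mixing reproduces the validation-table fractions", {
  stocks <- c(EG = 25, TZ = 100)

  # saline/EG/TZ = 1.5/0.5/1 mL/h -> EG fraction 1/6
  cj <- junction_concentration(c(saline = 1.5, EG = 0.5, TZ = 1), stocks)
  expect_equal(round(cj[["EG"]] / 25, 3), 0.167)
  expect_equal(round(cj[["TZ"]] / 100, 2), 0.33)

  # 3/7/3 -> EG fraction 7/13 = 0.54
  cj2 <- junction_concentration(c(saline = 3, EG = 7, TZ = 3), stocks)
  expect_equal(round(cj2[["EG"]] / 25, 2), 0.54)

  # only the EG pump running: C = C0, others 0
  cj3 <- junction_concentration(c(saline = 0, EG = 1, TZ = 0), stocks)
  expect_equal(cj3[["EG"]], 25)
  expect_equal(cj3[["TZ"]], 0)

  expect_error(junction_concentration(c(saline = 0, EG = 0, TZ = 0), stocks),
               "no_flow")
})

test_that("pump schedules validate segment structure", {
  ok <- data.frame(role = c("a", "a"), t_start_s = c(0, 10),
                   t_end_s = c(10, 20), rate_ml_h = c(1, 2))
  s <- pump_schedule(ok)
  expect_equal(unname(pump_rates(s, 5)["a"]), 1)
  expect_equal(unname(pump_rates(s, 10)["a"]), 2)   # boundary takes new rate
  expect_equal(unname(pump_rates(s, 20)["a"]), 2)   # final end inclusive
  expect_equal(schedule_duration(s), 20)

  gap <- ok; gap$t_start_s[2] <- 12
  expect_error(pump_schedule(gap), "contiguous")
  neg <- ok; neg$rate_ml_h[1] <- -1
  expect_error(pump_schedule(neg), ">= 0")
})

test_that("plug-flow transport is an exact dead-volume delay", {
  # step change at t = 900 s with constant Q_tot = 13 mL/h and V = 1 mL:
  # the cell is unchanged until exactly 1/13 h = 276.9 s later
  seg <- rbind(
    data.frame(role = "saline", t_start_s = c(0, 900), t_end_s = c(900, 2100),
               rate_ml_h = c(7, 3)),
    data.frame(role = "EG", t_start_s = c(0, 900), t_end_s = c(900, 2100),
               rate_ml_h = c(3, 7)),
    data.frame(role = "TZ", t_start_s = c(0, 900), t_end_s = c(900, 2100),
               rate_ml_h = c(3, 3))
  )
  sched <- pump_schedule(seg)
  line <- line_config(dead_volume_ml = 1.0, transport = "plug")
  ts <- simulate_line(sched, line, fix_dyes(), fix_geometry(), fix_detector(0),
                      n_trials = 1, seed = 1)[[1]]
  lag_s <- 1.0 / 13 * 3600                     # 276.92 s
  pre <- ts$C_eg_true[ts$time_s > lag_s + 1 & ts$time_s <= 900 + lag_s]
  expect_true(all(abs(pre - 3 / 13 * 25) < 1e-9))
  post <- ts$C_eg_true[ts$time_s >= 900 + lag_s + 1]
  expect_true(all(abs(post - 7 / 13 * 25) < 1e-9))
})

test_that("noiseless cumulative mass matches the closed-form integral", {
  preset <- experiment_preset("exp_b")
  line <- line_config()
  ts <- simulate_line(preset$schedule, line, fix_dyes(), fix_geometry(),
                      fix_detector(0), n_trials = 1, seed = 1,
                      balance_noise_sd_g = 0, balance_resolution_g = 1e-12)[[1]]
  # piecewise closed form: 13 mL/h for 900 s, then 13 mL/h again (total
  # flow is unchanged in exp_b) -> mass = rho * 13/3600 * t
  expect_equal(ts$mass_g, 13 / 3600 * ts$time_s, tolerance = 1e-9)

  va <- cumulative_volume(experiment_preset("exp_a")$schedule, c(0, 1800, 3600))
  expect_equal(va, 3 / 3600 * c(0, 1800, 3600), tolerance = 1e-12)
})

test_that("tanks-in-series: fixed point, monotone step response, mass conservation", {
  stocks <- c(EG = 25, TZ = 100)
  preset <- experiment_preset("exp_a")
  geo <- fix_geometry()
  for (n_tanks in c(1, 5, 20)) {
    line <- line_config(dead_volume_ml = 0.2, n_tanks = n_tanks)
    ts <- simulate_line(preset$schedule, line, fix_dyes(), geo,
                        fix_detector(0), n_trials = 1, seed = 1)[[1]]
    cj <- junction_concentration(c(saline = 1.5, EG = 0.5, TZ = 1), stocks)
    # steady state equals the junction concentration for any n_tanks
    expect_equal(ts$C_eg_true[length(ts$time_s)], cj[["EG"]], tolerance = 1e-6)
    # step response from saline is monotone (passive mixing chain)
    expect_true(all(diff(ts$C_eg_true) > -1e-12))
  }

  # solute mass conservation: integral of C_cell * Q_tot approaches the
  # injected integral of Q_eg * C0 as the line fills
  line <- line_config(dead_volume_ml = 0.2, n_tanks = 5)
  ts <- simulate_line(preset$schedule, line, fix_dyes(), geo, fix_detector(0),
                      n_trials = 1, seed = 1)[[1]]
  dt <- diff(ts$time_s[1:2])
  out_mass <- sum(ts$C_eg_true * 3 / 3600) * dt          # ug through the cell
  in_mass <- 0.5 * 25 / 3600 * max(ts$time_s)            # ug injected
  held <- line$dead_volume_ml * tail(ts$C_eg_true, 1)    # ug still in the line
  expect_equal(out_mass + held, in_mass, tolerance = 0.01)
})

test_that("lag to 50% response scales with dead_volume / Q_tot", {
  stocks <- c(EG = 25, TZ = 100)
  geo <- fix_geometry()
  t50 <- vapply(c(2, 4, 8), function(q_sal) {
    seg <- rbind(
      data.frame(role = "saline", t_start_s = 0, t_end_s = 1800, rate_ml_h = q_sal),
      data.frame(role = "EG", t_start_s = 0, t_end_s = 1800, rate_ml_h = 1),
      data.frame(role = "TZ", t_start_s = 0, t_end_s = 1800, rate_ml_h = 1)
    )
    line <- line_config(dead_volume_ml = 0.5, n_tanks = 5)
    ts <- simulate_line(pump_schedule(seg), line, fix_dyes(), geo,
                        fix_detector(0), n_trials = 1, seed = 1)[[1]]
    target <- 0.5 * tail(ts$C_eg_true, 1)
    ts$time_s[which(ts$C_eg_true >= target)[1]]
  }, numeric(1))
  q_tot <- c(4, 6, 10)
  ratio <- t50 * q_tot                 # should be ~ constant
  expect_lt(max(ratio) / min(ratio), 1.1)
})

test_that("unstable explicit time step is refused", {
  preset <- experiment_preset("exp_b")
  line <- line_config(dead_volume_ml = 0.01, n_tanks = 10)  # tank tau ~ 0.28 s
  expect_error(
    simulate_line(preset$schedule, line, fix_dyes(), fix_geometry(),
                  fix_detector(0), n_trials = 1, seed = 1),
    "unstable_timestep")
})

test_that("balance readout quantizes (half-even) and reproduces its noise SD", {
  expect_equal(balance_readout(0.123456, noise_sd_g = 0), 0.12346)
  # exact ties resolve half-even (coarse resolution keeps the tie exact in FP)
  expect_equal(balance_readout(1.25, noise_sd_g = 0, resolution_g = 0.5), 1.0)
  expect_equal(balance_readout(1.75, noise_sd_g = 0, resolution_g = 0.5), 2.0)
  expect_equal(balance_readout(c(0, 0.5, 1), noise_sd_g = 0), c(0, 0.5, 1))
  expect_error(balance_readout(c(1, 0.5)), "non-decreasing")

  draws <- balance_readout(rep(1, 1e4), noise_sd_g = 5e-4,
                           resolution_g = 1e-6, seed = 21)
  expect_equal(sd(draws), 5e-4, tolerance = 0.05)
})
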