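test_that("daily growth rate matches an independent re-evaluation and is monotone in food", {
  pj <- load_parameter_set("atkinson2006", "dgr", "juvenile")
  pa <- load_parameter_set("atkinson2006", "dgr", "all krill")
  # double-transcription oracle: the regression recomputed term by term
  # from the registry values, written independently of atkinson_dgr()
  oracle <- function(L, T, F, co)
    sum(co[c("a0")], co["aL"] * L, co["aL2"] * L^2,
        co["aF"] * F / (co["kF"] + F), co["aT"] * T, co["aT2"] * T^2)
  for (case in list(c(26, 0, 1), c(26, 2, 0.5), c(40, -1, 3))) {
    expect_equal(atkinson_dgr(case[1], case[2], case[3], pj),
                 oracle(case[1], case[2], case[3], pj$coefficients))
    expect_equal(atkinson_dgr(case[1], case[2], case[3], pa),
                 oracle(case[1], case[2], case[3], pa$coefficients))
  }
  # non-decreasing in chlorophyll on a dense grid, any temperature
  for (sst in seq(-2, 4, by = 0.5)) {
    r <- atkinson_dgr(26, sst, seq(0, 10, by = 0.05), pj)
    expect_true(all(diff(r) >= 0))
  }
  expect_error(atkinson_dgr(26, 0, -1, pj), "non-negative")
})

test_that("the two IMP functions reproduce the published 30 d vs 10 d contrast", {
  expect_equal(kawaguchi_imp(0), 30, tolerance = 0.05)
  taf <- load_parameter_set("tarling2006", "imp", "adult female")
  expect_equal(tarling_imp(0, 35, taf), 10, tolerance = 0.05)
  expect_true(kawaguchi_imp(0) / tarling_imp(0, 35, taf) >= 2.5)
  expect_true(kawaguchi_imp(0) / tarling_imp(0, 35, taf) <= 3.5)
  # temperature-only IMP decays monotonically with warming
  imps <- kawaguchi_imp(seq(-2, 5, by = 0.1))
  expect_true(all(diff(imps) < 0) && all(imps > 0))
  # adult-female IMPs lengthen again above 0.5 degC
  expect_gt(tarling_imp(1.5, 35, taf), tarling_imp(0.5, 35, taf))
  # juvenile IMP peaks near 3 degC on a temperature scan
  tj <- load_parameter_set("tarling2006", "imp", "juvenile")
  scan <- seq(-2, 5, by = 0.05)
  ij <- tarling_imp(scan, 26, tj)
  expect_lt(abs(scan[which.max(ij)] - 3), 0.5)
  expect_error(tarling_imp(0, 0, taf), "positive")
})

test_that("stage parameterizations switch at the 35 mm threshold", {
  expect_identical(stage_select(34.9, "atkinson2006"), "juvenile")
  expect_identical(stage_select(35.0, "atkinson2006"), "all krill")
  expect_identical(stage_select(35.0, "wiedenmann2008"), "all krill")
  expect_identical(stage_select(34.9, "tarling2006"), "juvenile")
  expect_identical(stage_select(35.0, "tarling2006"), "adult female")
  expect_error(stage_select(0, "atkinson2006"), "positive")
})

test_that("the moult clock grows stepwise, averages its IMP and extends on ice", {
  imp10 <- function(sst, len, stage) 10
  env <- list(sst = 0.5, chl = 1.2)
  # zero growth-rate function: moult happens, length unchanged
  st <- list(length = 26, stage = "juvenile", clock = moult_clock(10))
  for (i in 1:10) st <- moult_step(st, env, imp10,
                                   function(...) 0)
  expect_true(st$moulted)
  expect_equal(st$length, 26)
  # constant forcing: increment equals DGR x IMP, i.e. the sum of an
  # equivalent daily-rate accumulation over the IMP (oracle)
  dgr_const <- function(len, sst, chl, imp, stage) 0.07 * chl
  st <- list(length = 26, stage = "juvenile", clock = moult_clock(10))
  moult_days <- integer(0)
  for (i in 1:10) {
    st <- moult_step(st, env, imp10, dgr_const)
    if (st$moulted) moult_days <- c(moult_days, i)
  }
  daily_oracle <- sum(rep(0.07 * env$chl, 10))
  expect_equal(st$length - 26, daily_oracle)
  expect_identical(moult_days, 10L)
  # the within-IMP running means feed the increment
  st <- list(length = 26, stage = "juvenile", clock = moult_clock(3))
  seen <- NULL
  spy <- function(len, sst, chl, imp, stage) { seen <<- c(sst, chl); 0 }
  for (chl in c(1, 2, 6)) st <- moult_step(st, list(sst = 0, chl = chl),
                                           imp10, spy)
  expect_equal(seen, c(0, 3))  # mean of 1, 2, 6
  # three interleaved ice days extend a 10-day IMP to a day-13 moult
  st <- list(length = 26, stage = "juvenile", clock = moult_clock(10))
  day_of_moult <- NA
  for (i in 1:13) {
    st <- if (i %in% c(3, 6, 9)) moult_ice_day(st)
          else moult_step(st, env, imp10, dgr_const)
    if (isTRUE(st$moulted)) { day_of_moult <- i; break }
  }
  expect_identical(day_of_moult, 13L)
})

test_that("doubling the moulting frequency doubles cumulative growth", {
  env <- list(sst = 0, chl = 1)
  run <- function(imp) {
    st <- list(length = 26, stage = "juvenile", clock = moult_clock(imp))
    # identical 1 mm increments at every moult, whatever the IMP
    unit_increment <- function(len, sst, chl, imp_days, stage) 1 / imp_days
    for (i in 1:60) st <- moult_step(st, env, function(...) imp,
                                     unit_increment)
    st$length - 26
  }
  expect_equal(run(5), 2 * run(10))
  expect_gt(run(5), 0)
})

test_that("composite trajectories are constant between moults with rate = increment/IMP", {
  f <- const_forcing(sst = 0.5, chl = 1.5, n = 80)
  for (id in c("wiedenmann2008", "tarling2006")) {
    m <- krill_model(id)
    tr <- simulate_trajectory(m, f, simulation_config(start = f$date[1],
                                                      end = f$date[80]))
    # between moult events the length series is exactly constant
    changes <- diff(tr$length_mm) != 0
    expect_true(all(tr$moulted[-1][changes]))
    # effective daily rate between first and second moult = increment/IMP
    mo <- which(tr$moulted)
    expect_gt(length(mo), 1)
    imp <- tr$imp_days[mo[1]]  # IMP drawn at the first moult
    inc <- tr$length_mm[mo[2]] - tr$length_mm[mo[1]]
    expect_equal(inc / imp,
                 m$rate(tr$length_mm[mo[1]], 0.5, 1.5),
                 tolerance = 1e-10)
  }
})
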