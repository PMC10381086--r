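test_that("Holling type II response saturates from zero towards one", {
  expect_equal(holling_type_II(3, 3), 0.5)
  expect_equal(holling_type_II(0, 3), 0)
  expect_lt(holling_type_II(1e6, 3), 1)
  expect_gt(holling_type_II(1e6, 3), 0.999)
  expect_true(all(diff(holling_type_II(seq(0, 10, 0.1), 2)) > 0))
  expect_error(holling_type_II(1, 0), "positive")
  expect_error(holling_type_II(-1, 1), "non-negative")
})

test_that("clearance-feeding models cap at +0.25 mm/d and shrink without food", {
  for (id in c("hofmann2000", "fach2002")) {
    m <- krill_model(id)
    grid <- expand.grid(sst = seq(-2, 5, by = 0.25),
                        chl = seq(0, 20, by = 0.25))
    r <- mapply(function(s, c) m$rate(26, s, c), grid$sst, grid$chl)
    expect_equal(max(r), 0.25)               # cap binds exactly
    expect_true(all(r <= 0.25))
    # mid-summer starvation means shrinkage
    expect_lt(m$rate(26, 0.5, 0), 0)
    # cap onset falls at chl 1.4-1.7 mg m-3 for some temperature
    onset <- sapply(seq(-2, 5, by = 0.5), function(s) {
      chl <- seq(0, 5, by = 0.005)
      chl[which(sapply(chl, function(c) m$rate(26, s, c)) >= 0.25)[1]]
    })
    expect_true(any(onset >= 1.4 & onset <= 1.7))
  }
  # the Fach variant has the weaker temperature dependence of metabolism
  h <- krill_model("hofmann2000"); f <- krill_model("fach2002")
  spread <- function(m) m$rate(26, -2, 0) - m$rate(26, 5, 0)
  expect_lt(spread(f), spread(h))
})

test_that("DEB growth plateaus near 60 mm and respects the flux balance", {
  j <- krill_model("jager2015")
  cfg <- list(unlimited_food = TRUE)
  L <- 26
  for (i in 1:4000) {
    d <- j$deriv(L, list(sst = 0.5, chl = 0), NULL, cfg)
    L <- L + d
    if (d < 1e-4) break
  }
  expect_lt(abs(L - 60), 2)
  # under any constant f <= 1 the length never exceeds the f = 1 asymptote
  for (chl in c(0.5, 2, 8, 50)) {
    Lc <- 26
    for (i in 1:3000) Lc <- Lc + j$deriv(Lc, list(sst = 2, chl = chl),
                                         NULL, list())
    expect_lt(Lc, 60 + 1e-6)
  }
  # starvation: maintenance exceeds assimilation
  expect_lt(j$rate(26, 0, 0), 0)
  b <- krill_model("bahlburg2021")
  expect_lt(b$rate(26, 0, 0, photoperiod = 12), 0)
  # a mis-set allocation fraction is rejected
  ps <- load_parameter_set("jager2015", "growth", "all krill")
  ps$coefficients[["kappa"]] <- 1.2
  expect_error(deb_rate(26, list(sst = 0, chl = 1), ps), "allocation")
})

test_that("photoperiod scaling lowers respiration under short days only for the DEB variant", {
  jp <- load_parameter_set("jager2015", "growth", "all krill")
  bp <- load_parameter_set("bahlburg2021", "growth", "all krill")
  env_winter <- list(sst = 0, chl = 1, photoperiod = 5)
  expect_lte(deb_respiration(26, env_winter, bp, "photoperiod"),
             deb_respiration(26, env_winter, jp, "simplified"))
  # scaling is bounded and monotone over [0, 24]
  s <- photoperiod_scaling(seq(0, 24, by = 0.5))
  expect_true(all(s >= 0.5 & s <= 1))
  expect_true(all(diff(s) > 0))
  expect_error(photoperiod_scaling(25), "photoperiod")
  # rate models other than the photoperiod variant ignore the argument
  for (id in c("atkinson2006", "tarling2006", "hofmann2000", "jager2015",
               "ryabov2017")) {
    m <- krill_model(id)
    expect_equal(m$rate(26, 1, 1, photoperiod = 8),
                 m$rate(26, 1, 1, photoperiod = 20))
  }
  bb <- krill_model("bahlburg2021")
  expect_false(isTRUE(all.equal(bb$rate(26, 1, 1, photoperiod = 8),
                                bb$rate(26, 1, 1, photoperiod = 20))))
})

test_that("the energy-partitioning model grows at lower food than the DEB variants", {
  r <- krill_model("ryabov2017")
  b <- krill_model("bahlburg2021")
  need_r <- required_chl(r, 0.05, sst = 0, photoperiod = 20)
  need_b <- required_chl(b, 0.05, sst = 0, photoperiod = 20)
  expect_true(is.na(need_b) || need_r < need_b)
  expect_lte(r$rate(26, 0, 0), 0)
  # constant moderate forcing over a season: growth of order +5 mm
  f <- const_forcing(sst = 0, chl = 0.4, n = 166)
  tr <- simulate_trajectory(r, f, simulation_config())
  expect_gt(attr(tr, "final_change"), 2)
  expect_lt(attr(tr, "final_change"), 12)
})

test_that("the winter metabolic switch is inactive during the simulated season", {
  mods <- list(factor = 0.5, window = c("04-16", "10-31"))
  expect_equal(winter_switch(as.Date("2010-01-15"), mods), 1)
  expect_equal(winter_switch(as.Date("2010-07-01"), mods), 0.5)
  expect_equal(winter_switch("05-10", mods), 0.5)
  expect_error(winter_switch("05-10", list(factor = 1.5,
                                           window = c("04-16", "10-31"))),
               "factor")
  # config audit: every date of the default 166-day run lies outside the
  # winter windows configured for the switch-carrying models
  dates <- seq(as.Date("2009-11-01"), as.Date("2010-04-15"), by = "day")
  for (id in c("hofmann2000", "fach2002", "ryabov2017")) {
    reg <- load_model_registry(id)
    ps <- load_parameter_set(id, "growth", "all krill")
    m <- list(factor = ps$coefficients[["winter_factor"]],
              window = unlist(reg$winter_window))
    expect_true(all(vapply(dates, winter_switch, numeric(1),
                           modifiers = m) == 1))
  }
})

test_that("mechanistic models starve cleanly: negative growth, finite states", {
  f0 <- make_fixture("zero_food")
  cfg <- simulation_config()
  for (id in c("hofmann2000", "fach2002", "jager2015", "bahlburg2021",
               "ryabov2017")) {
    tr <- simulate_trajectory(id, f0, cfg)
    expect_true(all(is.finite(tr$length_mm)))
    expect_lt(attr(tr, "final_change"), 0)
    expect_true(all(diff(tr$length_mm) <= 0))
  }
})
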