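test_that("response surfaces are food-monotone and reproduce the documented optima", {
  surfaces <- lapply(krill_models("all"), response_surface,
                     sst_axis = coarse_sst, chl_axis = coarse_chl)
  for (s in surfaces) {
    expect_true(all(is.finite(s$rate)))
    expect_identical(dim(s$rate), c(length(coarse_sst), length(coarse_chl)))
    # non-decreasing along the chlorophyll axis at every temperature
    expect_true(all(apply(s$rate, 1, function(r) all(diff(r) >= -1e-12))))
  }
  argmax_sst <- function(s) {
    i <- which(s$rate == max(s$rate), arr.ind = TRUE)
    s$sst[i[1, 1]]
  }
  # the Tarling composite peaks at the cold end (around -1 degC), the
  # Kawaguchi-IMP composite at temperatures above 1 degC
  expect_lt(abs(argmax_sst(surfaces$tarling2006) - (-1)), 1.1)
  expect_gt(argmax_sst(surfaces$wiedenmann2008), 1)
  # all models agree on positive growth once food is plentiful
  hi <- which(coarse_chl >= 2)
  for (s in surfaces) expect_true(all(s$rate[, hi] > 0))
  # opposite growth directions at (1 mg m-3, 0 degC)
  j <- krill_model("jager2015"); t <- krill_model("tarling2006")
  expect_lt(j$rate(26, 0, 1), 0)
  expect_gt(t$rate(26, 0, 1), 0)
  expect_error(response_surface("atkinson2006", sst_axis = c(1, 1, 2)),
               "strictly increasing")
  expect_error(response_surface("bahlburg2021", photoperiod = NULL,
                                sst_axis = coarse_sst, chl_axis = coarse_chl),
               "photoperiod")
})

test_that("required chlorophyll inverts the growth response", {
  for (id in c("atkinson2006", "tarling2006", "ryabov2017")) {
    m <- krill_model(id)
    c10 <- required_chl(m, 0.10, sst = 1)
    c15 <- required_chl(m, 0.15, sst = 1)
    expect_gte(c15, c10)
    # inversion property: the returned chl achieves the target
    expect_gte(m$rate(26, 1, c10), 0.10)
    expect_lt(m$rate(26, 1, max(0, c10 - 2e-3)), 0.10)
  }
  # the growth cap makes higher targets unreachable
  u <- required_chl("hofmann2000", 0.30, sst = 1)
  expect_true(is.na(u))
  expect_identical(attr(u, "status"), "unreachable")
  # the mechanistic models need more food than any empirical model for
  # 0.1 mm/d at 1 degC and 26 mm
  req <- vapply(krill_models("all"), function(m) {
    r <- required_chl(m, 0.10, sst = 1)
    if (is.na(r)) Inf else r
  }, numeric(1))
  emp <- c("atkinson2006", "tarling2006", "wiedenmann2008")
  mech <- setdiff(krill_model_ids(), emp)
  expect_gt(min(req[mech]), max(req[emp]))
})

test_that("ensemble spread matches the direct population-SD formula", {
  f <- const_forcing(0.5, 1, n = 30)
  cfg <- simulation_config(start = f$date[1], end = f$date[30])
  ens <- simulate_ensemble(c("jager2015", "ryabov2017", "hofmann2000"),
                           f, cfg)
  sp <- ensemble_spread(ens)
  expect_identical(nrow(sp), 30L)
  expect_equal(sp$sd_mm[1], 0)  # common 26 mm start
  lens <- sapply(ens, function(tr) tr$length_mm)
  d <- 17
  mu <- mean(lens[d, ])
  expect_equal(sp$sd_mm[d], sqrt(mean((lens[d, ] - mu)^2)))
  # identical trajectories have zero spread everywhere
  expect_true(all(ensemble_spread(ens[c(1, 1, 1)])$sd_mm == 0))
  # misaligned dates are refused
  ens2 <- ens
  ens2[[2]]$date <- ens2[[2]]$date + 1
  expect_error(ensemble_spread(ens2), "misaligned")
})

test_that("divergence maps normalise cross-model spread per cell", {
  # toy 2-model cell with final values 10 and 30: direct arithmetic
  m <- matrix(c(10, 26, 30, 26), nrow = 2)
  dm <- divergence_map(m)
  expect_equal(dm$mean[1], 20)
  expect_equal(dm$sd[1], 10)          # population SD
  expect_equal(dm$cv[1], 0.5)
  expect_equal(dm$cv[2], 0)           # all models equal -> CV 0
  expect_error(divergence_map(matrix(1:3, ncol = 1)), "two models")
  # near-zero means are flagged undefined, not dropped
  dm0 <- divergence_map(matrix(c(0.01, -0.01, 5, 6), nrow = 2,
                               byrow = TRUE))
  expect_true(dm0$flagged[1] && is.na(dm0$cv[1]))
  expect_false(dm0$flagged[2])
  # cells where models uniformly predict near-initial lengths diverge less
  # than cells with mixed growth directions
  quiet_cell <- c(26.2, 25.9, 26.1, 26.0)     # Weddell-like: frozen, poor
  mixed_cell <- c(19, 26, 40, 60)             # strong disagreement
  dm2 <- divergence_map(rbind(quiet_cell, mixed_cell))
  expect_lt(dm2$cv[1], dm2$cv[2])
})

test_that("surfaces export to long-format CSV", {
  s <- response_surface("atkinson2006", sst_axis = c(0, 1),
                        chl_axis = c(0, 1, 2))
  path <- tempfile(fileext = ".csv")
  write_surface_csv(s, path)
  df <- read.csv(path)
  expect_identical(nrow(df), 6L)
  expect_equal(df$rate[df$sst == 1 & df$chl == 2],
               krill_model("atkinson2006")$rate(26, 1, 2))
})
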