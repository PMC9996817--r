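test_that("cosolvent regression recovers exact and generating parameters", {
  pts <- data.frame(methanol_mole_fraction = c(0.1, 0.2, 0.3),
                    log_kpw_obs = c(5.0, 4.0, 3.0))
  fit <- fit_cosolvent_regression(pts)
  expect_equal(fit$intercept, 6.0)
  expect_equal(fit$slope, -10.0)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(coef(fit)), c(6, -10))

  noisefree <- gen_cosolvent_series(5.86, -8, seq(0.05, 0.45, by = 0.05))
  expect_equal(fit_cosolvent_regression(noisefree)$intercept, 5.86,
               tolerance = 1e-9)

  expect_error(fit_cosolvent_regression(pts[1:2, ]),
               class = "plumetox_data_error")
  same_x <- data.frame(methanol_mole_fraction = rep(0.2, 4),
                       log_kpw_obs = 1:4)
  expect_error(fit_cosolvent_regression(same_x), class = "plumetox_data_error")
})

test_that("cosolvent regression is unbiased over noisy fixtures", {
  ints <- vapply(1:200, function(s) {
    pts <- gen_cosolvent_series(5.86, -8, seq(0.05, 0.45, by = 0.05),
                                noise_sd = 0.1, seed = s)
    fit_cosolvent_regression(pts)$intercept
  }, 0)
  expect_equal(mean(ints), 5.86, tolerance = 0.02)
})

test_that("PRC exchange coefficient follows -ln(f)/t", {
  expect_equal(prc_exchange_coefficient(list(fraction_retained = 1,
                                             deployment_days = 7)), 0)
  expect_equal(prc_exchange_coefficient(list(fraction_retained = exp(-1),
                                             deployment_days = 1)), 1)
  expect_equal(prc_exchange_coefficient(list(fraction_retained = 0.5,
                                             deployment_days = 3.5)),
               log(2) / 3.5)
  expect_error(prc_exchange_coefficient(list(fraction_retained = 0,
                                             deployment_days = 1)),
               class = "plumetox_domain_error")
})

test_that("PRC pooling scales, is idempotent, and recovers ke", {
  s <- default_sampler()
  one <- data.frame(compound = "PRC1", fraction_retained = 0.5,
                    deployment_days = 2)
  kin1 <- pool_prc_kinetics(one, s)  # PRC Kpw defaults to the analyte's
  expect_equal(kin1$ke, log(2) / 2)
  expect_equal(kin1$rs, kin1$ke * 10^5.86 * s$mass)

  two <- rbind(one, one)
  expect_equal(pool_prc_kinetics(two, s)$ke, kin1$ke)

  fix <- gen_prc_dissipation(0.5, c(0.5, 1, 2), compounds = paste0("P", 1:3))
  expect_equal(pool_prc_kinetics(fix, s)$ke, 0.5, tolerance = 1e-9)

  # transfer across hydrophobicity: ke scales with Kpw_PRC / Kpw_analyte
  kin_sc <- pool_prc_kinetics(one, s, prc_log_kpw = c(PRC1 = 4.86))
  expect_equal(kin_sc$ke, kin1$ke / 10)

  outside <- data.frame(compound = "P", fraction_retained = 0.99,
                        deployment_days = 1)
  expect_error(pool_prc_kinetics(outside, s), class = "plumetox_data_error")
})

test_that("regime classification follows ke*T", {
  s <- default_sampler()
  expect_equal(exchange_kinetics(0.01, s, deployment_days = 3.5)$regime, "kinetic")
  expect_equal(exchange_kinetics(0.3, s, deployment_days = 3.5)$regime, "intermediate")
  expect_equal(exchange_kinetics(2, s, deployment_days = 3.5)$regime, "equilibrium")
})

test_that("water concentration inverts uptake and guards ke = 0", {
  s <- default_sampler()
  kin <- exchange_kinetics(0.4, s, deployment_days = 3.5)
  expect_equal(water_concentration(0, s, kin, 3.5), 0)

  # equilibrium limit: absorbed = Kpw*m*100 infers cw = 100
  kin_eq <- exchange_kinetics(100, s)
  expect_equal(water_concentration(10^5.86 * s$mass * 100, s, kin_eq, 2), 100,
               tolerance = 1e-9)

  N <- gen_pas_uptake(data.frame(time_d = c(0, 3.5), cw = c(250, 250)), s, kin)
  expect_equal(water_concentration(N, s, kin, 3.5), 250, tolerance = 250 * 1e-3)

  kin0 <- exchange_kinetics(0, s, rs = 0.02)
  expect_equal(water_concentration(0.04, s, kin0, 0.5), 4)
  expect_error(water_concentration(-1, s, kin, 1),
               class = "plumetox_domain_error")
})

test_that("kinetic form approaches the general form as ke*t shrinks", {
  # the relative gap between the general inversion and the linear-uptake
  # approximation is (1 - exp(-x))/x - 1 ~ -x/2: below 1% for ke*t < 0.02
  # and below 7.5% throughout the kinetic regime (ke*t < 0.14)
  s <- default_sampler()
  gap <- function(keT, t = 2) {
    kin <- exchange_kinetics(keT / t, s)
    N <- 1.23
    general <- water_concentration(N, s, kin, t)
    kinetic <- N / (kin$rs * t)
    abs(general - kinetic) / general
  }
  for (keT in c(0.001, 0.019)) expect_lt(gap(keT), 0.01)
  for (keT in c(0.05, 0.1, 0.139)) expect_lt(gap(keT), 0.075)
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.1), gap, 0)) > 0))
})

test_that("kinetic rescaling reproduces the duration-scenario arithmetic", {
  expect_equal(rescale_kinetic(364, 0.5, 2), 91)
  expect_equal(rescale_kinetic(10, 3, 3), 10)
  expect_equal(round_half_away(rescale_kinetic(74, 0.5, 3.5)), 11)
  expect_error(rescale_kinetic(10, 0, 1), class = "plumetox_domain_error")
})

test_that("scenario table rescales, rounds, and conserves c*t per row", {
  base <- data.frame(station = "B", depth_band = "3-5 m", cw = 143,
                     t_ref = 0.5, distance_to_pen = 45)
  tab <- scenario_table(base, durations = c(1, 2, 3.5))
  expect_equal(tab$cw, c(72, 36, 20))
  expect_equal(unique(tab$rel_uncertainty), 0.5)

  same <- scenario_table(base, durations = 0.5)
  expect_equal(same$cw_raw, 143)

  multi <- data.frame(station = c("B", "E"), cw = c(143, 364), t_ref = 0.5)
  tab2 <- scenario_table(multi, durations = c(0.5, 1, 2, 3.5))
  ct <- tab2$cw_raw * tab2$duration_days
  for (st in c("B", "E"))
    expect_equal(diff(range(ct[tab2$station == st])), 0)

  expect_error(scenario_table(base, numeric(0)),
               class = "plumetox_config_error")
  expect_error(scenario_table(data.frame(station = 1:2, cw = 1:2,
                                         t_ref = c(0.5, 1)), 1),
               class = "plumetox_config_error")
})

test_that("LOD water equivalent scales as 1/t and rounds to one decimal", {
  s <- default_sampler()
  kin <- lod_reference_kinetics(s)
  expect_equal(lod_water_equivalent(0.04, s, kin, 0.5)$reported, 4)
  expect_equal(lod_water_equivalent(0.04, s, kin, 3.5)$reported, 0.6)
  l1 <- lod_water_equivalent(0.04, s, kin, 1)$raw
  l2 <- lod_water_equivalent(0.04, s, kin, 2)$raw
  expect_equal(l1 / l2, 2, tolerance = 1e-4)
  expect_equal(lod_water_equivalent(0, s, kin, 1)$raw, 0)
  expect_error(lod_water_equivalent(0.04, s, kin, 0),
               class = "plumetox_domain_error")
})

test_that("censoring preserves order and counts", {
  all_det <- censor(c(5, 6), 1)
  expect_false(any(all_det$censored))
  all_cen <- censor(c(0.1, 0.2), 1)
  expect_true(all(all_cen$censored))
  mix <- censor(c(0.03, 0.19, 0.01), 0.02)
  expect_equal(sum(mix$censored), 1L)
  expect_equal(sum(!mix$censored), 2L)
  expect_equal(mix$label, c("0.03", "0.19", "<LOD"))
  expect_error(censor(1, 0), class = "plumetox_domain_error")
})
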