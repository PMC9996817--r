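test_that("flow generator: null flow, residual recovery, determinism", {
  g0 <- gen_flow_field(flow_field_spec(tidal_amplitude = 0,
                                       residual_velocity = c(0, 0),
                                       noise_sd = 0),
                       duration_h = 6, dt_s = 600)
  expect_true(all(g0$u_ms == 0) && all(g0$v_ms == 0))

  # tidal ellipse averages out over one full period
  spec <- flow_field_spec(tidal_amplitude = 10, tidal_period = 12,
                          residual_velocity = c(5, 0), noise_sd = 0)
  g <- gen_flow_field(spec, duration_h = 12, dt_s = 600)
  n <- 12 * 3600 / 600  # samples covering [0, T)
  expect_equal(mean(g$u_ms[seq_len(n)]) * 100, 5, tolerance = 1e-6)
  expect_equal(mean(g$v_ms[seq_len(n)]) * 100, 0, tolerance = 1e-6)

  s42a <- gen_flow_field(flow_field_spec(seed = 42), 24, 600)
  s42b <- gen_flow_field(flow_field_spec(seed = 42), 24, 600)
  expect_identical(s42a$u_ms, s42b$u_ms)
  expect_identical(s42a$v_ms, s42b$v_ms)

  expect_error(gen_flow_field(spec, -1, 600), class = "plumetox_config_error")
  expect_error(gen_flow_field(spec, 6, 0), class = "plumetox_config_error")
})

test_that("default flow speeds stay within the 0-20 cm/s envelope", {
  g <- gen_flow_field(flow_field_spec(seed = 3), duration_h = 7 * 24, dt_s = 600)
  speed <- sqrt(g$u_ms^2 + g$v_ms^2) * 100
  expect_gte(mean(speed >= 0 & speed <= 20), 0.99)
})

test_that("PRC dissipation follows the first-order closed form", {
  expect_equal(gen_prc_dissipation(0, c(1, 5))$fraction_retained, c(1, 1))
  expect_equal(gen_prc_dissipation(1, 1)$fraction_retained, exp(-1))
  expect_equal(gen_prc_dissipation(0.2, 3.5)$fraction_retained, exp(-0.7))
  expect_error(gen_prc_dissipation(-0.1, 1), class = "plumetox_domain_error")
  expect_error(gen_prc_dissipation(1, c(1, 0)), class = "plumetox_domain_error")
  a <- gen_prc_dissipation(0.5, 1:4, noise_sd = 0.1, seed = 11)
  b <- gen_prc_dissipation(0.5, 1:4, noise_sd = 0.1, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$fraction_retained > 0 & a$fraction_retained <= 1))
})

test_that("cosolvent series: exact line, empty input, reproducible noise", {
  s <- gen_cosolvent_series(5.86, -8, c(0.1, 0.2, 0.3))
  expect_equal(s$log_kpw_obs, 5.86 - 8 * c(0.1, 0.2, 0.3))
  expect_identical(nrow(gen_cosolvent_series(5, -8, numeric(0))), 0L)
  a <- gen_cosolvent_series(5.86, -8, seq(0.1, 0.5, 0.1), 0.1, seed = 4)
  b <- gen_cosolvent_series(5.86, -8, seq(0.1, 0.5, 0.1), 0.1, seed = 4)
  expect_identical(a, b)
  expect_error(gen_cosolvent_series(5, -8, c(0.2, 1)),
               class = "plumetox_domain_error")
})

test_that("mortality generator: limits, conservation, binomial mean", {
  des <- mortality_design()
  zero <- gen_mortality(des, setNames(rep(0, 4), as.character(des$doses)),
                        seed = 1)
  expect_true(all(zero$dead == 0))
  expect_identical(nrow(zero), 20L)  # 4 doses x 5 tanks

  p1 <- setNames(c(0, 0, 0, 1), as.character(des$doses))
  all_dead <- gen_mortality(des, p1, seed = 1)
  expect_identical(sum(all_dead$dead[all_dead$treatment == 2]), 40L)
  expect_true(all(all_dead$dead >= 0 & all_dead$dead <= all_dead$n))

  expect_error(gen_mortality(des, c("0" = 0.1)),
               class = "plumetox_config_error")
  expect_error(gen_mortality(des, setNames(c(0, 0, 0, 1.2),
                                           as.character(des$doses))),
               class = "plumetox_domain_error")

  # Monte-Carlo mean of the binomial death process at p = 0.8
  des_big <- mortality_design(doses = 2, tanks_per_treatment = 2000)
  props <- vapply(1:5, function(s) {
    out <- gen_mortality(des_big, c("2" = 0.8), seed = s)
    mean(out$dead / out$n)
  }, 0)
  expect_equal(mean(props), 0.80, tolerance = 0.01)
})

test_that("sediment generator: symmetry, censoring, default range", {
  sym <- gen_sediment_field(distances = c(200, 200), patchiness_sd = 0)
  expect_equal(sym$value[1], sym$value[2])
  allcen <- gen_sediment_field(distances = c(0, 100), lod = 100, seed = 1)
  expect_true(all(allcen$censored))
  expect_true(all(allcen$label == "<LOD"))
  expect_error(gen_sediment_field(decay_length = 0),
               class = "plumetox_domain_error")

  # detected values under defaults emulate the observed few-hundredths to
  # few-tenths ng/g range: 0.5%-99.5% quantiles inside [0.02, 0.5]
  vals <- unlist(lapply(1:1000, function(s) {
    f <- gen_sediment_field(seed = s)
    f$value[!f$censored]
  }))
  q <- quantile(vals, c(0.005, 0.995))
  expect_gte(q[[1]], 0.02)
  expect_lte(q[[2]], 0.5)
})

test_that("forward PAS uptake: zero input, equilibrium limit, exact quadrature", {
  s <- default_sampler()
  kin <- exchange_kinetics(0.5, s, deployment_days = 4)
  expect_equal(gen_pas_uptake(data.frame(time_d = c(0, 4), cw = c(0, 0)), s, kin), 0)

  # ke*T >> 1: absorbed approaches equilibrium Kpw * m * cw
  kin_eq <- exchange_kinetics(50, s)
  N <- gen_pas_uptake(data.frame(time_d = c(0, 2), cw = c(100, 100)), s, kin_eq)
  expect_equal(N, 10^5.86 * s$mass * 100, tolerance = 1e-9)

  expect_error(gen_pas_uptake(data.frame(time_d = c(0, 1), cw = c(-1, -1)), s, kin),
               class = "plumetox_domain_error")
  # piecewise-constant series equals the sum of its closed-form pieces
  cw <- data.frame(time_d = c(0, 1, 2, 3), cw = c(50, 200, 0, 0))
  ke <- kin$ke; rs <- ke * kin$kpw * kin$mass
  manual <- rs * 50 / ke * (exp(-ke * 2) - exp(-ke * 3)) +
    rs * 200 / ke * (exp(-ke * 1) - exp(-ke * 2))
  expect_equal(gen_pas_uptake(cw, s, kin), manual, tolerance = 1e-12)
})

test_that("uptake/inference round trip recovers truth across regimes", {
  s <- default_sampler()
  for (log_kpw_val in c(3, 5, 7)) {
    samp <- polymer_sampler("AlteSil", mass = 0.001,
                            log_kpw = c(deltamethrin = log_kpw_val))
    for (keT in c(0.01, 0.14, 1, 10)) {
      t_col <- 3.5
      kin <- exchange_kinetics(keT / t_col, samp, deployment_days = t_col)
      N <- gen_pas_uptake(data.frame(time_d = c(0, t_col), cw = c(100, 100)),
                          samp, kin)
      cw_hat <- water_concentration(N, samp, kin, t_col)
      expect_equal(cw_hat, 100, tolerance = 1e-3)
    }
  }
})
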