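# Shared fixtures built in code.

default_sampler <- function() polymer_sampler("AlteSil", mass = 0.001)

# Kinetics whose sampling rate makes a 0.04 ng/g polymer LOD correspond to a
# 4 ng/L water LOD at 0.5 days (Rs = 0.04 ng/g * 1 g / (4 ng/L * 0.5 d)).
lod_reference_kinetics <- function(sampler = default_sampler()) {
  rs <- 0.02
  exchange_kinetics(rs / (10^log_kpw(sampler) * sampler$mass), sampler)
}

# Small dispersal run shared by dispersal and acceptance tests: 6 x 6 km at
# dx = 100 m, two cage releases 12 h apart, 30 h simulated.
small_run <- function(boundaries = "open", diffusivity = 1, seed = 1) {
  grid <- tracer_grid(60, 60, 100)
  spec <- flow_field_spec(tidal_amplitude = 5, residual_velocity = c(5, 0),
                          noise_sd = 1, seed = seed)
  flow <- gen_flow_field(spec, duration_h = 32, dt_s = 400)
  sch <- build_schedule(2, 12, positions = cbind(1000, 3000))
  params <- tracer_params(diffusivity = diffusivity, dt = 400,
                          duration_days = 1.25, boundaries = boundaries)
  list(grid = grid, flow = flow, schedule = sch, params = params,
       history = simulate_dispersal(grid, flow, sch, params))
}
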