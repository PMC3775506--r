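# Single-neuron oracles and runners used by the simulator and acceptance
# tests.

# Reference integration of the single-neuron two-ODE system (membrane +
# exponential excitatory conductance) on a fine grid; independent of the
# package's stepping code.
reference_epsp <- function(w_uS, t_spike, params, t_end, dt_fine) {
  n <- round(t_end / dt_fine)
  V <- params$E_l
  g <- 0
  out <- numeric(n)
  for (s in seq_len(n)) {
    t <- (s - 1) * dt_fine
    if (abs(t - t_spike) < dt_fine / 2) g <- g + w_uS
    gtot <- params$g_l + g
    vinf <- (params$g_l * params$E_l + g * params$E_E) / gtot
    V <- vinf + (V - vinf) * exp(-dt_fine * gtot / params$C_m)
    g <- g * exp(-dt_fine / params$tau_E)
    out[s] <- V
  }
  out
}

# One neuron of each population, no noise, optional stimulus spikes onto the
# excitatory neuron; returns spikes and the excitatory neuron's V trace.
run_single_neuron <- function(input_times = numeric(0), w_input = 5,
                              duration = 50, dt = 0.1, v_init = -65,
                              params = neuron_params()) {
  tun <- manual_tuning(x = 0.5, y = 0.5, u = 0.5, v = 0)
  tun_i <- manual_tuning(x = 0.1, y = 0.1, u = 0.5, v = 0)
  drive <- no_input()
  inp <- data.frame(neuron_id = rep(1L, length(input_times)),
                    time = input_times)
  class(inp) <- c("spike_record", "data.frame")
  cfg <- simulator_config(dt = dt, duration = duration,
                          V_init_mean = v_init, V_init_sd = 0,
                          record_v = 1L)
  simulate_network(tun, tun_i, empty_synapses(), inp, drive$noise,
                   input_params(w_input = w_input), params, cfg)
}
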