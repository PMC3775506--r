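#' Neuron parameters of the conductance-based LIF model
#'
#' Membrane dynamics follow
#' \deqn{C_m dV/dt = g_l (E_l - V) + g_E (E_E - V) + g_I (E_I - V)}
#' with exponentially decaying summed synaptic conductances. A spike is
#' emitted when `V >= V_thresh`; `V` is clamped to `V_reset` for
#' `tau_refrac` ms. The defaults give a membrane time constant
#' `tau_m = C_m / g_l = 10` ms.
#'
#' @param C_m Membrane capacitance, nF.
#' @param g_l Leak conductance, microsiemens.
#' @param E_l Leak (resting) potential, mV.
#' @param E_E,E_I Excitatory / inhibitory reversal potentials, mV.
#' @param tau_E,tau_I Synaptic conductance time constants, ms.
#' @param V_thresh Spike threshold, mV.
#' @param V_reset Reset potential, mV.
#' @param tau_refrac Refractory period, ms.
#' @return Object of class `neuron_params`.
#' @export
neuron_params <- function(C_m = 1, g_l = 0.1, E_l = -70, E_E = 0, E_I = -70,
                          tau_E = 5, tau_I = 10,
                          V_thresh = -50, V_reset = -70, tau_refrac = 1) {
  stopifnot(C_m > 0, g_l > 0, tau_E > 0, tau_I > 0,
            E_I <= V_reset, V_reset <= V_thresh, V_thresh < E_E)
  structure(list(C_m = C_m, g_l = g_l, E_l = E_l, E_E = E_E, E_I = E_I,
                 tau_E = tau_E, tau_I = tau_I, V_thresh = V_thresh,
                 V_reset = V_reset, tau_refrac = tau_refrac),
            class = "neuron_params")
}

#' Simulator configuration
#'
#' @param dt Integration step, ms.
#' @param duration Simulated time, ms.
#' @param V_init_mean,V_init_sd Initial membrane potentials are drawn from
#'   `Normal(V_init_mean, V_init_sd)`; draws above threshold are redrawn so
#'   no neuron spikes spuriously at t = 0.
#' @param record_v Optional integer vector of global neuron indices whose
#'   voltage traces are recorded.
#' @return Object of class `simulator_config`.
#' @export
simulator_config <- function(dt = 0.1, duration = 1000,
                             V_init_mean = -65, V_init_sd = 10,
                             record_v = integer(0)) {
  stopifnot(dt > 0, duration >= 0)
  structure(list(dt = dt, duration = duration,
                 V_init_mean = V_init_mean, V_init_sd = V_init_sd,
                 record_v = as.integer(record_v)),
            class = "simulator_config")
}

#' Exponential membrane update over one step
#'
#' With conductances frozen over the step the membrane equation is linear
#' and its exact solution is
#' `V' = V_inf + (V - V_inf) * exp(-dt * g_tot / C_m)` with
#' `g_tot = g_l + g_E + g_I` and
#' `V_inf = (g_l E_l + g_E E_E + g_I E_I) / g_tot`. `V_inf` is a convex
#' combination of the reversal potentials, so the update can never leave
#' `[E_I, E_E]` once inside.
#'
#' @param V Membrane potential(s), mV.
#' @param g_E,g_I Synaptic conductances, microsiemens.
#' @param params A [neuron_params()].
#' @param dt Step, ms.
#' @return Updated potential(s), mV.
#' @export
exponential_step <- function(V, g_E, g_I, params, dt) {
  g_tot <- params$g_l + g_E + g_I
  v_inf <- (params$g_l * params$E_l + g_E * params$E_E + g_I * params$E_I) / g_tot
  v_inf + (V - v_inf) * exp(-dt * g_tot / params$C_m)
}

#' Delivery step of a delayed spike
#'
#' Delays are discretized to the nearest integer number of steps, never less
#' than one, so a spike can never influence the step it was emitted in.
#'
#' @param emission_step Integer step the spike was emitted in.
#' @param delay Delay in ms.
#' @param dt Step, ms.
#' @return Integer delivery step.
#' @export
schedule_delivery <- function(emission_step, delay, dt) {
  emission_step + pmax(1L, as.integer(round(delay / dt)))
}

# Draw initial membrane potentials, redrawing values above threshold.
draw_v_init <- function(n, mean, sd, v_thresh) {
  v <- stats::rnorm(n, mean, sd)
  bad <- which(v >= v_thresh)
  while (length(bad) > 0) {
    v[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[v[bad] >= v_thresh]
  }
  v
}

# CSR-index external spike events by integration step (constant weight per
# channel). Returns list(ptr, tgt (0-based)) with ptr of length n_steps + 1.
index_events_by_step <- function(time_ms, target, dt, n_steps) {
  step <- as.integer(floor(time_ms / dt))
  keep <- step >= 0L & step < n_steps
  step <- step[keep]
  target <- target[keep]
  o <- order(step)
  counts <- tabulate(step[o] + 1L, nbins = n_steps)
  list(ptr = c(0L, cumsum(counts)), tgt = as.integer(target[o] - 1L))
}

#' Integrate the spiking network
#'
#' Runs the conductance-based LIF network with delayed recurrent spike
#' delivery. Stimulus input spikes reach excitatory neurons through an
#' excitatory synapse of weight `w_input` (nS); every neuron additionally
#' receives the excitatory- and inhibitory-polarity noise trains at
#' `w_noise` (nS). Recurrent synapse weights are in microsiemens.
#'
#' Initial membrane potentials are drawn inside this function, so wrap calls
#' in `set.seed()` for reproducibility.
#'
#' @param tuning_e,tuning_i Tuning tables (only their sizes are used here).
#' @param synapses Named list of `synapse_table`s (`EE`, `EI`, `IE`, `II`)
#'   as returned by [build_network()].
#' @param input_spikes `spike_record` of stimulus spikes (excitatory
#'   neuron ids).
#' @param noise_spikes List with `exc` and `inh` `spike_record`s over all
#'   neurons in global indexing (excitatory first, then inhibitory).
#' @param inputs An [input_params()] (synapse weights in nS).
#' @param params A [neuron_params()].
#' @param config A [simulator_config()].
#' @return List with `spikes` (a `spike_record` with columns `neuron_id`,
#'   `time`, `population`) and `vtrace` (matrix, steps x recorded neurons).
#' @export
simulate_network <- function(tuning_e, tuning_i, synapses, input_spikes,
                             noise_spikes, inputs, params, config) {
  n_exc <- nrow(tuning_e); n_inh <- nrow(tuning_i)
  n <- n_exc + n_inh
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))

  # recurrent synapses in global indexing, CSR by source
  glob <- function(tab) {
    src_off <- if (substr(tab$pathway[1], 1, 1) == "I") n_exc else 0L
    tgt_off <- if (substr(tab$pathway[1], 2, 2) == "I") n_exc else 0L
    data.frame(src = tab$source_id + src_off,
               tgt = tab$target_id + tgt_off,
               w = tab$weight,
               dstep = pmax(1L, as.integer(round(tab$delay / dt))))
  }
  all_syn <- do.call(rbind, lapply(
    Filter(function(s) nrow(s) > 0, synapses), glob))
  if (is.null(all_syn)) {
    all_syn <- data.frame(src = integer(0), tgt = integer(0),
                          w = numeric(0), dstep = integer(0))
  }
  o <- order(all_syn$src)
  all_syn <- all_syn[o, , drop = FALSE]
  syn_ptr <- c(0L, cumsum(tabulate(all_syn$src, nbins = n)))

  # external events: stimulus (E only, exc polarity) + noise per polarity,
  # each channel CSR-indexed by step with a constant weight
  uS <- 1e-3 # nS -> uS
  stim <- index_events_by_step(input_spikes$time, input_spikes$neuron_id,
                               dt, n_steps)
  nxE <- index_events_by_step(noise_spikes$exc$time,
                              noise_spikes$exc$neuron_id, dt, n_steps)
  nxI <- index_events_by_step(noise_spikes$inh$time,
                              noise_spikes$inh$neuron_id, dt, n_steps)

  v_init <- draw_v_init(n, config$V_init_mean, config$V_init_sd,
                        params$V_thresh)
  nrn <- c(unclass(params),
           list(refrac_steps = max(1L, as.integer(round(params$tau_refrac / dt)))))

  out <- sim_core(n_exc, n_inh, v_init, nrn, dt, n_steps,
                  as.integer(syn_ptr), as.integer(all_syn$tgt - 1L),
                  as.numeric(all_syn$w), as.integer(all_syn$dstep),
                  stim$ptr, stim$tgt, inputs$w_input * uS,
                  nxE$ptr, nxE$tgt, inputs$w_noise * uS,
                  nxI$ptr, nxI$tgt, inputs$w_noise * uS,
                  as.integer(config$record_v - 1L))

  spikes <- data.frame(
    neuron_id = ifelse(out$neuron_id > n_exc, out$neuron_id - n_exc,
                       out$neuron_id),
    time = out$step * dt,
    population = ifelse(out$neuron_id > n_exc, "I", "E"))
  class(spikes) <- c("spike_record", "data.frame")
  list(spikes = spikes, vtrace = out$vtrace)
}
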